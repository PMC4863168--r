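#' Time-averaged mean square displacement per track
#'
#' For each track and each admissible time lag `k * dt`, the MSD is the
#' average squared displacement over all (overlapping) ordered frame pairs
#' separated by that lag — the standard time-averaged estimator. Because
#' long lags are supported by few pairs and are statistically unreliable,
#' lags are restricted to at most `max_lag_fraction` of the track's total
#' time: a 300-frame track at 1 frame/s yields lags 1..30 s at the default.
#'
#' @param tracks Track table with columns `track_id`, `frame`, `x`, `y`
#'   (positions in um, frames uniformly sampled).
#' @param dt Frame interval in seconds.
#' @param max_lag_fraction Largest admissible lag as a fraction of total
#'   track time; default 0.1 (the usual single-particle-tracking criterion).
#'
#' @return A tibble with columns `track_id`, `lag` (s), `msd` (um^2) and
#'   `n_pairs` (number of frame pairs averaged at that lag).
#' @export
#' @examples
#' trk <- simulate_brownian(D = 1e-3, n_frames = 300, seed = 1)
#' compute_msd(trk)
compute_msd <- function(tracks, dt = 1, max_lag_fraction = 0.1) {
  check_tracks(tracks)
  check_number(dt, "dt", lower = 0, allow_zero = FALSE)
  check_number(max_lag_fraction, "max_lag_fraction", lower = 0,
               allow_zero = FALSE)
  min_frames <- ceiling(1 / max_lag_fraction) + 1L
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < min_frames) {
        stop_too_short(sprintf(
          "track %s has %d frames; at max_lag_fraction = %g at least %d frames are needed.",
          format(key$track_id), n, max_lag_fraction, min_frames
        ))
      }
      max_steps <- floor(max_lag_fraction * n)
      msd_one(df$x, df$y, max_steps, dt)
    }) |>
    dplyr::ungroup()
}

msd_one <- function(x, y, max_steps, dt) {
  n <- length(x)
  ks <- seq_len(max_steps)
  vals <- vapply(ks, function(k) {
    dxk <- x[(1 + k):n] - x[1:(n - k)]
    dyk <- y[(1 + k):n] - y[1:(n - k)]
    mean(dxk^2 + dyk^2)
  }, numeric(1))
  tibble::tibble(lag = ks * dt, msd = vals, n_pairs = n - ks)
}

#' Pool per-track MSD curves into an ensemble curve
#'
#' Lag-wise weighted mean of per-track MSD values with weights equal to the
#' number of frame pairs, which is identical to pooling all squared
#' displacements across tracks before averaging. All tracks must share the
#' frame interval: the lag grids must nest on a common spacing.
#'
#' @param msd Per-track MSD table from [compute_msd()], or a track table
#'   (columns `track_id`, `frame`, `x`, `y`), in which case per-track MSDs
#'   are computed first with `...` passed to [compute_msd()].
#' @param ... Passed to [compute_msd()] when `msd` is a track table.
#'
#' @return A tibble with columns `lag`, `msd`, `n_pairs` (pairs pooled).
#' @export
ensemble_msd <- function(msd, ...) {
  if (!is.data.frame(msd)) {
    stop_invalid("`msd` must be a data frame.")
  }
  if (all(c("frame", "x", "y") %in% names(msd))) {
    msd <- compute_msd(msd, ...)
  }
  if (!all(c("lag", "msd", "n_pairs") %in% names(msd))) {
    stop_invalid("`msd` must have columns lag, msd, n_pairs (see compute_msd()).")
  }
  base_lag <- min(msd$lag)
  if (any(abs(msd$lag / base_lag - round(msd$lag / base_lag)) > 1e-8)) {
    stop_invalid("lags are not multiples of a common frame interval; tracks with mixed frame intervals cannot be pooled.")
  }
  msd |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(
      msd = sum(.data$msd * .data$n_pairs) / sum(.data$n_pairs),
      n_pairs = sum(.data$n_pairs),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lag)
}

# Shared constrained least-squares core. Columns of the design are chosen so
# every coefficient is nonnegative on physical grounds (D, v^2, epsilon >= 0).
fit_msd_core <- function(msd, model, weight_by_pairs) {
  if (!is.data.frame(msd) || !all(c("lag", "msd") %in% names(msd))) {
    stop_invalid("`msd` must be a data frame with columns lag and msd.")
  }
  if ("track_id" %in% names(msd) && length(unique(msd$track_id)) > 1L) {
    stop_invalid("`msd` holds several tracks; use fit_tracks() or ensemble_msd() first.")
  }
  n <- nrow(msd)
  min_lags <- if (model == "flow") 3L else 2L
  if (n < min_lags) {
    stop_too_short(sprintf(
      "the %s fit needs at least %d lags; got %d.", model, min_lags, n
    ))
  }
  tau <- msd$lag
  w <- if (weight_by_pairs) {
    if (!"n_pairs" %in% names(msd)) {
      stop_invalid("weighting by pairs requires an `n_pairs` column.")
    }
    msd$n_pairs / mean(msd$n_pairs)
  } else {
    rep(1, n)
  }
  degenerate <- all(msd$msd == 0)
  A <- if (model == "flow") cbind(4 * tau, tau^2, 1) else cbind(4 * tau, 1)
  if (degenerate) {
    coefs <- numeric(ncol(A))
  } else {
    sw <- sqrt(w)
    coefs <- pracma::lsqnonneg(A * sw, msd$msd * sw)$x
  }
  fitted_vals <- drop(A %*% coefs)
  resid <- msd$msd - fitted_vals
  out <- list(
    model = model,
    D = coefs[1],
    v_um_min = if (model == "flow") sqrt(coefs[2]) * 60 else NA_real_,
    epsilon = coefs[length(coefs)],
    rss = sum(w * resid^2),
    n_lags = n,
    df_residual = n - ncol(A),
    weighted = weight_by_pairs,
    degenerate = degenerate,
    p_value = NA_real_,
    data = tibble::tibble(lag = tau, msd = msd$msd,
                          fitted = fitted_vals, residual = resid)
  )
  class(out) <- "motion_fit"
  out
}

#' Fit the Brownian MSD model
#'
#' Least-squares fit of `MSD(tau) = 4 * D * tau + epsilon` with `D` and the
#' localization-error offset `epsilon` constrained nonnegative (the offset is
#' positive by construction: it equals four times the localization error
#' variance).
#'
#' @param msd A single MSD curve (columns `lag`, `msd`, optionally `n_pairs`).
#' @param weight_by_pairs Weight lags by their pair counts (default
#'   unweighted, matching common practice over the restricted lag range).
#'
#' @return A `motion_fit` object; see [tidy.motion_fit()] /
#'   [glance.motion_fit()] for tabular views.
#' @export
#' @examples
#' curve <- tibble::tibble(lag = 1:20, msd = 4e-3 * (1:20) + 0.01)
#' glance(fit_brownian(curve))
fit_brownian <- function(msd, weight_by_pairs = FALSE) {
  fit_msd_core(msd, "brownian", weight_by_pairs)
}

#' Fit the flow (directed-motion) MSD model
#'
#' Least-squares fit of `MSD(tau) = 4 * D * tau + (v * tau)^2 + epsilon`,
#' all parameters nonnegative. The drift speed is reported in um/min
#' (the conventional reporting unit for intracellular transport); all
#' internal computation is in um and s.
#'
#' @inheritParams fit_brownian
#' @return A `motion_fit` object with a finite `v_um_min`.
#' @export
fit_flow <- function(msd, weight_by_pairs = FALSE) {
  fit_msd_core(msd, "flow", weight_by_pairs)
}

#' Choose between the Brownian and flow MSD models
#'
#' The two models are nested (Brownian is the `v = 0` limit of flow), so the
#' comparison is an F-test on the drop in residual sum of squares for the one
#' extra parameter. Ties and untestable cases (too few lags, degenerate
#' all-zero curves) resolve to Brownian by parsimony.
#'
#' @inheritParams fit_brownian
#' @param level Significance level at which the quadratic term is kept;
#'   default 0.05.
#'
#' @return The selected `motion_fit`, with `p_value` filled in.
#' @export
#' @examples
#' trk <- simulate_brownian(D = 1e-3, n_frames = 300, seed = 1)
#' select_model(compute_msd(trk))$model
select_model <- function(msd, level = 0.05, weight_by_pairs = FALSE) {
  check_number(level, "level", lower = 0, allow_zero = FALSE)
  fb <- fit_brownian(msd, weight_by_pairs = weight_by_pairs)
  if (fb$degenerate || fb$n_lags < 4L) {
    return(fb)
  }
  # a numerically exact linear fit needs no quadratic term (parsimony)
  if (fb$rss <= .Machine$double.eps^0.5 * sum(msd$msd^2)) {
    return(fb)
  }
  ff <- fit_flow(msd, weight_by_pairs = weight_by_pairs)
  df2 <- ff$df_residual
  if (ff$rss <= 0) {
    # flow reproduces the curve exactly; keep it unless brownian does too
    if (fb$rss <= 0) return(fb)
    ff$p_value <- 0
    return(ff)
  }
  f_stat <- (fb$rss - ff$rss) / (ff$rss / df2)
  p <- pf(f_stat, 1, df2, lower.tail = FALSE)
  if (is.finite(p) && p < level) {
    ff$p_value <- p
    ff
  } else {
    fb$p_value <- p
    fb
  }
}

#' Fit motion models to every track of an ensemble
#'
#' Maps [select_model()] (or a forced single model) over the per-track MSD
#' curves and binds the per-track parameter estimates into one tibble.
#'
#' @param msd Per-track MSD table from [compute_msd()].
#' @param method `"select"` (default, F-test model selection),
#'   `"brownian"`, or `"flow"`.
#' @inheritParams select_model
#'
#' @return A tibble with one row per track: `track_id`, `model`, `D`
#'   (um^2/s), `v_um_min`, `epsilon` (um^2), `rss`, `p_value`, `n_lags`,
#'   `degenerate`.
#' @export
#' @examples
#' ens <- simulate_ensemble(motion_domain("brownian", 150, D = 1e-3),
#'                          n_tracks = 4, seed = 3)
#' fit_tracks(compute_msd(ens))
fit_tracks <- function(msd, method = c("select", "brownian", "flow"),
                       level = 0.05, weight_by_pairs = FALSE) {
  method <- match.arg(method)
  if (!"track_id" %in% names(msd)) {
    msd$track_id <- 1L
  }
  fit_fun <- switch(method,
    select = function(m) select_model(m, level = level,
                                      weight_by_pairs = weight_by_pairs),
    brownian = function(m) fit_brownian(m, weight_by_pairs = weight_by_pairs),
    flow = function(m) fit_flow(m, weight_by_pairs = weight_by_pairs)
  )
  msd |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) glance(fit_fun(df))) |>
    dplyr::ungroup()
}

#' @export
print.motion_fit <- function(x, ...) {
  cat(sprintf("<motion_fit: %s model, %d lags%s>\n", x$model, x$n_lags,
              if (x$degenerate) ", degenerate" else ""))
  cat(sprintf("  D       = %.4g um^2/s\n", x$D))
  if (x$model == "flow") cat(sprintf("  v       = %.4g um/min\n", x$v_um_min))
  cat(sprintf("  epsilon = %.4g um^2\n  rss     = %.4g\n", x$epsilon, x$rss))
  invisible(x)
}

#' Tidy a motion-model fit into one row per parameter
#'
#' @param x A `motion_fit` from [fit_brownian()], [fit_flow()] or
#'   [select_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @export
tidy.motion_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("D", "v", "epsilon"),
    estimate = c(x$D, x$v_um_min, x$epsilon),
    unit = c("um^2/s", "um/min", "um^2")
  )
  if (x$model == "brownian") out <- out[out$term != "v", ]
  out
}

#' One-row summary of a motion-model fit
#'
#' @inheritParams tidy.motion_fit
#' @return A one-row tibble with `model`, `D`, `v_um_min`, `epsilon`, `rss`,
#'   `p_value`, `n_lags`, `degenerate`.
#' @export
glance.motion_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, D = x$D, v_um_min = x$v_um_min, epsilon = x$epsilon,
    rss = x$rss, p_value = x$p_value, n_lags = x$n_lags,
    degenerate = x$degenerate
  )
}

#' Plot an MSD curve with its fitted motion model
#'
#' @param object A `motion_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed MSD points and the fitted curve.
#' @export
autoplot.motion_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$lag)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$msd)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#D55E00") +
    ggplot2::labs(
      x = "lag (s)", y = expression(MSD ~ (mu * m^2)),
      title = sprintf("%s model fit", object$model)
    ) +
    ggplot2::theme_minimal()
}
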