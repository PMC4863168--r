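#' Gyration tensor of a 2D trajectory
#'
#' The gyration tensor is the second moment of the visited positions about
#' their centroid, `T_ij = <x_i x_j> - <x_i><x_j>`, with the average taken
#' over the trajectory's frames (population normalization, 1/N). Its
#' eigenvalues describe the spatial extent of the track along its principal
#' axes and feed the asphericity shape statistic.
#'
#' @param points A data frame with columns `x`, `y` (um); a single track.
#' @return A `gyration_tensor` object: 2x2 `tensor` (um^2), `eigenvalues`
#'   sorted descending, number of frames `n`, and a `degenerate` flag (all
#'   points identical).
#' @seealso [asphericity()]
#' @export
#' @examples
#' gyration_tensor(data.frame(x = 1:10, y = 2 * (1:10)))
gyration_tensor <- function(points) {
  check_single_track(points)
  n <- nrow(points)
  if (n < 2L) {
    stop_too_short("a gyration tensor needs at least 2 points.")
  }
  x <- points$x
  y <- points$y
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_invalid("`points` contains non-finite coordinates.")
  }
  txx <- mean(x^2) - mean(x)^2
  tyy <- mean(y^2) - mean(y)^2
  txy <- mean(x * y) - mean(x) * mean(y)
  tensor <- matrix(c(txx, txy, txy, tyy), 2, 2,
                   dimnames = list(c("x", "y"), c("x", "y")))
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0) # clamp roundoff negatives; T is PSD by construction
  out <- list(
    tensor = tensor,
    eigenvalues = sort(ev, decreasing = TRUE),
    n = n,
    degenerate = sum(ev) <= 0
  )
  class(out) <- "gyration_tensor"
  out
}

#' @export
print.gyration_tensor <- function(x, ...) {
  cat(sprintf("<gyration_tensor: n = %d, lambda = (%.4g, %.4g)%s>\n",
              x$n, x$eigenvalues[1], x$eigenvalues[2],
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# Asphericity from eigenvalues, general d-dimensional form:
# sum over pairs of (lambda_i - lambda_j)^2, normalized by
# (d - 1) * (sum lambda)^2. In 2D this is ((l1 - l2) / (l1 + l2))^2.
alpha_from_eigenvalues <- function(lambda) {
  s <- sum(lambda)
  if (s <= 0) {
    return(0)
  }
  d <- length(lambda)
  pairs <- utils::combn(d, 2)
  num <- sum((lambda[pairs[1, ]] - lambda[pairs[2, ]])^2)
  num / ((d - 1) * s^2)
}

#' Asphericity of a single trajectory
#'
#' A dimensionless shape statistic in \[0, 1\] built from the gyration-tensor
#' eigenvalues: 0 for isotropic (strongly confined) motion, 1 for perfectly
#' directed motion along a line. It is invariant under translation, rotation
#' and uniform scaling of the track. A degenerate (single-point) track maps
#' to 0, the maximally "confined" limit, and is flagged via the
#' `"degenerate"` attribute so callers can exclude it.
#'
#' @param g A `gyration_tensor`, or a data frame of points (in which case the
#'   tensor is computed first).
#' @return A single number in \[0, 1\] with attribute `degenerate`.
#' @export
#' @examples
#' asphericity(data.frame(x = 1:10, y = 1:10))          # collinear -> 1
#' asphericity(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))) # square -> 0
asphericity <- function(g) {
  if (is.data.frame(g)) {
    g <- gyration_tensor(g)
  }
  if (!inherits(g, "gyration_tensor")) {
    stop_invalid("`g` must be a gyration_tensor or a data frame of points.")
  }
  a <- alpha_from_eigenvalues(g$eigenvalues)
  attr(a, "degenerate") <- g$degenerate
  a
}

#' Per-track asphericity over an ensemble
#'
#' @param tracks Track table (`track_id`, `frame`, `x`, `y`).
#' @return A tibble with one row per track: `track_id`, `n_frames`, `alpha`,
#'   `degenerate`.
#' @export
track_asphericity <- function(tracks) {
  ev <- track_eigenvalues(tracks)
  dplyr::transmute(
    ev,
    track_id = .data$track_id,
    n_frames = .data$n_frames,
    alpha = ifelse(.data$l1 + .data$l2 > 0,
                   ((.data$l1 - .data$l2) / (.data$l1 + .data$l2))^2, 0),
    degenerate = .data$l1 + .data$l2 <= 0
  )
}

# Gyration-tensor eigenvalues per track, vectorized through the closed form
# for a symmetric 2x2 matrix (no per-track eigen() calls).
track_eigenvalues <- function(tracks) {
  check_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      txx = mean(.data$x^2) - mean(.data$x)^2,
      tyy = mean(.data$y^2) - mean(.data$y)^2,
      txy = mean(.data$x * .data$y) - mean(.data$x) * mean(.data$y),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      disc = sqrt(((.data$txx - .data$tyy) / 2)^2 + .data$txy^2),
      l1 = pmax((.data$txx + .data$tyy) / 2 + .data$disc, 0),
      l2 = pmax((.data$txx + .data$tyy) / 2 - .data$disc, 0)
    ) |>
    dplyr::select("track_id", "n_frames", "l1", "l2")
}

#' Ensemble asphericity
#'
#' Two estimators are available. The default ratio-of-means estimator,
#' `mean((l1 - l2)^2) / mean((l1 + l2)^2)` over tracks, is the one whose
#' large-ensemble Brownian limit equals the closed form
#' `2 (d + 2) / (5 d + 4) = 4/7 ~= 0.571` in 2D; the mean-of-ratios
#' estimator averages the per-track asphericities instead (its Brownian
#' limit is lower, around 0.4, because the ratio is taken before averaging).
#'
#' @inheritParams track_asphericity
#' @param estimator `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' ens <- simulate_ensemble(motion_domain("brownian", 100, D = 1e-3),
#'                          n_tracks = 200, seed = 1)
#' ensemble_asphericity(ens)
ensemble_asphericity <- function(tracks,
                                 estimator = c("ratio_of_means",
                                               "mean_of_ratios")) {
  estimator <- match.arg(estimator)
  ev <- track_eigenvalues(tracks)
  if (estimator == "ratio_of_means") {
    denom <- mean((ev$l1 + ev$l2)^2)
    if (denom <= 0) {
      return(0)
    }
    mean((ev$l1 - ev$l2)^2) / denom
  } else {
    mean(purrr::map2_dbl(ev$l1, ev$l2,
                         ~ alpha_from_eigenvalues(c(.x, .y))))
  }
}

# Vectorized single-particle asphericities of n_sims pure Brownian walks of
# n_frames positions each. The statistic is scale invariant, so unit-variance
# increments are used. Assumes the caller seeded the RNG.
brownian_alpha_batch <- function(n_frames, n_sims) {
  ix <- matrix(rnorm((n_frames - 1) * n_sims), n_frames - 1, n_sims)
  iy <- matrix(rnorm((n_frames - 1) * n_sims), n_frames - 1, n_sims)
  X <- rbind(0, apply(ix, 2, cumsum))
  Y <- rbind(0, apply(iy, 2, cumsum))
  mx <- colMeans(X)
  my <- colMeans(Y)
  txx <- colMeans(X^2) - mx^2
  tyy <- colMeans(Y^2) - my^2
  txy <- colMeans(X * Y) - mx * my
  disc <- sqrt(((txx - tyy) / 2)^2 + txy^2)
  tr <- txx + tyy
  # alpha = ((l1 - l2)/(l1 + l2))^2 with l1,2 = tr/2 +- disc
  ifelse(tr > 0, (2 * disc / tr)^2, 0)
}

#' Monte-Carlo calibration of the Brownian asphericity tail probability
#'
#' Simulates ensembles of pure 2D Brownian walks at each requested track
#' length, records the empirical distribution of the single-particle
#' asphericity, and estimates the tail probability that a Brownian track
#' exceeds the asphericity threshold `alpha_thr`. That probability is the
#' false-positive rate of calling a Brownian stretch "directed" at that
#' threshold, which is what justifies the segmentation default of 0.8
#' (tail probability of a few percent across realistic track lengths).
#'
#' Distributions are stored as fixed-width histograms so the tail integral
#' reduces to a bin sum; `alpha_thr` should be a multiple of `bin_width`
#' for the stored histogram and the directly counted tail to agree exactly.
#'
#' @param track_lengths Integer vector of track lengths (frames, >= 3).
#' @param alpha_thr Asphericity threshold in \[0, 1\]; default 0.8.
#' @param n_sims Simulated tracks per length (>= 1000).
#' @param seed Integer seed; the calibration is deterministic given
#'   `track_lengths`, `n_sims` and `seed`.
#' @param bin_width Histogram bin width for the stored distributions.
#' @param chunk_size Tracks simulated per chunk, bounding peak memory so
#'   1e5-track calibrations stream rather than materialise.
#' @param keep_samples Keep the raw asphericity draws (memory permitting);
#'   useful for diagnostics.
#'
#' @return An `asphericity_calibration` object with `summary` (tibble:
#'   `length`, `tail_prob`, `n_sims`), `histograms` (tibble: `length`,
#'   `bin_lo`, `bin_hi`, `count`), and the calibration settings.
#' @export
#' @examples
#' cal <- calibrate_tail_probability(c(10, 50, 100), n_sims = 2000, seed = 1)
#' tidy(cal)
calibrate_tail_probability <- function(track_lengths, alpha_thr = 0.8,
                                       n_sims = 10000, seed = 1L,
                                       bin_width = 0.01,
                                       chunk_size = 20000L,
                                       keep_samples = FALSE) {
  if (length(track_lengths) < 1L || any(track_lengths < 3) ||
      any(track_lengths != round(track_lengths))) {
    stop_invalid("`track_lengths` must be whole numbers >= 3.")
  }
  check_number(alpha_thr, "alpha_thr", lower = 0)
  if (alpha_thr > 1) {
    stop_invalid("`alpha_thr` must lie in [0, 1].")
  }
  n_sims <- check_count(n_sims, "n_sims", lower = 1000L)
  check_number(bin_width, "bin_width", lower = 0, allow_zero = FALSE)
  chunk_size <- check_count(chunk_size, "chunk_size", lower = 1L)
  breaks <- seq(0, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-12) {
    breaks <- c(breaks, 1)
  }
  res <- with_local_seed(seed, purrr::map(seq_along(track_lengths), function(i) {
    len <- track_lengths[i]
    counts <- integer(length(breaks) - 1L)
    n_tail <- 0L
    done <- 0L
    alphas_all <- if (keep_samples) numeric(n_sims) else NULL
    while (done < n_sims) {
      m <- min(chunk_size, n_sims - done)
      a <- brownian_alpha_batch(len, m)
      n_tail <- n_tail + sum(a >= alpha_thr)
      idx <- findInterval(a, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
      counts <- counts + tabulate(idx, nbins = length(counts))
      if (keep_samples) alphas_all[(done + 1):(done + m)] <- a
      done <- done + m
    }
    list(
      summary = tibble::tibble(length = len, tail_prob = n_tail / n_sims,
                               n_sims = n_sims),
      hist = tibble::tibble(length = len,
                            bin_lo = breaks[-length(breaks)],
                            bin_hi = breaks[-1],
                            count = counts),
      samples = alphas_all
    )
  }))
  out <- list(
    summary = dplyr::bind_rows(purrr::map(res, "summary")),
    histograms = dplyr::bind_rows(purrr::map(res, "hist")),
    alpha_thr = alpha_thr,
    n_sims = n_sims,
    bin_width = bin_width,
    seed = seed
  )
  if (keep_samples) {
    out$samples <- setNames(purrr::map(res, "samples"),
                            as.character(track_lengths))
  }
  class(out) <- "asphericity_calibration"
  out
}

#' Tail probability at an arbitrary threshold from a stored calibration
#'
#' Evaluates `P(alpha_sp >= alpha_thr)` as a bin sum over the stored
#' histograms, one value per calibrated track length. Exact when
#' `alpha_thr` falls on a histogram bin edge; otherwise the enclosing bin is
#' included (a conservative, nonincreasing-in-threshold estimate).
#'
#' @param calibration An `asphericity_calibration`.
#' @param alpha_thr Threshold in \[0, 1\].
#' @return A tibble with columns `length`, `alpha_thr`, `tail_prob`.
#' @export
tail_probability <- function(calibration, alpha_thr) {
  if (!inherits(calibration, "asphericity_calibration")) {
    stop_invalid("`calibration` must be an asphericity_calibration.")
  }
  if (is.null(calibration$histograms)) {
    stop_invalid("this calibration carries no stored distributions.")
  }
  check_number(alpha_thr, "alpha_thr", lower = 0)
  if (alpha_thr > 1) {
    stop_invalid("`alpha_thr` must lie in [0, 1].")
  }
  calibration$histograms |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(
      alpha_thr = alpha_thr,
      tail_prob = sum(.data$count[.data$bin_hi > alpha_thr]) /
        sum(.data$count),
      .groups = "drop"
    )
}

#' @export
print.asphericity_calibration <- function(x, ...) {
  cat(sprintf(
    "<asphericity_calibration: alpha_thr = %g, %d lengths, %d sims each, seed %s>\n",
    x$alpha_thr, nrow(x$summary), x$n_sims, format(x$seed)
  ))
  cat(sprintf("  tail probability range: %.4f - %.4f\n",
              min(x$summary$tail_prob), max(x$summary$tail_prob)))
  invisible(x)
}

#' @describeIn calibrate_tail_probability Per-length tail probabilities as a
#'   tibble.
#' @param x An `asphericity_calibration`.
#' @param ... Unused.
#' @export
tidy.asphericity_calibration <- function(x, ...) {
  dplyr::mutate(x$summary, alpha_thr = x$alpha_thr)
}

#' @describeIn calibrate_tail_probability One-row summary (threshold, tail
#'   probability range, settings).
#' @export
glance.asphericity_calibration <- function(x, ...) {
  tibble::tibble(
    alpha_thr = x$alpha_thr,
    min_tail_prob = min(x$summary$tail_prob),
    max_tail_prob = max(x$summary$tail_prob),
    n_lengths = nrow(x$summary),
    n_sims = x$n_sims,
    seed = x$seed
  )
}

#' Plot a calibration: Brownian tail probability against track length
#'
#' @param object An `asphericity_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asphericity_calibration <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$length, y = 100 * .data$tail_prob)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "track length (frames)",
      y = sprintf("P(alpha >= %g) (%%)", object$alpha_thr),
      title = "Brownian asphericity tail probability"
    ) +
    ggplot2::theme_minimal()
}

#' Write / read an asphericity calibration summary as delimited text
#'
#' The summary table (length, tail probability, simulation count) plus the
#' calibration settings round-trip through a commented TSV, so a calibration
#' computed once can be reused by later segmentation runs. Stored
#' distributions are not serialized; recompute with `keep_samples` or keep
#' the object if you need them.
#'
#' @param calibration An `asphericity_calibration`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns an `asphericity_calibration` (without histograms).
#' @export
write_calibration <- function(calibration, path) {
  if (!inherits(calibration, "asphericity_calibration")) {
    stop_invalid("`calibration` must be an asphericity_calibration.")
  }
  meta <- c(
    sprintf("# alpha_thr: %.17g", calibration$alpha_thr),
    sprintf("# n_sims: %d", calibration$n_sims),
    sprintf("# bin_width: %.17g", calibration$bin_width),
    sprintf("# seed: %.17g", as.numeric(calibration$seed))
  )
  readr::write_lines(meta, path)
  readr::write_tsv(calibration$summary, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("file not found: %s", path))
  }
  meta_lines <- grep("^#", readr::read_lines(path), value = TRUE)
  meta_val <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta_lines, value = TRUE)
    if (length(ln) == 0L) {
      stop_invalid(sprintf("calibration file lacks `%s` metadata.", key))
    }
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln[1]))
  }
  summary <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  out <- list(
    summary = summary,
    histograms = NULL,
    alpha_thr = meta_val("alpha_thr"),
    n_sims = as.integer(meta_val("n_sims")),
    bin_width = meta_val("bin_width"),
    seed = meta_val("seed")
  )
  class(out) <- "asphericity_calibration"
  out
}
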