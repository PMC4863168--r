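#' Describe one motion domain of a synthetic trajectory
#'
#' A motion domain is a stretch of consecutive frames during which a particle
#' moves by a single mechanism: pure Brownian diffusion, or directed ("flow")
#' transport superposed on Brownian jitter. Stop-and-go transport along a
#' microtubule is modelled as an alternation of such domains.
#'
#' @param kind `"brownian"` or `"flow"`.
#' @param duration Number of frames the domain occupies (>= 1).
#' @param D Diffusion coefficient in um^2/s (>= 0). Flow domains keep their
#'   own diffusive jitter, so `D` applies to both kinds.
#' @param v Drift speed in um/min; used only when `kind = "flow"`.
#' @param heading Drift direction in radians; used only when `kind = "flow"`.
#'
#' @return A one-row tibble with columns `kind`, `duration`, `D`, `v`,
#'   `heading`. Rows from several calls can be stacked with
#'   [dplyr::bind_rows()] to describe a stop-and-go trajectory.
#' @seealso [simulate_stop_and_go()]
#' @export
#' @examples
#' dplyr::bind_rows(
#'   motion_domain("brownian", 60, D = 1e-3),
#'   motion_domain("flow", 30, D = 1e-3, v = 0.45, heading = pi / 4)
#' )
motion_domain <- function(kind = c("brownian", "flow"), duration, D = 0,
                          v = 0, heading = 0) {
  kind <- match.arg(kind)
  duration <- check_count(duration, "duration", lower = 1L)
  check_number(D, "D", lower = 0)
  check_number(heading, "heading")
  if (kind == "flow") {
    check_number(v, "v", lower = 0)
  } else {
    v <- 0
    heading <- 0
  }
  tibble::tibble(kind = kind, duration = duration, D = D, v = v,
                 heading = heading)
}

#' Simulate a pure Brownian trajectory
#'
#' Positions follow a 2D random walk whose per-axis increments are independent
#' Gaussian draws with variance `2 * D * dt`. Localization error is modelled
#' as independent Gaussian noise of standard deviation `noise_sd` added to the
#' *stored* positions only — it does not accumulate into the true path, which
#' is what makes the fitted MSD offset a constant.
#'
#' @param D Diffusion coefficient in um^2/s (>= 0).
#' @param n_frames Number of frames (>= 2). At the default 1 frame/s,
#'   120–300 frames cover a 2–5 minute acquisition.
#' @param dt Frame interval in seconds (> 0); default 1 s.
#' @param noise_sd Standard deviation of the localization error, um.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and repeated calls are bit-identical.
#' @param track_id Identifier stored in the `track_id` column.
#'
#' @return A tibble with columns `track_id`, `frame` (0-based), `x`, `y` (um)
#'   and `label` (ground-truth domain kind, here all `"brownian"`).
#' @export
#' @examples
#' trk <- simulate_brownian(D = 1e-3, n_frames = 300, seed = 1)
#' head(trk)
simulate_brownian <- function(D, n_frames, dt = 1, noise_sd = 0, seed = NULL,
                              track_id = 1L) {
  n_frames <- check_count(n_frames, "n_frames", lower = 2L)
  check_number(dt, "dt", lower = 0, allow_zero = FALSE)
  simulate_stop_and_go(
    motion_domain("brownian", duration = n_frames, D = D),
    dt = dt, noise_sd = noise_sd, seed = seed, track_id = track_id
  )
}

#' Simulate a stop-and-go trajectory from a table of motion domains
#'
#' Domains are concatenated in row order. Within a flow domain every step
#' gains a constant displacement `v * dt` along `heading` (with `v` converted
#' from um/min to um/s) on top of Brownian increments drawn with that domain's
#' `D`. The first frame of the track sits at the origin and carries the first
#' domain's label; every later frame is labelled by the domain that generated
#' the step into it.
#'
#' @param domains A tibble of motion domains, e.g. built with
#'   [motion_domain()] and [dplyr::bind_rows()].
#' @inheritParams simulate_brownian
#'
#' @return A tibble as in [simulate_brownian()], with one row per frame and
#'   `label` giving the ground-truth kind. `sum(domains$duration)` rows.
#' @export
#' @examples
#' dom <- dplyr::bind_rows(
#'   motion_domain("brownian", 50, D = 3.7e-4),
#'   motion_domain("flow", 40, D = 3.7e-4, v = 0.45, heading = 0),
#'   motion_domain("brownian", 50, D = 3.7e-4)
#' )
#' trk <- simulate_stop_and_go(dom, seed = 7)
#' table(trk$label)
simulate_stop_and_go <- function(domains, dt = 1, noise_sd = 0, seed = NULL,
                                 track_id = 1L) {
  if (!is.data.frame(domains) || nrow(domains) == 0L) {
    stop_invalid("`domains` must be a data frame with at least one row.")
  }
  needed <- c("kind", "duration")
  if (!all(needed %in% names(domains))) {
    stop_invalid("`domains` needs columns kind and duration (see motion_domain()).")
  }
  if (!all(domains$kind %in% c("brownian", "flow"))) {
    stop_invalid("domain `kind` must be \"brownian\" or \"flow\".")
  }
  if (any(domains$duration < 1) || any(domains$duration != round(domains$duration))) {
    stop_invalid("domain `duration` must be a positive whole number of frames.")
  }
  check_number(dt, "dt", lower = 0, allow_zero = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  for (col in c("D", "v", "heading")) {
    if (!col %in% names(domains)) domains[[col]] <- 0
  }
  if (any(domains$D < 0) || any(domains$v < 0)) {
    stop_invalid("domain `D` and `v` must be nonnegative.")
  }
  n_total <- sum(domains$duration)
  if (n_total < 2L) {
    stop_invalid("the track must span at least 2 frames in total.")
  }

  with_local_seed(seed, {
    dx <- numeric(0)
    dy <- numeric(0)
    labels <- domains$kind[1]
    for (j in seq_len(nrow(domains))) {
      # first domain contributes duration-1 steps (frame 0 is the origin)
      k <- domains$duration[j] - (j == 1L)
      if (k == 0L) next
      sd_step <- sqrt(2 * domains$D[j] * dt)
      step_x <- rnorm(k, 0, sd_step)
      step_y <- rnorm(k, 0, sd_step)
      if (domains$kind[j] == "flow") {
        v_um_s <- domains$v[j] / 60
        step_x <- step_x + v_um_s * dt * cos(domains$heading[j])
        step_y <- step_y + v_um_s * dt * sin(domains$heading[j])
      }
      dx <- c(dx, step_x)
      dy <- c(dy, step_y)
      labels <- c(labels, rep(domains$kind[j], k))
    }
    x <- cumsum(c(0, dx))
    y <- cumsum(c(0, dy))
    if (noise_sd > 0) {
      x <- x + rnorm(n_total, 0, noise_sd)
      y <- y + rnorm(n_total, 0, noise_sd)
    }
    tibble::tibble(
      track_id = track_id,
      frame = seq_len(n_total) - 1L,
      x = x, y = y,
      label = labels
    )
  })
}

#' Simulate an ensemble of independent trajectories
#'
#' Per-track seeds are derived deterministically from the master `seed`
#' (track i uses `seed + i`), so the same call reproduces the same ensemble
#' bit-for-bit and individual tracks can be regenerated in isolation.
#'
#' Large ensembles (e.g. 1e5 tracks for Monte-Carlo calibration) need not be
#' held in memory at once: pass `apply_fn` to reduce each track to a summary
#' as soon as it is generated, in which case only the list of summaries is
#' retained.
#'
#' @param domains Domain table applied to every track (see
#'   [simulate_stop_and_go()]), or a function `function(i, seed)` returning a
#'   domain table for track `i` when tracks should differ structurally.
#' @param n_tracks Number of tracks (>= 1).
#' @param seed Master seed (required, for reproducibility).
#' @param heading_shuffle When `TRUE`, all flow headings of each track are
#'   rotated by a single uniform random angle per track, mimicking transport
#'   along randomly oriented microtubules while keeping the heading constant
#'   within a track.
#' @param apply_fn Optional function applied to each track tibble; its
#'   results are returned as a list instead of the tracks themselves.
#' @inheritParams simulate_brownian
#'
#' @return One tibble of all tracks (track_id = 1..n_tracks), or the list of
#'   `apply_fn` results.
#' @export
#' @examples
#' ens <- simulate_ensemble(motion_domain("brownian", 120, D = 1e-3),
#'                          n_tracks = 5, seed = 42)
#' dplyr::count(ens, track_id)
simulate_ensemble <- function(domains, n_tracks, dt = 1, noise_sd = 0,
                              seed = 1L, heading_shuffle = FALSE,
                              apply_fn = NULL) {
  n_tracks <- check_count(n_tracks, "n_tracks", lower = 1L)
  check_number(seed, "seed")
  domain_fn <- if (is.function(domains)) {
    domains
  } else {
    function(i, seed) domains
  }
  one <- function(i) {
    seed_i <- seed + i
    dom <- domain_fn(i, seed_i)
    if (heading_shuffle && any(dom$kind == "flow")) {
      rot <- with_local_seed(seed_i * 2L + 1L, runif(1, 0, 2 * pi))
      dom$heading <- dom$heading + rot
    }
    trk <- simulate_stop_and_go(dom, dt = dt, noise_sd = noise_sd,
                                seed = seed_i, track_id = i)
    if (is.null(apply_fn)) trk else apply_fn(trk)
  }
  out <- purrr::map(seq_len(n_tracks), one)
  if (is.null(apply_fn)) dplyr::bind_rows(out) else out
}
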