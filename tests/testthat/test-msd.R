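test_that("MSD equals the naive pairwise double loop and honours the lag cap", {
  trk <- random_track(20, seed = 1)
  got <- compute_msd(trk, max_lag_fraction = 0.5)
  want <- naive_msd(trk$x, trk$y, max_steps = 10)
  expect_equal(got$lag, want$lag)
  expect_equal(got$msd, want$msd, tolerance = 1e-12)
  expect_equal(got$n_pairs, want$n_pairs)

  # stationary track
  still <- make_track(rep(2, 15), rep(-1, 15))
  expect_true(all(compute_msd(still, max_lag_fraction = 0.4)$msd == 0))

  # 300 frames at 1 frame/s -> admissible lags 1..30 s at the 10% cap
  long <- random_track(300, seed = 2)
  expect_equal(compute_msd(long)$lag, 1:30)

  err <- tryCatch(compute_msd(random_track(10, seed = 3)),
                  error = identity)
  expect_s3_class(err, "sptmotion_too_short")
  expect_match(conditionMessage(err), "11")
})

test_that("noiseless curves invert exactly and the models nest", {
  lag <- 1:20
  d_true <- 1e-3
  eps <- 0.01
  lin <- tibble::tibble(lag = lag, msd = 4 * d_true * lag + eps)
  fb <- fit_brownian(lin)
  expect_equal(fb$D, d_true, tolerance = 1e-9)
  expect_equal(fb$epsilon, eps, tolerance = 1e-9)

  v_s <- 0.45 / 60
  quad <- tibble::tibble(lag = lag,
                         msd = 4 * d_true * lag + (v_s * lag)^2 + eps)
  ff <- fit_flow(quad)
  expect_equal(ff$D, d_true, tolerance = 1e-6)
  expect_equal(ff$v_um_min, 0.45, tolerance = 1e-6)
  expect_equal(ff$epsilon, eps, tolerance = 1e-6)

  # v = 0 limit: the flow fit collapses onto the brownian fit
  f0 <- fit_flow(lin)
  expect_equal(f0$v_um_min, 0, tolerance = 1e-6)
  expect_equal(f0$D, fb$D, tolerance = 1e-6)

  # nesting: flow residual never exceeds brownian residual
  for (s in 1:10) {
    set.seed(s)
    curve <- tibble::tibble(lag = 1:15, msd = abs(rnorm(15, 0.05, 0.02)))
    expect_lte(fit_flow(curve)$rss, fit_brownian(curve)$rss + 1e-12)
  }

  # degenerate all-zero curve
  dg <- fit_brownian(tibble::tibble(lag = 1:5, msd = rep(0, 5)))
  expect_true(dg$degenerate)
  expect_equal(c(dg$D, dg$epsilon), c(0, 0))
  expect_error(fit_flow(tibble::tibble(lag = 1:2, msd = c(1, 2))),
               class = "sptmotion_too_short")
})

test_that("the MSD curve is invariant under isometries of the track", {
  trk <- random_track(40, seed = 4)
  ref <- compute_msd(trk, max_lag_fraction = 0.25)
  for (s in 1:5) {
    set.seed(s)
    moved <- rotate_track(trk, runif(1, 0, 2 * pi),
                          dx = rnorm(1, 0, 10), dy = rnorm(1, 0, 10))
    expect_equal(compute_msd(moved, max_lag_fraction = 0.25)$msd, ref$msd,
                 tolerance = 1e-10)
  }
})

test_that("ensemble MSD equals brute-force pooling of pairs across tracks", {
  t1 <- random_track(20, seed = 5, id = 1L)
  t2 <- random_track(16, seed = 6, id = 2L)
  both <- dplyr::bind_rows(t1, t2)
  got <- ensemble_msd(compute_msd(both, max_lag_fraction = 0.25))

  o1 <- naive_msd(t1$x, t1$y, 5)
  o2 <- naive_msd(t2$x, t2$y, 4)
  pooled <- sapply(1:5, function(k) {
    v1 <- o1$msd[k] * o1$n_pairs[k]
    v2 <- if (k <= 4) o2$msd[k] * o2$n_pairs[k] else 0
    n2 <- if (k <= 4) o2$n_pairs[k] else 0
    (v1 + v2) / (o1$n_pairs[k] + n2)
  })
  expect_equal(got$msd, pooled, tolerance = 1e-12)

  # single track and duplicated track are fixed points
  single <- compute_msd(t1, max_lag_fraction = 0.25)
  expect_equal(ensemble_msd(single)$msd, single$msd)
  dup <- dplyr::bind_rows(t1, dplyr::mutate(t1, track_id = 2L))
  expect_equal(ensemble_msd(compute_msd(dup, max_lag_fraction = 0.25))$msd,
               single$msd, tolerance = 1e-12)

  mixed <- dplyr::bind_rows(
    tibble::tibble(track_id = 1, lag = c(1, 2), msd = c(1, 2), n_pairs = c(5L, 4L)),
    tibble::tibble(track_id = 2, lag = c(1.5, 3), msd = c(1, 2), n_pairs = c(5L, 4L))
  )
  expect_error(ensemble_msd(mixed), class = "sptmotion_invalid_argument")
})

test_that("model selection distinguishes the motion modes", {
  lag <- 1:25
  lin <- tibble::tibble(lag = lag, msd = 4e-3 * lag + 0.01)
  expect_equal(select_model(lin)$model, "brownian")
  quad <- tibble::tibble(lag = lag, msd = 4e-3 * lag + (0.05 * lag)^2 + 0.01)
  expect_equal(select_model(quad)$model, "flow")

  # transport-scale simulation: the majority of each class is recovered; the
  # Brownian side is the weaker one because neighbouring MSD lags are highly
  # correlated, which is exactly why segmentation adds the asphericity gate
  ens_b <- simulate_ensemble(motion_domain("brownian", 300, D = 1e-3),
                             n_tracks = 200, seed = 21, noise_sd = 0.02)
  ens_f <- simulate_ensemble(
    motion_domain("flow", 300, D = 1e-3, v = 0.45, heading = 0.9),
    n_tracks = 200, seed = 22, noise_sd = 0.02
  )
  sel_b <- fit_tracks(compute_msd(ens_b), method = "select")
  sel_f <- fit_tracks(compute_msd(ens_f), method = "select")
  expect_gt(mean(sel_b$model == "brownian"), 0.5)
  expect_gt(mean(sel_f$model == "flow"), 0.5)
})

test_that("tidiers expose the fit parameters in reporting units", {
  quad <- tibble::tibble(lag = 1:10, msd = 4e-3 * (1:10) + (0.02 * (1:10))^2)
  ff <- fit_flow(quad)
  td <- tidy(ff)
  expect_equal(td$term, c("D", "v", "epsilon"))
  expect_equal(td$unit, c("um^2/s", "um/min", "um^2"))
  gl <- glance(ff)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$v_um_min, ff$v_um_min)

  tb <- tidy(fit_brownian(tibble::tibble(lag = 1:5, msd = 1:5)))
  expect_false("v" %in% tb$term)

  p <- autoplot(ff)
  expect_s3_class(p, "ggplot")
})
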