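test_that("gyration tensor matches the naive covariance loop and its analytic cases", {
  trk <- random_track(10, seed = 1)
  g <- gyration_tensor(trk)
  expect_equal(unname(g$tensor), naive_gyration(trk$x, trk$y),
               tolerance = 1e-12)
  expect_true(all(diff(g$eigenvalues) <= 0))
  expect_true(all(g$eigenvalues >= 0))

  # straight line: second eigenvalue exactly zero
  lin <- collinear_track(12, angle = 0.3)
  expect_equal(gyration_tensor(lin)$eigenvalues[2], 0, tolerance = 1e-12)

  # square vertices: isotropic, equal eigenvalues
  sq <- gyration_tensor(square_track())
  expect_equal(sq$eigenvalues[1], sq$eigenvalues[2], tolerance = 1e-12)

  # all points identical: zero tensor, flagged degenerate
  still <- gyration_tensor(make_track(rep(1, 5), rep(2, 5)))
  expect_true(still$degenerate)
  expect_equal(still$eigenvalues, c(0, 0))
  expect_error(gyration_tensor(make_track(1, 1)),
               class = "sptmotion_too_short")
})

test_that("asphericity hits its directed and confined limits and is isometry/scale invariant", {
  expect_equal(as.numeric(asphericity(collinear_track(10, angle = 1.2))), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(asphericity(square_track())), 0, tolerance = 1e-12)

  still <- asphericity(make_track(rep(0, 4), rep(0, 4)))
  expect_equal(as.numeric(still), 0)
  expect_true(attr(still, "degenerate"))

  for (s in 1:8) {
    trk <- random_track(25, seed = s)
    a <- as.numeric(asphericity(trk))
    expect_gte(a, 0)
    expect_lte(a, 1)
    set.seed(s + 100)
    moved <- rotate_track(trk, runif(1, 0, 2 * pi), rnorm(1), rnorm(1))
    expect_equal(as.numeric(asphericity(moved)), a, tolerance = 1e-9)
    scaled <- dplyr::mutate(trk, x = 7.3 * x, y = 7.3 * y)
    expect_equal(as.numeric(asphericity(scaled)), a, tolerance = 1e-9)
  }

  # per-track table agrees with the single-track eigen path
  ens <- simulate_ensemble(motion_domain("brownian", 30, D = 1e-3),
                           n_tracks = 6, seed = 9)
  tbl <- track_asphericity(ens)
  direct <- vapply(split(ens, ens$track_id), function(df) {
    as.numeric(asphericity(df[c("x", "y")]))
  }, numeric(1))
  expect_equal(tbl$alpha, unname(direct), tolerance = 1e-10)
})

test_that("ensemble asphericity reaches the directed limit and the Brownian 4/7 value", {
  one_line <- collinear_track(20)
  expect_equal(ensemble_asphericity(one_line), 1, tolerance = 1e-12)

  drift <- simulate_ensemble(
    motion_domain("flow", 50, D = 0, v = 2, heading = 0.8),
    n_tracks = 20, seed = 3
  )
  expect_gt(ensemble_asphericity(drift), 0.999)

  ens <- simulate_ensemble(motion_domain("brownian", 100, D = 1e-3),
                           n_tracks = 2000, seed = 17)
  expect_equal(ensemble_asphericity(ens), 4 / 7, tolerance = 0.05)
  # the per-track average sits well below the ratio-of-means value
  expect_lt(ensemble_asphericity(ens, estimator = "mean_of_ratios"), 0.5)
})

test_that("calibration tail probabilities match direct counting and behave monotonically", {
  cal <- calibrate_tail_probability(c(10, 40), alpha_thr = 0.8,
                                    n_sims = 1000, seed = 5,
                                    keep_samples = TRUE)
  for (len in c("10", "40")) {
    a <- cal$samples[[len]]
    expect_length(a, 1000)
    expect_true(all(a >= 0 & a <= 1))
    # counting oracle: stored tail equals direct counting of the draws
    expect_equal(
      cal$summary$tail_prob[cal$summary$length == as.numeric(len)],
      mean(a >= 0.8)
    )
    # histogram bin sum reproduces the same tail (0.8 is a bin edge)
    hist_tail <- sum(cal$histograms$count[
      cal$histograms$length == as.numeric(len) & cal$histograms$bin_lo >= 0.8
    ]) / 1000
    expect_equal(
      cal$summary$tail_prob[cal$summary$length == as.numeric(len)],
      hist_tail
    )
  }

  # a zero threshold is always exceeded
  cal0 <- calibrate_tail_probability(c(10, 25), alpha_thr = 0,
                                     n_sims = 1000, seed = 5)
  expect_true(all(cal0$summary$tail_prob == 1))

  # tail probability nonincreasing in the threshold
  tp <- vapply(seq(0, 1, by = 0.1), function(thr) {
    tail_probability(cal, thr)$tail_prob[1]
  }, numeric(1))
  expect_true(all(diff(tp) <= 0))

  # determinism and chunking equivalence
  again <- calibrate_tail_probability(c(10, 40), alpha_thr = 0.8,
                                      n_sims = 1000, seed = 5)
  expect_equal(again$summary, cal$summary)
  chunked <- calibrate_tail_probability(c(10, 40), alpha_thr = 0.8,
                                        n_sims = 1000, seed = 5,
                                        chunk_size = 128L)
  expect_equal(chunked$summary$n_sims, cal$summary$n_sims)

  expect_error(calibrate_tail_probability(10, alpha_thr = 1.2, n_sims = 1000),
               class = "sptmotion_invalid_argument")
  expect_error(calibrate_tail_probability(2, n_sims = 1000),
               class = "sptmotion_invalid_argument")
})

test_that("the vectorized calibration agrees with the per-track simulation route", {
  len <- 50
  cal <- calibrate_tail_probability(len, alpha_thr = 0.8, n_sims = 2000,
                                    seed = 31)
  ens <- simulate_ensemble(motion_domain("brownian", len, D = 1e-3),
                           n_tracks = 600, seed = 32)
  rate <- mean(track_asphericity(ens)$alpha >= 0.8)
  # binomial 3-sigma agreement between the two independent routes
  p <- cal$summary$tail_prob
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / 600) + 3 * sqrt(p * (1 - p) / 2000))
})

test_that("calibration summaries serialize and round-trip through text", {
  cal <- calibrate_tail_probability(c(12, 60), alpha_thr = 0.8,
                                    n_sims = 1000, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$summary$length, cal$summary$length)
  expect_equal(back$summary$tail_prob, cal$summary$tail_prob)
  expect_equal(back$alpha_thr, cal$alpha_thr)
  expect_equal(back$n_sims, cal$n_sims)
  expect_equal(back$seed, cal$seed)

  expect_equal(nrow(tidy(cal)), 2L)
  expect_equal(glance(cal)$n_sims, 1000L)
  expect_s3_class(autoplot(cal), "ggplot")
})
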