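test_that("segments tile the track and carry brute-force mean speeds", {
  trk <- random_track(9, seed = 1)
  seg <- partition_segments(trk, m = 3)
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$n_frames, rep(3L, 3))
  expect_equal(seg$frame_start, c(0L, 3L, 6L))

  # remainder frames are appended to the last segment
  seg10 <- partition_segments(random_track(10, seed = 2), m = 3)
  expect_equal(nrow(seg10), 3L)
  expect_equal(seg10$n_frames, c(3L, 3L, 4L))
  expect_equal(sum(seg10$n_frames), 10L)

  # pure drift: every segment speed equals the drift vector exactly
  v <- 6 # um/min
  h <- 0.7
  drift <- simulate_stop_and_go(
    motion_domain("flow", 12, D = 0, v = v, heading = h), seed = 1
  )
  segd <- partition_segments(drift, m = 3)
  expect_equal(segd$v_x, rep(v / 60 * cos(h), 4), tolerance = 1e-12)
  expect_equal(segd$v_y, rep(v / 60 * sin(h), 4), tolerance = 1e-12)

  # oracle: mean of within-span finite differences over dt
  trk2 <- random_track(12, seed = 3)
  seg2 <- partition_segments(trk2, m = 4, dt = 0.5)
  for (i in seq_len(nrow(seg2))) {
    span <- which(trk2$frame >= seg2$frame_start[i] &
                    trk2$frame <= seg2$frame_end[i])
    expect_equal(seg2$v_x[i], mean(diff(trk2$x[span])) / 0.5,
                 tolerance = 1e-12)
    expect_equal(seg2$v_y[i], mean(diff(trk2$y[span])) / 0.5,
                 tolerance = 1e-12)
  }

  expect_error(partition_segments(random_track(5, seed = 4), m = 3),
               class = "sptmotion_too_short")
})

test_that("speed thresholds are the configured fraction of the ensemble mean", {
  segs <- tibble::tibble(
    track_id = 1, segment = 1:12,
    v_x = rep(c(0.3, -0.3), 6), v_y = rep(-0.12, 12)
  )
  thr <- derive_thresholds(segs)
  expect_equal(thr$v_x_thr, 0.7 * 0.3)
  expect_equal(thr$v_y_thr, 0.7 * 0.12)

  set.seed(5)
  rnd <- tibble::tibble(track_id = 1, segment = 1:40,
                        v_x = rnorm(40), v_y = rnorm(40))
  thr2 <- derive_thresholds(rnd, factor = 0.5)
  expect_equal(thr2$v_x_thr, 0.5 * mean(abs(rnd$v_x)), tolerance = 1e-12)
  expect_equal(thr2$v_y_thr, 0.5 * mean(abs(rnd$v_y)), tolerance = 1e-12)

  expect_error(derive_thresholds(segs[1:5, ]),
               class = "sptmotion_invalid_argument")
})

test_that("sequence grouping reproduces a linear run scan under both axis rules", {
  set.seed(6)
  segs <- tibble::tibble(track_id = rep(1:2, each = 20),
                         segment = rep(1:20, 2),
                         v_x = rnorm(40, 0, 0.02), v_y = rnorm(40, 0, 0.02))
  thr <- tibble::tibble(v_x_thr = 0.015, v_y_thr = 0.02)
  for (rule in c("or", "and")) {
    got <- group_sequences(segs, thr, rule = rule)
    above <- if (rule == "or") {
      abs(segs$v_x) >= 0.015 | abs(segs$v_y) >= 0.02
    } else {
      abs(segs$v_x) >= 0.015 & abs(segs$v_y) >= 0.02
    }
    expect_equal(got$above, above)
    for (id in 1:2) {
      sub <- got[got$track_id == id, ]
      # oracle: a new run starts at every status change
      want <- cumsum(c(TRUE, diff(sub$above) != 0))
      expect_equal(sub$sequence_id, want)
    }
  }

  # all below -> one run; alternating -> runs of length one
  low <- tibble::tibble(track_id = 1, segment = 1:10,
                        v_x = rep(0.001, 10), v_y = rep(0.001, 10))
  expect_equal(unique(group_sequences(low, thr)$sequence_id), 1)
  alt <- tibble::tibble(track_id = 1, segment = 1:10,
                        v_x = rep(c(0.1, 0.001), 5), v_y = 0.001)
  expect_equal(group_sequences(alt, thr)$sequence_id, 1:10)
})

test_that("classification labels pure drift as one flow domain and respects the thresholds", {
  drift <- simulate_stop_and_go(
    motion_domain("flow", 30, D = 0, v = 6, heading = 0.7), seed = 1
  )
  quiet <- simulate_brownian(D = 1e-4, n_frames = 30, seed = 2, track_id = 2L)
  ens <- dplyr::bind_rows(drift, quiet)
  seg <- segment_tracks(ens)
  dom1 <- dplyr::filter(attr(seg, "domains"), track_id == 1)
  expect_equal(nrow(dom1), 1L)
  expect_equal(dom1$kind, "flow")
  expect_equal(dom1$n_frames, 30L)
  expect_equal(dom1$alpha_L, 1, tolerance = 1e-9)

  # impossible asphericity threshold: everything is diffusion
  seg_hi <- segment_tracks(ens, alpha_thr = 1)
  expect_true(all(seg_hi$label == "diffusion"))

  # zero thresholds and zero alpha_thr: every >= 2-segment run becomes flow
  thr0 <- tibble::tibble(v_x_thr = 0, v_y_thr = 0, factor = 0,
                         stat = "mean_abs", n_segments = 20L)
  seg_lo <- segment_tracks(ens, alpha_thr = 0, thresholds = thr0)
  expect_true(all(seg_lo$label == "flow"))
})

test_that("segmented output tiles every frame, bans short flow domains, and is deterministic and scale-equivariant", {
  dom <- dplyr::bind_rows(
    motion_domain("brownian", 45, D = 3.7e-4),
    motion_domain("flow", 45, D = 3.7e-4, v = 2, heading = 0.4),
    motion_domain("brownian", 30, D = 3.7e-4)
  )
  ens <- simulate_ensemble(dom, n_tracks = 12, seed = 8, noise_sd = 0.02)
  m <- 3
  seg <- segment_tracks(ens, m = m)

  # tiling: exactly the input frames, each labelled once
  expect_equal(nrow(seg), nrow(ens))
  expect_equal(
    dplyr::arrange(seg[c("track_id", "frame")], track_id, frame),
    dplyr::arrange(ens[c("track_id", "frame")], track_id, frame),
    ignore_attr = TRUE
  )
  expect_true(all(seg$label %in% c("diffusion", "flow")))

  # no flow domain shorter than 2 m frames
  doms <- attr(seg, "domains")
  expect_true(all(doms$n_frames[doms$kind == "flow"] >= 2 * m))

  # determinism
  seg2 <- segment_tracks(ens, m = m)
  expect_equal(tibble::as_tibble(seg), tibble::as_tibble(seg2))

  # scale equivariance: scaling positions scales thresholds, not labels
  scaled <- dplyr::mutate(ens, x = 10 * x, y = 10 * y)
  seg_sc <- segment_tracks(scaled, m = m)
  expect_equal(seg_sc$label, seg$label)
  thr <- attr(seg, "thresholds")
  thr_sc <- attr(seg_sc, "thresholds")
  expect_equal(thr_sc$v_x_thr, 10 * thr$v_x_thr, tolerance = 1e-9)
})

test_that("ground-truth agreement reaches the level recorded by the parameter sweep", {
  sweep <- readr::read_tsv(test_path("fixtures", "segmentation-sweep.tsv"),
                           comment = "#", show_col_types = FALSE)
  run_agreement <- function(v, seed) {
    dom <- dplyr::bind_rows(
      motion_domain("brownian", 60, D = 3.7e-4),
      motion_domain("flow", 60, D = 3.7e-4, v = v, heading = 0.4),
      motion_domain("brownian", 60, D = 3.7e-4)
    )
    ens <- simulate_ensemble(dom, n_tracks = 20, seed = seed,
                             noise_sd = 0.02, heading_shuffle = TRUE)
    seg <- segment_tracks(ens)
    mean(seg$label ==
           ifelse(seg$label_true == "flow", "flow", "diffusion"))
  }
  bar <- min(sweep$agreement[sweep$v_um_min == 0.45])
  expect_gte(run_agreement(0.45, seed = 1), bar)
  # detection strengthens with drift speed
  expect_gte(run_agreement(4, seed = 1),
             max(sweep$agreement[sweep$v_um_min == 0.45]))
})

test_that("population fractions match brute-force frame counting in both schemes", {
  # all-diffusion ensemble
  alldiff <- tibble::tibble(track_id = rep(1:3, each = 10),
                            frame = rep(0:9, 3), label = "diffusion")
  pf <- population_fractions(alldiff)
  expect_equal(pf$fraction[pf$scheme == "time" & pf$label == "diffusion"], 1)
  expect_equal(pf$fraction[pf$scheme == "tracks" & pf$label == "flow"], 0)

  set.seed(9)
  mixed <- tibble::tibble(
    track_id = rep(1:5, each = 20), frame = rep(0:19, 5),
    label = sample(c("diffusion", "flow"), 100, replace = TRUE,
                   prob = c(0.7, 0.3))
  )
  pf2 <- population_fractions(mixed)
  # time scheme: direct frame counting
  expect_equal(
    pf2$fraction[pf2$scheme == "time" & pf2$label == "flow"],
    sum(mixed$label == "flow") / nrow(mixed)
  )
  # track scheme: dominant label per track, counted by hand
  dom_by_hand <- sapply(split(mixed$label, mixed$track_id), function(l) {
    if (sum(l == "flow") > length(l) / 2) "flow" else "diffusion"
  })
  expect_equal(
    pf2$fraction[pf2$scheme == "tracks" & pf2$label == "flow"],
    mean(dom_by_hand == "flow")
  )
  # fractions sum to one within each scheme
  sums <- tapply(pf2$fraction, pf2$scheme, sum)
  expect_equal(as.vector(sums), c(1, 1))

  # per-condition grouping
  mixed$condition <- rep(c("A", "B"), length.out = nrow(mixed))
  pfc <- population_fractions(mixed)
  expect_setequal(unique(pfc$condition), c("A", "B"))
})
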