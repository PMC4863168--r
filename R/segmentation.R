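#' Partition tracks into fixed-length segments with mean speed components
#'
#' Each track is cut into consecutive, non-overlapping segments of `m`
#' frames; a terminal remainder shorter than `m` is appended to the last
#' segment so that segments tile every frame. Within a segment the speed
#' components are the mean of the per-frame finite differences divided by
#' the frame interval (for a pure drift track this recovers the drift
#' velocity exactly); the per-frame maxima of the absolute components are
#' recorded too, for the alternative thresholding statistic.
#'
#' @param tracks Track table (`track_id`, `frame`, `x`, `y`), positions in
#'   um. Every track must have at least `2 * m` frames (the minimum that can
#'   host one candidate flow sequence of two segments).
#' @param m Segment length in frames; default 3.
#' @param dt Frame interval in seconds.
#'
#' @return A tibble with one row per segment: `track_id`, `segment`,
#'   `frame_start`, `frame_end`, `n_frames`, `v_x`, `v_y`, `v_x_max`,
#'   `v_y_max` (um/s).
#' @export
#' @examples
#' trk <- simulate_brownian(D = 1e-3, n_frames = 30, seed = 1)
#' partition_segments(trk)
partition_segments <- function(tracks, m = 3, dt = 1) {
  check_tracks(tracks)
  m <- check_count(m, "m", lower = 2L)
  check_number(dt, "dt", lower = 0, allow_zero = FALSE)
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 2L * m) {
        stop_too_short(sprintf(
          "track %s has %d frames; segmentation with m = %d needs at least %d.",
          format(key$track_id), n, m, 2L * m
        ))
      }
      n_seg <- floor(n / m)
      seg <- pmin(ceiling(seq_len(n) / m), n_seg)
      vx <- diff(df$x) / dt
      vy <- diff(df$y) / dt
      # displacement i -> i+1 belongs to the segment of frame i+1 when that
      # step stays inside one segment; steps crossing a boundary belong to
      # neither (speeds are "within each segment").
      purrr::map_dfr(seq_len(n_seg), function(s) {
        idx <- which(seg == s)
        steps <- idx[-length(idx)] # step i connects position i and i+1
        tibble::tibble(
          segment = s,
          frame_start = df$frame[idx[1]],
          frame_end = df$frame[idx[length(idx)]],
          n_frames = length(idx),
          v_x = mean(vx[steps]),
          v_y = mean(vy[steps]),
          v_x_max = max(abs(vx[steps])),
          v_y_max = max(abs(vy[steps]))
        )
      })
    }) |>
    dplyr::ungroup()
}

#' Ensemble speed thresholds for flow detection
#'
#' Thresholds are an ensemble property: the per-axis threshold is a fixed
#' fraction (default 70%) of the average of the ensemble distribution of
#' segment speed magnitudes. Two readings of "distribution average" are
#' offered: the mean of the per-segment `|v_x|`, `|v_y|` (default), or the
#' mean of the per-segment maxima of the per-frame absolute components.
#'
#' @param segments Segment table from [partition_segments()], pooled over
#'   all tracks of the ensemble to be analysed (>= 10 segments).
#' @param factor Fraction of the distribution average used as threshold;
#'   default 0.70.
#' @param stat `"mean_abs"` (default) or `"mean_max"`.
#'
#' @return A one-row tibble: `v_x_thr`, `v_y_thr` (um/s), `factor`, `stat`,
#'   `n_segments`.
#' @export
derive_thresholds <- function(segments, factor = 0.70,
                              stat = c("mean_abs", "mean_max")) {
  stat <- match.arg(stat)
  check_number(factor, "factor", lower = 0)
  if (!is.data.frame(segments) ||
      !all(c("v_x", "v_y") %in% names(segments))) {
    stop_invalid("`segments` must come from partition_segments().")
  }
  if (nrow(segments) < 10L) {
    stop_invalid(sprintf(
      "threshold derivation needs at least 10 segments; got %d.",
      nrow(segments)
    ))
  }
  if (stat == "mean_abs") {
    vx <- mean(abs(segments$v_x))
    vy <- mean(abs(segments$v_y))
  } else {
    if (!all(c("v_x_max", "v_y_max") %in% names(segments))) {
      stop_invalid("stat = \"mean_max\" needs v_x_max / v_y_max columns.")
    }
    vx <- mean(segments$v_x_max)
    vy <- mean(segments$v_y_max)
  }
  tibble::tibble(
    v_x_thr = factor * vx, v_y_thr = factor * vy,
    factor = factor, stat = stat, n_segments = nrow(segments)
  )
}

#' Group consecutive segments into above/below-threshold sequences
#'
#' Marks each segment as above threshold and collapses maximal runs of
#' equal status into candidate sequences. A segment is above threshold when
#' `|v_x| >= v_x_thr` *or* `|v_y| >= v_y_thr` by default, so a drift aligned
#' with a single axis is not missed; `rule = "and"` requires both.
#'
#' @param segments Per-track segment table from [partition_segments()].
#' @param thresholds One-row threshold table from [derive_thresholds()] (or
#'   any data frame with `v_x_thr`, `v_y_thr`).
#' @param rule `"or"` (default) or `"and"`.
#'
#' @return `segments` with added columns `above` (logical) and
#'   `sequence_id` (run index within each track).
#' @export
group_sequences <- function(segments, thresholds, rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (!is.data.frame(thresholds) ||
      !all(c("v_x_thr", "v_y_thr") %in% names(thresholds))) {
    stop_invalid("`thresholds` must come from derive_thresholds().")
  }
  if (any(c(thresholds$v_x_thr, thresholds$v_y_thr) < 0)) {
    stop_invalid("thresholds must be nonnegative.")
  }
  above_x <- abs(segments$v_x) >= thresholds$v_x_thr[1]
  above_y <- abs(segments$v_y) >= thresholds$v_y_thr[1]
  segments$above <- if (rule == "or") above_x | above_y else above_x & above_y
  segments |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      r <- rle(df$above)
      df$sequence_id <- rep(seq_along(r$lengths), r$lengths)
      df
    }) |>
    dplyr::ungroup()
}

#' Classify sequences into diffusion and flow-motion domains
#'
#' A sequence of two or more consecutive above-threshold segments becomes a
#' flow-motion domain when its local asphericity `alpha_L` — computed on the
#' positions the sequence spans — exceeds `alpha_thr`; every other frame is
#' labelled diffusion. Isolated single above-threshold segments are absorbed
#' into the surrounding diffusion, and adjacent same-label domains are
#' merged, with each final domain's `alpha_L` recorded over its merged span.
#' Sequences with a degenerate (zero) gyration tensor are labelled
#' diffusion.
#'
#' @param sequences Output of [group_sequences()].
#' @param tracks The track table the segments came from. An existing `label`
#'   column (e.g. simulation ground truth) is preserved as `label_true`.
#' @param alpha_thr Local-asphericity threshold; default 0.8, a value at
#'   which a pure Brownian stretch is misclassified as flow only a few
#'   percent of the time (see [calibrate_tail_probability()]).
#'
#' @return An `spt_segmented` tibble with one row per frame: `track_id`,
#'   `frame`, `x`, `y`, `label` ("diffusion"/"flow"), `domain_id`,
#'   `alpha_L`. Attributes: `domains` (per-domain summary tibble),
#'   `thresholds`, `alpha_thr`.
#' @export
classify_domains <- function(sequences, tracks, alpha_thr = 0.8) {
  check_tracks(tracks)
  check_number(alpha_thr, "alpha_thr", lower = 0)
  if (!all(c("above", "sequence_id") %in% names(sequences))) {
    stop_invalid("`sequences` must come from group_sequences().")
  }
  thresholds <- sequences |>
    dplyr::distinct(dplyr::across(dplyr::any_of(c("v_x_thr", "v_y_thr"))))
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  if ("label" %in% names(tracks)) {
    tracks <- dplyr::rename(tracks, label_true = "label")
  }
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      seqs <- sequences[sequences$track_id == key$track_id, , drop = FALSE]
      if (nrow(seqs) == 0L) {
        stop_invalid(sprintf("no segments found for track %s.",
                             format(key$track_id)))
      }
      lab <- rep("diffusion", nrow(df))
      for (sid in unique(seqs$sequence_id)) {
        run <- seqs[seqs$sequence_id == sid, , drop = FALSE]
        if (!run$above[1] || nrow(run) < 2L) next
        idx <- which(df$frame >= min(run$frame_start) &
                       df$frame <= max(run$frame_end))
        a <- asphericity(df[idx, c("x", "y")])
        if (!attr(a, "degenerate") && as.numeric(a) > alpha_thr) {
          lab[idx] <- "flow"
        }
      }
      # merge adjacent same-label stretches into domains and record alpha_L
      r <- rle(lab)
      dom_id <- rep(seq_along(r$lengths), r$lengths)
      alpha_l <- numeric(nrow(df))
      for (d in seq_along(r$lengths)) {
        idx <- which(dom_id == d)
        alpha_l[idx] <- if (length(idx) >= 2L) {
          as.numeric(asphericity(df[idx, c("x", "y")]))
        } else {
          0
        }
      }
      df$label <- lab
      df$domain_id <- dom_id
      df$alpha_L <- alpha_l
      df
    }) |>
    dplyr::ungroup()
  domains <- out |>
    dplyr::group_by(.data$track_id, .data$domain_id) |>
    dplyr::summarise(
      kind = .data$label[1],
      frame_start = min(.data$frame),
      frame_end = max(.data$frame),
      n_frames = dplyr::n(),
      alpha_L = .data$alpha_L[1],
      .groups = "drop"
    )
  attr(out, "domains") <- domains
  attr(out, "thresholds") <- thresholds
  attr(out, "alpha_thr") <- alpha_thr
  class(out) <- c("spt_segmented", class(out))
  out
}

#' Segment tracks into diffusion and flow-motion domains
#'
#' End-to-end wrapper for the rule-based local analysis: (i) partition each
#' trajectory into `m`-frame segments, (ii) average the speed components
#' over each segment, (iii) derive ensemble speed thresholds as a fraction
#' of the mean absolute segment speeds and group consecutive segments into
#' above/below-threshold sequences, (iv) classify each above-threshold
#' sequence of two or more segments as a flow-motion domain when its local
#' asphericity exceeds `alpha_thr`. Classification of a single track
#' therefore depends on the ensemble it is analysed with; the thresholds
#' used are attached to the output for provenance.
#'
#' @inheritParams partition_segments
#' @inheritParams derive_thresholds
#' @inheritParams group_sequences
#' @inheritParams classify_domains
#' @param thresholds Optional precomputed thresholds (from
#'   [derive_thresholds()]); when supplied, `factor`/`stat` are ignored and
#'   the ensemble-threshold step is skipped.
#'
#' @return See [classify_domains()].
#' @export
#' @examples
#' dom <- dplyr::bind_rows(
#'   motion_domain("brownian", 60, D = 3.7e-4),
#'   motion_domain("flow", 60, D = 3.7e-4, v = 0.45, heading = 0.4)
#' )
#' ens <- simulate_ensemble(dom, n_tracks = 10, seed = 2)
#' seg <- segment_tracks(ens)
#' population_fractions(seg)
segment_tracks <- function(tracks, m = 3, dt = 1, factor = 0.70,
                           alpha_thr = 0.8, rule = c("or", "and"),
                           stat = c("mean_abs", "mean_max"),
                           thresholds = NULL) {
  segments <- partition_segments(tracks, m = m, dt = dt)
  if (is.null(thresholds)) {
    thresholds <- derive_thresholds(segments, factor = factor,
                                    stat = match.arg(stat))
  }
  segments <- dplyr::mutate(segments,
                            v_x_thr = thresholds$v_x_thr[1],
                            v_y_thr = thresholds$v_y_thr[1])
  seqs <- group_sequences(segments, thresholds, rule = match.arg(rule))
  classify_domains(seqs, tracks, alpha_thr = alpha_thr)
}

#' Diffusion / flow population fractions over an ensemble
#'
#' Reports, per condition when a `condition` column is present, two
#' weighting schemes side by side: the fraction of total tracked time spent
#' in each motion kind (`scheme = "time"`), and the fraction of tracks whose
#' dominant-by-time kind is each kind (`scheme = "tracks"`, ties resolved to
#' diffusion by parsimony). Within each scheme the fractions sum to 1.
#'
#' @param segmented An `spt_segmented` table from [segment_tracks()] /
#'   [classify_domains()] (any data frame with `track_id`, `frame`, `label`
#'   works).
#' @return A tibble with columns (`condition`,) `scheme`, `label`,
#'   `fraction`, `n` (frames for the time scheme, tracks for the track
#'   scheme).
#' @export
population_fractions <- function(segmented) {
  if (!is.data.frame(segmented) ||
      !all(c("track_id", "label") %in% names(segmented))) {
    stop_invalid("`segmented` must have columns track_id and label.")
  }
  if (nrow(segmented) == 0L) {
    stop_invalid("`segmented` has no rows.")
  }
  has_cond <- "condition" %in% names(segmented)
  grp <- if (has_cond) c("condition") else character(0)
  kinds <- c("diffusion", "flow")
  one_condition <- function(df) {
    time_tbl <- tibble::tibble(
      scheme = "time",
      label = kinds,
      fraction = vapply(kinds, function(k) mean(df$label == k), numeric(1),
                        USE.NAMES = FALSE),
      n = vapply(kinds, function(k) sum(df$label == k), numeric(1),
                 USE.NAMES = FALSE)
    )
    dominant <- df |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(
        dom = if (mean(.data$label == "flow") > 0.5) "flow" else "diffusion",
        .groups = "drop"
      )
    track_tbl <- tibble::tibble(
      scheme = "tracks",
      label = kinds,
      fraction = vapply(kinds, function(k) mean(dominant$dom == k),
                        numeric(1), USE.NAMES = FALSE),
      n = vapply(kinds, function(k) sum(dominant$dom == k), numeric(1),
                 USE.NAMES = FALSE)
    )
    dplyr::bind_rows(time_tbl, track_tbl)
  }
  if (has_cond) {
    segmented |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(function(df, key) one_condition(df)) |>
      dplyr::ungroup()
  } else {
    one_condition(segmented)
  }
}
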