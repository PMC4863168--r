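#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the field-standard defaults:
#' 1 s frame interval, MSD lags capped at 10% of the track time, 3-frame
#' segments, speed thresholds at 70% of the ensemble mean absolute segment
#' speeds, and a local-asphericity threshold of 0.8.
#'
#' @param frame_interval Frame interval, s (> 0).
#' @param max_lag_fraction MSD lag cap as a fraction of track time.
#' @param m Segment length, frames.
#' @param speed_factor Fraction of the ensemble speed average used as
#'   threshold.
#' @param alpha_thr Local-asphericity threshold for flow domains.
#' @param threshold_rule `"or"` or `"and"` axis combination.
#' @param threshold_stat `"mean_abs"` or `"mean_max"`.
#' @param selection_level F-test level for MSD model selection.
#' @param weight_by_pairs Weight MSD fits by pair counts.
#' @param calibration_lengths Track lengths for the Brownian calibration.
#' @param calibration_n_sims Simulated tracks per calibration length.
#' @param seed Master seed for every stochastic stage.
#' @param xy_unit,time_unit Unit declarations recorded in outputs.
#'
#' @return An `spt_config` list that serializes losslessly through
#'   [write_config()] / [read_config()].
#' @export
analysis_config <- function(frame_interval = 1,
                            max_lag_fraction = 0.1,
                            m = 3,
                            speed_factor = 0.70,
                            alpha_thr = 0.8,
                            threshold_rule = "or",
                            threshold_stat = "mean_abs",
                            selection_level = 0.05,
                            weight_by_pairs = FALSE,
                            calibration_lengths = c(10, 30, 100, 300),
                            calibration_n_sims = 10000,
                            seed = 1,
                            xy_unit = "um",
                            time_unit = "s") {
  check_number(frame_interval, "frame_interval", lower = 0, allow_zero = FALSE)
  check_number(max_lag_fraction, "max_lag_fraction", lower = 0,
               allow_zero = FALSE)
  if (max_lag_fraction > 1) {
    stop_invalid("`max_lag_fraction` must lie in (0, 1].")
  }
  check_count(m, "m", lower = 2L)
  check_number(speed_factor, "speed_factor", lower = 0)
  check_number(alpha_thr, "alpha_thr", lower = 0)
  if (alpha_thr > 1) stop_invalid("`alpha_thr` must lie in [0, 1].")
  if (!threshold_rule %in% c("or", "and")) {
    stop_invalid("`threshold_rule` must be \"or\" or \"and\".")
  }
  if (!threshold_stat %in% c("mean_abs", "mean_max")) {
    stop_invalid("`threshold_stat` must be \"mean_abs\" or \"mean_max\".")
  }
  check_number(selection_level, "selection_level", lower = 0,
               allow_zero = FALSE)
  check_count(calibration_n_sims, "calibration_n_sims", lower = 1000L)
  check_number(seed, "seed")
  cfg <- list(
    frame_interval = frame_interval,
    max_lag_fraction = max_lag_fraction,
    m = as.integer(m),
    speed_factor = speed_factor,
    alpha_thr = alpha_thr,
    threshold_rule = threshold_rule,
    threshold_stat = threshold_stat,
    selection_level = selection_level,
    weight_by_pairs = isTRUE(weight_by_pairs),
    calibration_lengths = as.integer(calibration_lengths),
    calibration_n_sims = as.integer(calibration_n_sims),
    seed = as.numeric(seed),
    xy_unit = xy_unit,
    time_unit = time_unit
  )
  class(cfg) <- "spt_config"
  cfg
}

#' @export
print.spt_config <- function(x, ...) {
  cat("<spt_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Write / read an analysis configuration (YAML)
#'
#' @param config An `spt_config` from [analysis_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `spt_config`. The round trip is lossless.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "spt_config")) {
    stop_invalid("`config` must come from analysis_config().")
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("file not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Declare a simulated input condition for the pipeline
#'
#' @param domains Domain table (see [motion_domain()]) applied to every
#'   track.
#' @param n_tracks Number of tracks to simulate.
#' @param noise_sd Localization error, um.
#' @param heading_shuffle Randomize each track's flow heading (one rotation
#'   per track).
#' @return An `spt_sim_spec` understood by [run_pipeline()].
#' @export
simulation_spec <- function(domains, n_tracks, noise_sd = 0.02,
                            heading_shuffle = TRUE) {
  n_tracks <- check_count(n_tracks, "n_tracks", lower = 1L)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(domains = domains, n_tracks = n_tracks, noise_sd = noise_sd,
         heading_shuffle = isTRUE(heading_shuffle)),
    class = "spt_sim_spec"
  )
}

#' Run the full tracking-analysis pipeline
#'
#' Chains ingest/simulate, per-track MSD, motion-model fitting with model
#' selection, Brownian asphericity calibration (computed once and shared
#' across conditions), trajectory segmentation and population-fraction
#' summary. Two runs with identical config and inputs produce identical
#' outputs, including the files written to `output_dir`.
#'
#' @param input One condition or a named list of conditions; each condition
#'   is a track table, a path readable by [read_tracks()], or a
#'   [simulation_spec()].
#' @param config An [analysis_config()].
#' @param output_dir Optional directory; when given, every stage's table is
#'   written there as commented delimited text stamped with the config hash
#'   and master seed.
#' @param calibration Optional precomputed [calibrate_tail_probability()]
#'   result to reuse.
#'
#' @return An `spt_report` list: `tracks`, `msd`, `fits`, `segmented`,
#'   `fractions` (tibbles, each with a `condition` column), `calibration`,
#'   `config`, `config_hash`, `log`.
#' @export
#' @examples
#' \donttest{
#' lfn_like <- simulation_spec(
#'   motion_domain("brownian", 150, D = 1e-3), n_tracks = 20
#' )
#' rep <- run_pipeline(list(LFN = lfn_like),
#'                     config = analysis_config(calibration_n_sims = 1000,
#'                                              calibration_lengths = c(30, 150)))
#' rep$fractions
#' }
run_pipeline <- function(input, config = analysis_config(),
                         output_dir = NULL, calibration = NULL) {
  if (!inherits(config, "spt_config")) {
    stop_invalid("`config` must come from analysis_config().")
  }
  conditions <- if (is.data.frame(input) || !is.list(input) ||
                      inherits(input, "spt_sim_spec")) {
    list(all = input)
  } else {
    input
  }
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    names(conditions) <- paste0("condition_", seq_along(conditions))
  }
  hash <- config_hash(config)
  log <- list()
  note <- function(stage, condition, msg) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, condition = condition, message = msg
    )
  }

  ingest_one <- function(obj, cond, idx) {
    tr <- if (inherits(obj, "spt_sim_spec")) {
      simulate_ensemble(obj$domains, n_tracks = obj$n_tracks,
                        dt = config$frame_interval, noise_sd = obj$noise_sd,
                        seed = config$seed + 10000 * idx,
                        heading_shuffle = obj$heading_shuffle)
    } else if (is.character(obj)) {
      tryCatch(read_tracks(obj), error = function(e) {
        abort(sprintf("stage ingest (%s): %s", cond, conditionMessage(e)),
              parent = e)
      })
    } else if (is.data.frame(obj)) {
      check_tracks(obj)
      obj
    } else {
      stop_invalid(sprintf(
        "condition `%s` must be a track table, a path or a simulation_spec.",
        cond
      ))
    }
    note("ingest", cond,
         sprintf("%d tracks, %d frames", length(unique(tr$track_id)),
                 nrow(tr)))
    tr
  }

  stage <- function(name, cond, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s (%s): %s", name, cond, conditionMessage(e)),
            parent = e)
    })
  }

  tracks <- purrr::imap(conditions,
                        function(obj, cond) {
                          idx <- match(cond, names(conditions))
                          ingest_one(obj, cond, idx)
                        })

  if (is.null(calibration)) {
    calibration <- calibrate_tail_probability(
      config$calibration_lengths, alpha_thr = config$alpha_thr,
      n_sims = config$calibration_n_sims, seed = config$seed
    )
    note("calibrate", "*", sprintf(
      "tail probability %.3f-%.3f at alpha_thr = %g",
      min(calibration$summary$tail_prob),
      max(calibration$summary$tail_prob), config$alpha_thr
    ))
  } else {
    note("calibrate", "*", "reused supplied calibration")
  }

  per_cond <- purrr::imap(tracks, function(tr, cond) {
    msd <- stage("msd", cond, compute_msd(
      tr, dt = config$frame_interval,
      max_lag_fraction = config$max_lag_fraction
    ))
    fits <- stage("fit", cond, fit_tracks(
      msd, method = "select", level = config$selection_level,
      weight_by_pairs = config$weight_by_pairs
    ))
    note("fit", cond, sprintf(
      "%d brownian / %d flow by model selection",
      sum(fits$model == "brownian"), sum(fits$model == "flow")
    ))
    seg <- stage("segment", cond, segment_tracks(
      tr, m = config$m, dt = config$frame_interval,
      factor = config$speed_factor, alpha_thr = config$alpha_thr,
      rule = config$threshold_rule, stat = config$threshold_stat
    ))
    note("segment", cond, sprintf(
      "%d domain(s), %.1f%% of time flow-labelled",
      nrow(attr(seg, "domains")), 100 * mean(seg$label == "flow")
    ))
    list(
      msd = dplyr::mutate(msd, condition = cond, .before = 1),
      fits = dplyr::mutate(fits, condition = cond, .before = 1),
      segmented = dplyr::mutate(tibble::as_tibble(seg), condition = cond,
                                .before = 1)
    )
  })

  segmented <- dplyr::bind_rows(purrr::map(per_cond, "segmented"))
  fractions <- population_fractions(segmented)
  note("summarise", "*", sprintf("%d condition(s)", length(conditions)))

  report <- list(
    tracks = dplyr::bind_rows(purrr::imap(
      tracks, function(tr, cond) dplyr::mutate(tr, condition = cond,
                                               .before = 1)
    )),
    msd = dplyr::bind_rows(purrr::map(per_cond, "msd")),
    fits = dplyr::bind_rows(purrr::map(per_cond, "fits")),
    segmented = segmented,
    fractions = fractions,
    calibration = calibration,
    config = config,
    config_hash = hash,
    log = dplyr::bind_rows(log)
  )
  class(report) <- "spt_report"
  if (!is.null(output_dir)) {
    write_report(report, output_dir)
  }
  report
}

#' @export
print.spt_report <- function(x, ...) {
  cat(sprintf("<spt_report: %d track(s), %d condition(s), config %s>\n",
              length(unique(x$tracks$track_id)),
              length(unique(x$tracks$condition)), x$config_hash))
  print(x$fractions)
  invisible(x)
}

#' Write every table of a pipeline report to a directory
#'
#' Each file is delimited text with `#` header comments embedding the config
#' hash and master seed, so a report directory is self-describing and
#' byte-reproducible for a fixed seed.
#'
#' @param report An `spt_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "spt_report")) {
    stop_invalid("`report` must come from run_pipeline().")
  }
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  stamp <- c(
    sprintf("config_hash: %s", report$config_hash),
    sprintf("seed: %.15g", report$config$seed),
    sprintf("units: %s, %s", report$config$xy_unit, report$config$time_unit)
  )
  write_tbl <- function(tbl, name) {
    p <- file.path(dir, name)
    readr::write_lines(paste0("# ", c("sptmotion report table", stamp)), p)
    readr::write_csv(tbl, p, append = TRUE, col_names = TRUE)
  }
  write_tbl(report$tracks, "tracks.csv")
  write_tbl(report$msd, "msd.csv")
  write_tbl(report$fits, "fits.csv")
  write_tbl(tibble::as_tibble(report$segmented), "segmented.csv")
  write_tbl(report$fractions, "fractions.csv")
  write_calibration(report$calibration, file.path(dir, "calibration.tsv"))
  write_config(report$config, file.path(dir, "config.yaml"))
  write_tbl(report$log, "log.csv")
  invisible(dir)
}
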