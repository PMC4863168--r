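# Internal helpers: argument checking, seeding, track-table validation.

stop_invalid <- function(msg) {
  abort(msg, class = "sptmotion_invalid_argument")
}

stop_too_short <- function(msg) {
  abort(msg, class = c("sptmotion_too_short", "sptmotion_invalid_argument"))
}

check_number <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || (!allow_zero && x == lower)) {
    stop_invalid(sprintf(
      "`%s` must be %s %s.", name,
      if (allow_zero) ">=" else ">", format(lower)
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop_invalid(sprintf("`%s` must be a single whole number.", name))
  }
  if (x < lower) {
    stop_invalid(sprintf("`%s` must be >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the ambient stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  check_number(seed, "seed")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# A track table holds one row per (track, frame) with positions in micrometres.
check_tracks <- function(tracks, name = "tracks") {
  if (!is.data.frame(tracks)) {
    stop_invalid(sprintf("`%s` must be a data frame.", name))
  }
  needed <- c("track_id", "frame", "x", "y")
  missing <- setdiff(needed, names(tracks))
  if (length(missing) > 0L) {
    stop_invalid(sprintf(
      "`%s` is missing required column(s): %s.", name,
      paste(missing, collapse = ", ")
    ))
  }
  if (nrow(tracks) == 0L) {
    stop_invalid(sprintf("`%s` has no rows.", name))
  }
  if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y))) {
    stop_invalid(sprintf("`%s` contains non-finite coordinates.", name))
  }
  invisible(tracks)
}

check_single_track <- function(tracks, name = "points") {
  check_tracks2 <- is.data.frame(tracks) && all(c("x", "y") %in% names(tracks))
  if (!check_tracks2) {
    stop_invalid(sprintf("`%s` must be a data frame with columns x and y.", name))
  }
  if ("track_id" %in% names(tracks) && length(unique(tracks$track_id)) > 1L) {
    stop_invalid(sprintf(
      "`%s` holds %d tracks; this function expects a single track.",
      name, length(unique(tracks$track_id))
    ))
  }
  invisible(tracks)
}
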