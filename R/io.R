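#' Read particle trajectories from delimited text
#'
#' Two dialects are supported: `"plain"` — columns `track_id`, `frame`,
#' `x_um`/`x`, `y_um`/`y` and optionally `label`, with `#` comment lines
#' (the format [write_tracks()] emits) — and `"trackmate"` — a TrackMate
#' spot export with columns `TRACK_ID`, `FRAME`, `POSITION_X`,
#' `POSITION_Y`, tolerating the extra non-numeric header rows newer
#' TrackMate versions insert. `"auto"` picks by header.
#'
#' Frames must be unique within a track; duplicated (track, frame) pairs are
#' a parse error reported with their row numbers. Tracks whose frames are
#' not contiguous are handled per `gap_policy`: `"split"` (default) cuts the
#' track at every gap into independently analysable pieces (suffixing the
#' id), `"bridge"` fills single-frame gaps by linear interpolation and
#' splits at longer ones, `"keep"` leaves gaps in place with a warning.
#'
#' @param path Path to a delimited text file (comma or tab separated).
#' @param dialect `"auto"`, `"plain"` or `"trackmate"`.
#' @param gap_policy `"split"`, `"bridge"` or `"keep"`.
#' @param scale_xy Factor applied to coordinates to convert them to um
#'   (e.g. the pixel size when the export is in pixels). Default 1.
#'
#' @return A tibble with columns `track_id` (character), `frame` (integer),
#'   `x`, `y` (um) and `label` when present, ordered by track and frame.
#'   Attribute `gaps`: a tibble describing every gap found.
#' @export
read_tracks <- function(path, dialect = c("auto", "plain", "trackmate"),
                        gap_policy = c("split", "bridge", "keep"),
                        scale_xy = 1) {
  dialect <- match.arg(dialect)
  gap_policy <- match.arg(gap_policy)
  check_number(scale_xy, "scale_xy", lower = 0, allow_zero = FALSE)
  if (!file.exists(path)) {
    stop_invalid(sprintf("file not found: %s", path))
  }
  raw <- readr::read_delim(
    path, delim = guess_delim(path), comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
  if (nrow(raw) == 0L) {
    warn(sprintf("no track rows in %s; returning an empty track table.",
                 path))
    return(empty_tracks())
  }
  if (dialect == "auto") {
    dialect <- if ("TRACK_ID" %in% names(raw)) "trackmate" else "plain"
  }
  cols <- if (dialect == "trackmate") {
    c(track_id = "TRACK_ID", frame = "FRAME",
      x = "POSITION_X", y = "POSITION_Y")
  } else {
    c(track_id = "track_id", frame = "frame",
      x = pick_col(raw, c("x_um", "x")), y = pick_col(raw, c("y_um", "y")))
  }
  missing <- cols[!cols %in% names(raw)]
  if (length(missing) > 0L) {
    stop_invalid(sprintf(
      "%s: missing required column(s): %s.", path,
      paste(missing, collapse = ", ")
    ))
  }
  tr <- tibble::tibble(
    track_id = raw[[cols[["track_id"]]]],
    frame = suppressWarnings(as.numeric(raw[[cols[["frame"]]]])),
    x = suppressWarnings(as.numeric(raw[[cols[["x"]]]])),
    y = suppressWarnings(as.numeric(raw[[cols[["y"]]]])),
    row = seq_len(nrow(raw))
  )
  if ("label" %in% names(raw)) tr$label <- raw$label
  # TrackMate v7+ puts 3 descriptive rows under the header; drop non-numeric
  non_num <- !is.finite(tr$frame) | !is.finite(tr$x) | !is.finite(tr$y)
  if (dialect == "trackmate") {
    tr <- tr[!non_num, , drop = FALSE]
    if (nrow(tr) == 0L) {
      warn(sprintf("no numeric track rows in %s.", path))
      return(empty_tracks())
    }
  } else if (any(non_num)) {
    stop_invalid(sprintf(
      "%s: non-numeric frame/x/y at row(s) %s.", path,
      paste(head(tr$row[non_num], 5L), collapse = ", ")
    ))
  }
  if (any(tr$frame != round(tr$frame))) {
    stop_invalid(sprintf("%s: frame numbers must be whole numbers.", path))
  }
  tr$frame <- as.integer(tr$frame)
  tr$x <- tr$x * scale_xy
  tr$y <- tr$y * scale_xy
  dup <- duplicated(tr[c("track_id", "frame")])
  if (any(dup)) {
    stop_invalid(sprintf(
      "%s: duplicate (track_id, frame) pair(s) at row(s) %s.", path,
      paste(head(tr$row[dup], 5L), collapse = ", ")
    ))
  }
  tr <- dplyr::arrange(tr, .data$track_id, .data$frame)
  apply_gap_policy(dplyr::select(tr, -"row"), gap_policy)
}

guess_delim <- function(path) {
  first <- readr::read_lines(path, n_max = 20)
  first <- first[!grepl("^#", first)]
  if (length(first) == 0L) {
    return(",")
  }
  if (sum(grepl("\t", first)) >= sum(grepl(",", first))) "\t" else ","
}

pick_col <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit) == 0L) candidates[1] else hit[1]
}

empty_tracks <- function() {
  out <- tibble::tibble(track_id = character(), frame = integer(),
                        x = numeric(), y = numeric())
  attr(out, "gaps") <- tibble::tibble(track_id = character(),
                                      after_frame = integer(),
                                      gap_frames = integer())
  out
}

apply_gap_policy <- function(tr, gap_policy) {
  pieces <- tr |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_split()
  gaps <- list()
  out <- purrr::map(pieces, function(df) {
    id <- df$track_id[1]
    jump <- diff(df$frame)
    gap_at <- which(jump > 1L)
    if (length(gap_at) > 0L) {
      gaps[[length(gaps) + 1L]] <<- tibble::tibble(
        track_id = id,
        after_frame = df$frame[gap_at],
        gap_frames = jump[gap_at] - 1L
      )
    }
    if (length(gap_at) == 0L || gap_policy == "keep") {
      return(df)
    }
    if (gap_policy == "bridge") {
      bridged <- list(df)
      one_frame <- gap_at[jump[gap_at] == 2L]
      if (length(one_frame) > 0L) {
        fill <- df[one_frame, ]
        fill$frame <- fill$frame + 1L
        fill$x <- (df$x[one_frame] + df$x[one_frame + 1L]) / 2
        fill$y <- (df$y[one_frame] + df$y[one_frame + 1L]) / 2
        bridged <- c(bridged, list(fill))
      }
      df <- dplyr::arrange(dplyr::bind_rows(bridged), .data$frame)
      jump <- diff(df$frame)
      gap_at <- which(jump > 1L)
      if (length(gap_at) == 0L) {
        return(df)
      }
    }
    # split at remaining gaps
    piece_id <- cumsum(c(0L, as.integer(jump > 1L)))
    df$track_id <- paste0(df$track_id, "_s", piece_id + 1L)
    df
  })
  gaps_tbl <- if (length(gaps) > 0L) {
    dplyr::bind_rows(gaps)
  } else {
    tibble::tibble(track_id = character(), after_frame = integer(),
                   gap_frames = integer())
  }
  if (nrow(gaps_tbl) > 0L) {
    warn(sprintf("%d gap(s) found in %d track(s); gap policy: %s.",
                 sum(gaps_tbl$gap_frames), length(unique(gaps_tbl$track_id)),
                 gap_policy))
  }
  out <- dplyr::bind_rows(out)
  attr(out, "gaps") <- gaps_tbl
  out
}

#' Write a track table as commented delimited text
#'
#' Coordinates are written as `x_um`, `y_um`; `label` and any extra columns
#' are preserved. Lines starting with `#` carry provenance (extra comments
#' can be supplied) and are skipped by [read_tracks()].
#'
#' @param tracks Track table (`track_id`, `frame`, `x`, `y`, ...).
#' @param path Output file path.
#' @param comments Character vector of extra header comment lines (written
#'   verbatim after a leading `# `).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, comments = character()) {
  check_tracks(tracks)
  out <- dplyr::rename(tracks, x_um = "x", y_um = "y")
  header <- c("# sptmotion track table (positions in um, frames 0-based)",
              paste0("# ", comments))
  readr::write_lines(header[nzchar(sub("^# ", "", header))], path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
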