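#' Manders M1 overlap coefficient (pixel-based colocalization)
#'
#' Fraction of above-threshold red-channel intensity that falls inside the
#' green-channel mask: `M1 = colocalized red / total red`. With red the
#' DNA channel and green an endosome or lysosome marker, M1 answers "what
#' fraction of the DNA signal sits in marker-positive structures".
#'
#' @param red Numeric matrix of red-channel intensities.
#' @param green_mask Logical (or 0/1) matrix of the same shape marking
#'   green-positive pixels.
#' @param red_threshold Intensity threshold; red pixels with intensity
#'   strictly above it contribute. Default 0. See [costes_threshold()] for
#'   an automatic choice.
#'
#' @return A one-row tibble: `m1` (NA when there is no above-threshold red
#'   signal), `red_total`, `red_in_mask` (summed intensities), `n_red_pixels`,
#'   `n_coloc_pixels`, `red_threshold`.
#' @export
#' @examples
#' red <- matrix(runif(64), 8, 8)
#' mask <- matrix(rep(c(TRUE, FALSE), each = 32), 8, 8)
#' manders_m1(red, mask)
manders_m1 <- function(red, green_mask, red_threshold = 0) {
  if (!is.matrix(red) || !is.numeric(red)) {
    stop_invalid("`red` must be a numeric matrix.")
  }
  if (!is.matrix(green_mask) || !all(dim(green_mask) == dim(red))) {
    stop_invalid("`green_mask` must be a matrix with the same shape as `red`.")
  }
  check_number(red_threshold, "red_threshold", lower = 0)
  mask <- green_mask > 0
  sel <- red > red_threshold
  red_total <- sum(red[sel])
  red_in <- sum(red[sel & mask])
  tibble::tibble(
    m1 = if (red_total > 0) red_in / red_total else NA_real_,
    red_total = red_total,
    red_in_mask = red_in,
    n_red_pixels = sum(sel),
    n_coloc_pixels = sum(sel & mask),
    red_threshold = red_threshold
  )
}

#' Automatic intensity threshold in the style of Costes
#'
#' Regresses green on red over all pixels, then walks the candidate red
#' threshold downward until the below-threshold pixels show no positive
#' red-green correlation. The returned value can be passed to
#' [manders_m1()]; with clean masks a fixed user threshold is often
#' preferable and remains the default there.
#'
#' @param red,green Numeric matrices of the same shape.
#' @param n_steps Number of candidate thresholds spanning the red range.
#' @return A single threshold value on the red intensity scale.
#' @export
costes_threshold <- function(red, green, n_steps = 100) {
  if (!is.matrix(red) || !is.matrix(green) ||
      !all(dim(red) == dim(green))) {
    stop_invalid("`red` and `green` must be numeric matrices of equal shape.")
  }
  n_steps <- check_count(n_steps, "n_steps", lower = 2L)
  r <- as.vector(red)
  g <- as.vector(green)
  cand <- seq(max(r), min(r), length.out = n_steps)
  for (t in cand) {
    below <- r < t
    if (sum(below) < 3L || stats::sd(r[below]) == 0 ||
        stats::sd(g[below]) == 0) {
      next
    }
    if (stats::cor(r[below], g[below]) <= 0) {
      return(t)
    }
  }
  min(r)
}

#' Object-based colocalization of two spot sets
#'
#' A red spot counts as colocalized when its centroid lies within
#' `max_dist` of any green centroid. The default 0.5 um is a
#' diffraction-scale spot radius; it is a convention, not a measured value,
#' and should be tuned to the imaging system.
#'
#' @param red,green Data frames of spot centroids with columns `x`, `y`
#'   (um).
#' @param max_dist Distance cutoff in um (> 0).
#'
#' @return A one-row tibble: `percent` (0-100, NA when `red` is empty),
#'   `n_colocalized`, `n_total`, `max_dist`.
#' @export
#' @examples
#' red <- data.frame(x = c(0, 5, 10), y = c(0, 0, 0))
#' green <- data.frame(x = c(0.1, 20), y = c(0, 0))
#' object_colocalization(red, green, max_dist = 0.5)
object_colocalization <- function(red, green, max_dist = 0.5) {
  check_number(max_dist, "max_dist", lower = 0, allow_zero = FALSE)
  for (nm in c("red", "green")) {
    s <- get(nm)
    if (!is.data.frame(s) || !all(c("x", "y") %in% names(s))) {
      stop_invalid(sprintf("`%s` must be a data frame with columns x and y.",
                           nm))
    }
  }
  n_red <- nrow(red)
  if (n_red == 0L) {
    return(tibble::tibble(percent = NA_real_, n_colocalized = 0L,
                          n_total = 0L, max_dist = max_dist))
  }
  n_col <- if (nrow(green) == 0L) {
    0L
  } else {
    d2 <- outer(red$x, green$x, "-")^2 + outer(red$y, green$y, "-")^2
    sum(apply(d2, 1, min) <= max_dist^2)
  }
  tibble::tibble(
    percent = 100 * n_col / n_red,
    n_colocalized = as.integer(n_col),
    n_total = n_red,
    max_dist = max_dist
  )
}

#' Aggregate per-image colocalization results
#'
#' Mean and standard deviation of a colocalization statistic over images or
#' cells, the usual way such measurements are reported.
#'
#' @param results A tibble of per-image results (rows from [manders_m1()] or
#'   [object_colocalization()] bound together, optionally with grouping
#'   columns such as `condition`).
#' @param statistic Column to aggregate, `"percent"` or `"m1"`.
#' @return A tibble with `mean`, `sd` and `n_images` (per group when
#'   grouping columns are present and `results` is grouped).
#' @export
summarise_colocalization <- function(results,
                                     statistic = c("percent", "m1")) {
  statistic <- match.arg(statistic)
  if (!statistic %in% names(results)) {
    stop_invalid(sprintf("`results` has no `%s` column.", statistic))
  }
  dplyr::summarise(
    results,
    mean = mean(.data[[statistic]], na.rm = TRUE),
    sd = stats::sd(.data[[statistic]], na.rm = TRUE),
    n_images = sum(!is.na(.data[[statistic]])),
    .groups = "drop"
  )
}
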