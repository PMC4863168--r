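#' Plot trajectories, coloured by motion label when available
#'
#' @param tracks A track table, optionally with a `label` column (ground
#'   truth from the simulator or predictions from [segment_tracks()]).
#' @return A ggplot object, one path per track with equal axis scaling.
#' @export
plot_tracks <- function(tracks) {
  check_tracks(tracks)
  p <- ggplot2::ggplot(tracks,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$track_id))
  p <- if ("label" %in% names(tracks)) {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data$label)) +
      ggplot2::scale_colour_manual(
        values = c(diffusion = "#D55E00", flow = "#0072B2",
                   brownian = "#D55E00"),
        name = NULL
      )
  } else {
    p + ggplot2::geom_path()
  }
  p +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot MSD curves
#'
#' @param msd A per-track or ensemble MSD table (see [compute_msd()],
#'   [ensemble_msd()]).
#' @return A ggplot object; one curve per track when `track_id` is present.
#' @export
plot_msd <- function(msd) {
  if (!all(c("lag", "msd") %in% names(msd))) {
    stop_invalid("`msd` must have columns lag and msd.")
  }
  p <- ggplot2::ggplot(msd, ggplot2::aes(x = .data$lag, y = .data$msd))
  p <- if ("track_id" %in% names(msd)) {
    p + ggplot2::geom_line(ggplot2::aes(group = .data$track_id),
                           alpha = 0.4)
  } else {
    p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' Stacked-bar view of diffusion/flow population fractions
#'
#' @param fractions Output of [population_fractions()].
#' @param scheme `"time"` or `"tracks"` weighting.
#' @return A ggplot object, one bar per condition (or a single bar).
#' @export
plot_fractions <- function(fractions, scheme = c("time", "tracks")) {
  scheme <- match.arg(scheme)
  if (!all(c("scheme", "label", "fraction") %in% names(fractions))) {
    stop_invalid("`fractions` must come from population_fractions().")
  }
  df <- fractions[fractions$scheme == scheme, , drop = FALSE]
  if (!"condition" %in% names(df)) df$condition <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = 100 * .data$fraction,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(diffusion = "#D55E00", flow = "#0072B2"), name = NULL
    ) +
    ggplot2::labs(x = NULL, y = sprintf("%% of %s", scheme)) +
    ggplot2::theme_minimal()
}
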