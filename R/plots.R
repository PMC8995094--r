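# Diagnostic figures. All return ggplot objects so callers can restyle them.

#' Gap-versus-length scatter plot with plateau lines
#'
#' The standard view of contact-site morphometry: per-structure gap distance
#' against cER length, faceted by condition/tether when present, with
#' optional dashed horizontal plateau lines and the length threshold as a
#' dotted vertical line.
#'
#' @param structures Structure-level tibble (`gap_nm`, `length_nm`).
#' @param plateau Optional [plateau_gap()] result to annotate.
#' @return A ggplot.
#' @export
plot_gap_vs_length <- function(structures, plateau = NULL) {
  keys <- intersect(c("condition", "tether"), names(structures))
  p <- ggplot2::ggplot(structures,
                       ggplot2::aes(x = .data$length_nm, y = .data$gap_nm)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "cER length (nm)", y = "ER-PM gap distance (nm)") +
    ggplot2::coord_cartesian(ylim = c(0, 30)) +
    ggplot2::theme_minimal()
  if (length(keys) > 0) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(keys, collapse = "+"))))
  }
  if (!is.null(plateau)) {
    p <- p +
      ggplot2::geom_hline(data = plateau,
                          ggplot2::aes(yintercept = .data$plateau_gap_nm),
                          linetype = "dashed") +
      ggplot2::geom_vline(data = plateau,
                          ggplot2::aes(xintercept = .data$length_threshold_nm),
                          linetype = "dotted")
  }
  p
}

#' Plot an R/R0 ratio trace
#'
#' R/R0 against time for every ROI, with protocol events as labelled
#' vertical lines.
#'
#' @param object A [ratio_trace()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ratio_trace <- function(object, ...) {
  ev <- attr(object, "events")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$R_over_R0,
                                            group = .data$roi_id)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "R/R0") +
    ggplot2::theme_minimal()
  if (length(ev) > 0) {
    evd <- tibble::tibble(event = names(ev), time_s = as.numeric(ev))
    p <- p +
      ggplot2::geom_vline(data = evd, ggplot2::aes(xintercept = .data$time_s),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_text(data = evd,
                         ggplot2::aes(x = .data$time_s, y = Inf,
                                      label = .data$event),
                         inherit.aes = FALSE, vjust = 1.2, hjust = -0.05,
                         size = 3, colour = "grey30")
  }
  p
}

#' Plot a multi-channel line profile
#' @param profile A [line_profile()] tibble.
#' @return A ggplot with one line per channel.
#' @export
plot_line_profile <- function(profile) {
  xcol <- if ("position_um" %in% names(profile)) "position_um" else "position_px"
  long <- tidyr::pivot_longer(profile,
                              cols = !dplyr::starts_with("position"),
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xcol]], y = .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xcol == "position_um") "position (µm)"
                  else "position (px)",
                  y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}
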