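# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the pairwise comparisons of a group test
#' @param x An [group_compare()] result.
#' @param ... Unused.
#' @return Tibble of contrasts with estimates, adjusted p-values and stars.
#' @exportS3Method generics::tidy
tidy.mcs_anova <- function(x, ...) x$pairs

#' One-row model summary of a group test
#' @param x An [group_compare()] result.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.mcs_anova <- function(x, ...) {
  tibble::tibble(
    test = x$test, f_statistic = x$f_statistic,
    df_between = x$df[1], df_within = x$df[2],
    p_value = x$p_value, degenerate = x$degenerate
  )
}

#' Per-punctum table of a segmentation result
#' @param x A [segment_puncta()] result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.puncta_set <- function(x, ...) x$puncta

#' One-row summary of a segmentation result
#' @param x A [segment_puncta()] result.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.puncta_set <- function(x, ...) {
  tibble::tibble(
    n_puncta = nrow(x$puncta),
    mean_area_um2 = if (nrow(x$puncta)) mean(x$puncta$area_um2) else NA_real_,
    coverage_fraction = x$coverage_fraction,
    cell_area_um2 = x$cell_area_um2,
    threshold = x$threshold,
    n_removed_small = x$n_removed_small
  )
}
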