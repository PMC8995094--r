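#' Asymptotic gap ("plateau") of long cortical-ER structures
#'
#' On gap-versus-length scatter data, elongated cER sheets anchored by a
#' tether cluster at a tether-specific gap distance. This statistic formalises
#' the dashed plateau line of such scatter plots: the mean gap over structures
#' whose length is strictly greater than a threshold, with sample sd and a
#' seeded nonparametric bootstrap percentile confidence interval.
#'
#' The threshold is condition-specific (300 nm is the usual onset; 700 nm and
#' 600 nm are used for the short and long artificial MAPPER tethers after
#' store depletion) and is always recorded in the output.
#'
#' @param structures Structure-level tibble with `gap_nm` and `length_nm`
#'   (e.g. from [cer_morphometry()] or [simulate_cer_population()]).
#' @param length_threshold_nm Strict length threshold in nm (default 300).
#' @param by Character vector of grouping columns; defaults to whichever of
#'   `condition`, `tether` are present. Use `character()` for no grouping.
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return A tibble of class `plateau_estimate`, one row per group:
#'   `length_threshold_nm`, `n_long`, `plateau_gap_nm`, `sd_nm`, `sem_nm`,
#'   `ci_lo_nm`, `ci_hi_nm`. Groups with no qualifying structure yield an
#'   explicit empty estimate (`n_long = 0`, NA statistics), not an error.
#' @examples
#' pop <- simulate_cer_population(500, plateau_gap_nm = 5.2, seed = 3)
#' plateau_gap(pop)
#' @export
plateau_gap <- function(structures,
                        length_threshold_nm = 300,
                        by = NULL,
                        n_boot = 2000,
                        conf_level = 0.95,
                        seed = 1L) {
  stopifnot(is.data.frame(structures),
            all(c("gap_nm", "length_nm") %in% names(structures)),
            length_threshold_nm > 0, n_boot >= 1,
            conf_level > 0, conf_level < 1)
  by <- by %||% intersect(c("condition", "tether"), names(structures))

  one <- function(df, key) {
    g <- df$gap_nm[df$length_nm > length_threshold_nm]
    n <- length(g)
    if (n == 0) {
      return(tibble::tibble(
        length_threshold_nm = length_threshold_nm, n_long = 0L,
        plateau_gap_nm = NA_real_, sd_nm = NA_real_, sem_nm = NA_real_,
        ci_lo_nm = NA_real_, ci_hi_nm = NA_real_
      ))
    }
    ci <- with_fixed_seed(seed, {
      idx <- sample.int(n, n * n_boot, replace = TRUE)
      means <- rowMeans(matrix(g[idx], nrow = n_boot))
      stats::quantile(means, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                      names = FALSE, type = 7)
    })
    tibble::tibble(
      length_threshold_nm = length_threshold_nm, n_long = n,
      plateau_gap_nm = mean(g),
      sd_nm = if (n >= 2) stats::sd(g) else NA_real_,
      sem_nm = if (n >= 2) stats::sd(g) / sqrt(n) else NA_real_,
      ci_lo_nm = ci[1], ci_hi_nm = ci[2]
    )
  }

  out <- if (length(by) == 0) {
    one(structures, NULL)
  } else {
    structures |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(one) |>
      dplyr::ungroup()
  }
  class(out) <- c("plateau_estimate", class(out))
  out
}

#' Tidy gap-versus-length scatter table
#'
#' Per-structure (length, gap) pairs in plotting order, grouped by whatever
#' condition/tether labels are present. Deterministic ordering by group then
#' `structure_id`; concatenating the per-group tables recovers the input
#' multiset of records.
#'
#' @inheritParams plateau_gap
#' @return A tibble with `structure_id`, grouping columns, `length_nm`,
#'   `gap_nm`, ordered by group and structure id.
#' @export
scatter_table <- function(structures) {
  stopifnot(is.data.frame(structures),
            all(c("gap_nm", "length_nm") %in% names(structures)))
  keys <- intersect(c("condition", "tether"), names(structures))
  cols <- c("structure_id", keys, "length_nm", "gap_nm")
  cols <- intersect(cols, names(structures))
  structures |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(intersect(c(keys, "structure_id"), cols))))
}
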