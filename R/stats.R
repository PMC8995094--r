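#' One-way ANOVA with Tukey or Dunnett post-hoc comparisons
#'
#' Group comparison as routinely applied to per-structure or per-cell
#' measurements: one-way ANOVA followed by either Tukey's HSD (all pairwise
#' contrasts) or Dunnett's test (each group against a named control).
#' Adjusted p-values are mapped to the usual star convention
#' (`*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001).
#' The underlying tests are delegated to [stats::aov()], [stats::TukeyHSD()]
#' and [multcomp::glht()].
#'
#' @param data A data frame.
#' @param value Name of the numeric response column (string).
#' @param group Name of the grouping column (string).
#' @param scheme `"tukey"` or `"dunnett"`.
#' @param control Control group label; required for Dunnett.
#' @return An object of class `mcs_anova`: list with `test`, `f_statistic`,
#'   `df`, `p_value`, `pairs` (tibble: `contrast`, `estimate`, `p_adj`,
#'   `stars`) and a `degenerate` flag (TRUE when the within-group variance is
#'   essentially zero, in which case p-values are not meaningful).
#'   [tidy()] returns the pairwise table, [glance()] the ANOVA row.
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 5),
#'                 y = c(rnorm(5), rnorm(5, 1), rnorm(5, 2)))
#' group_compare(d, "y", "g")
#' @export
group_compare <- function(data, value, group,
                          scheme = c("tukey", "dunnett"), control = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs at least 2 observations", call. = FALSE)
  if (scheme == "dunnett") {
    if (is.null(control)) stop("Dunnett's test requires a `control` group", call. = FALSE)
    if (!control %in% levels(g)) stop("`control` is not a group level", call. = FALSE)
    g <- stats::relevel(g, ref = control)
  }
  df <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  ss_within <- an["Residuals", "Sum Sq"]
  degenerate <- ss_within < .Machine$double.eps * sum(y^2)
  if (degenerate) {
    warning("zero within-group variance; p-values are degenerate", call. = FALSE)
  }

  if (scheme == "tukey") {
    tk <- stats::TukeyHSD(fit)$g
    pairs <- tibble::tibble(
      contrast = rownames(tk),
      estimate = tk[, "diff"],
      conf_lo = tk[, "lwr"], conf_hi = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  } else {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    ci <- stats::confint(gl)$confint
    pairs <- tibble::tibble(
      contrast = names(sm$test$coefficients),
      estimate = as.numeric(sm$test$coefficients),
      conf_lo = ci[, "lwr"], conf_hi = ci[, "upr"],
      p_adj = as.numeric(sm$test$pvalues)
    )
  }
  pairs$stars <- significance_stars(pairs$p_adj)

  structure(list(
    test = if (scheme == "tukey") "one-way ANOVA + Tukey HSD"
           else "one-way ANOVA + Dunnett",
    f_statistic = an["g", "F value"],
    df = c(an["g", "Df"], an["Residuals", "Df"]),
    p_value = an["g", "Pr(>F)"],
    pairs = pairs,
    degenerate = degenerate
  ), class = "mcs_anova")
}

#' Significance stars for adjusted p-values
#'
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001,
#' `ns` otherwise.
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of codes.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out[p <= 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' @export
print.mcs_anova <- function(x, ...) {
  cat(sprintf("<%s> F(%d, %d) = %.3f, p = %.3g%s\n", x$test, x$df[1], x$df[2],
              x$f_statistic, x$p_value,
              if (x$degenerate) " [degenerate variance]" else ""))
  print(x$pairs)
  invisible(x)
}
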