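#' ER-PM gap distance of a traced membrane pair
#'
#' Emulates the per-pixel distance measurement used on EM membrane traces:
#' the cER trace is resampled to uniform spacing (default: the recorded pixel
#' size), the minimum Euclidean distance from each resampled cER point to the
#' PM polyline (true point-to-segment distance) is computed, and the mean over
#' cER points is returned. Distances are measured from the ER trace to the PM,
#' not symmetrised: the cER trace delimits the structure being scored.
#'
#' @param pair A `trace_pair` tibble (see [simulate_trace_pair()]) or any data
#'   frame with columns `membrane` (`"PM"`/`"ER"`), `x_nm`, `y_nm`; or a list
#'   with elements `pm` and `er`, each a two-column matrix.
#' @param spacing_nm Resampling interval for the cER trace (nm). Defaults to
#'   the `pixel_size_nm` attribute of `pair`, else 0.5 nm.
#'
#' @return A one-row tibble with `gap_nm` and `n_distance_samples` (number of
#'   resampled cER points averaged).
#'
#' @examples
#' tp <- simulate_trace_pair(gap_nm = 17, length_nm = 66, seed = 1)
#' gap_distance(tp)$gap_nm   # 17 exactly for noiseless parallel traces
#' @export
gap_distance <- function(pair, spacing_nm = NULL) {
  xy <- split_pair(pair)
  spacing_nm <- spacing_nm %||% attr(pair, "pixel_size_nm") %||% 0.5
  stopifnot(spacing_nm > 0)
  er_pts <- resample_polyline(xy$er, spacing_nm)
  d <- min_dist_to_polyline(er_pts, xy$pm)
  tibble::tibble(gap_nm = mean(d), n_distance_samples = nrow(er_pts))
}

#' Cortical-ER length of a traced structure
#'
#' Sum of Euclidean segment lengths of the polyline drawn along the cER long
#' axis. If the trace pair contains a dedicated long-axis polyline (rows with
#' `membrane == "AXIS"`), that polyline is measured; otherwise the cER trace
#' itself is. The measure is invariant under rigid transforms.
#'
#' @inheritParams gap_distance
#' @return Length in nm (scalar).
#' @examples
#' cer_length(cbind(c(0, 30, 30), c(0, 40, 100)))  # 110
#' @export
cer_length <- function(pair) {
  if (is.data.frame(pair) && "membrane" %in% names(pair)) {
    m <- if (any(pair$membrane == "AXIS")) "AXIS" else "ER"
    xy <- as_xy(pair[pair$membrane == m, c("x_nm", "y_nm")])
  } else if (is.list(pair) && !is.null(pair$er)) {
    xy <- as_xy(pair$axis %||% pair$er)
  } else {
    xy <- as_xy(pair)
  }
  if (nrow(xy) < 2L) stop("length trace needs at least 2 points", call. = FALSE)
  polyline_arclength(xy)
}

#' Cylindric cleft volume between cER and PM
#'
#' Models the cytosolic cleft between a cER sheet and the PM as a cylinder of
#' diameter equal to the cER length and height equal to the gap distance:
#' \eqn{V = \pi (L/2)^2 g}. The diameter convention is isolated here so it
#' can be swapped if a different cylinder construction is preferred.
#'
#' @param gap_nm Gap distance(s) in nm, > 0.
#' @param length_nm cER length(s) in nm, > 0.
#' @return Volume(s) in nm^3.
#' @examples
#' cleft_volume(1, 2)  # pi
#' @export
cleft_volume <- function(gap_nm, length_nm) {
  if (any(!is.finite(gap_nm)) || any(gap_nm <= 0)) {
    stop("`gap_nm` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(length_nm)) || any(length_nm <= 0)) {
    stop("`length_nm` must be positive and finite", call. = FALSE)
  }
  pi * (length_nm / 2)^2 * gap_nm
}

#' Morphometry of a set of traced structures
#'
#' Applies [gap_distance()], [cer_length()] and [cleft_volume()] to every
#' structure in a vertex-level trace table, yielding one record per structure.
#'
#' @param traces A data frame of trace vertices with columns `structure_id`,
#'   `membrane`, `x_nm`, `y_nm` and optionally `condition`, `tether` (one or
#'   several structures; e.g. several [simulate_trace_pair()] outputs bound
#'   together, or [read_trace_csv()] output).
#' @param spacing_nm Resampling interval passed to [gap_distance()].
#' @return A tibble with one row per structure: `structure_id`, `condition`,
#'   `tether`, `gap_nm`, `n_distance_samples`, `length_nm`,
#'   `cleft_volume_nm3`.
#' @export
cer_morphometry <- function(traces, spacing_nm = NULL) {
  stopifnot(is.data.frame(traces),
            all(c("structure_id", "membrane", "x_nm", "y_nm") %in% names(traces)))
  spacing_nm <- spacing_nm %||% attr(traces, "pixel_size_nm") %||% 0.5
  labels <- intersect(c("condition", "tether"), names(traces))
  traces |>
    dplyr::group_by(.data$structure_id) |>
    dplyr::group_modify(function(df, key) {
      g <- gap_distance(df, spacing_nm = spacing_nm)
      L <- cer_length(df)
      lab <- df[1, labels, drop = FALSE]
      dplyr::bind_cols(
        lab,
        g,
        tibble::tibble(length_nm = L, cleft_volume_nm3 = cleft_volume(g$gap_nm, L))
      )
    }) |>
    dplyr::ungroup()
}

#' Cortical filter: keep structures closer than 30 nm to the PM
#'
#' Retains structures whose mean gap distance is strictly below the cortical
#' threshold, the criterion used to call an ER sheet "cortical". The number of
#' discarded records is reported as attribute `n_discarded` and via a message.
#'
#' @param structures A tibble with a `gap_nm` column (e.g. [cer_morphometry()]
#'   or [simulate_cer_population()] output).
#' @param max_gap_nm Strict upper bound on the gap (nm); default 30.
#' @return The retained subset, with attribute `n_discarded`.
#' @export
cortical_filter <- function(structures, max_gap_nm = 30) {
  stopifnot(is.data.frame(structures), "gap_nm" %in% names(structures))
  keep <- structures$gap_nm < max_gap_nm
  out <- structures[keep, , drop = FALSE]
  n_disc <- sum(!keep)
  if (n_disc > 0) {
    message(sprintf("cortical_filter: discarded %d structure(s) with gap >= %g nm",
                    n_disc, max_gap_nm))
  }
  attr(out, "n_discarded") <- n_disc
  out
}

#' Per-group morphometry summaries
#'
#' Mean and sample standard deviation (n - 1 denominator) of gap, length and
#' cleft volume per group. Volumes are averaged per structure (mean of the
#' per-structure volumes), never recomputed from mean gap and mean length.
#' Standard errors of the mean are reported alongside, explicitly labelled.
#'
#' @param structures A structure-level tibble with `gap_nm`, `length_nm`,
#'   `cleft_volume_nm3`.
#' @param group_keys Character vector of grouping columns present in
#'   `structures` (default `c("condition", "tether")`, intersected with the
#'   available columns).
#' @return One row per group with `n`, `mean_*`, `sd_*`, `sem_*` columns and a
#'   logical `sd_defined` flag (FALSE for single-record groups, whose sd is
#'   undefined and returned as NA).
#' @export
condition_summary <- function(structures, group_keys = c("condition", "tether")) {
  stopifnot(is.data.frame(structures),
            all(c("gap_nm", "length_nm", "cleft_volume_nm3") %in% names(structures)))
  group_keys <- intersect(group_keys, names(structures))
  if (nrow(structures) == 0) warning("condition_summary: no records", call. = FALSE)
  out <- structures |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_gap_nm = mean(.data$gap_nm),
      sd_gap_nm = stats::sd(.data$gap_nm),
      mean_length_nm = mean(.data$length_nm),
      sd_length_nm = stats::sd(.data$length_nm),
      mean_volume_nm3 = mean(.data$cleft_volume_nm3),
      sd_volume_nm3 = stats::sd(.data$cleft_volume_nm3),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sem_gap_nm = .data$sd_gap_nm / sqrt(.data$n),
      sem_length_nm = .data$sd_length_nm / sqrt(.data$n),
      sem_volume_nm3 = .data$sd_volume_nm3 / sqrt(.data$n),
      sd_defined = .data$n >= 2L
    )
  if (any(!out$sd_defined)) {
    warning("condition_summary: group(s) with a single record; sd undefined",
            call. = FALSE)
  }
  out
}

#' Fold change between two group means
#'
#' Ratio of the mean of a morphometric field in group `to` over group `from`,
#' reported at full precision together with a 2-significant-figure label
#' mirroring the usual "x.y-fold" reporting style.
#'
#' @param from,to Either two one-row summaries from [condition_summary()] or
#'   two plain numbers (the group means).
#' @param field For summary inputs, one of `"gap"`, `"length"`, `"volume"`.
#' @return A one-row tibble with `field`, `mean_from`, `mean_to`, `ratio`
#'   (full precision) and `label` (2 significant figures, e.g. `"2.4-fold"`).
#' @examples
#' fold_change(66, 156)   # ratio 2.36...
#' @export
fold_change <- function(from, to, field = c("length", "gap", "volume")) {
  field <- match.arg(field)
  pick <- function(x) {
    if (is.data.frame(x)) {
      if (nrow(x) != 1L) stop("summary input must have exactly one row", call. = FALSE)
      col <- paste0("mean_", field, switch(field, volume = "_nm3", "_nm"))
      x[[col]]
    } else {
      as.numeric(x)
    }
  }
  a <- pick(from)
  b <- pick(to)
  if (!is.finite(a) || a == 0) stop("zero or undefined denominator mean", call. = FALSE)
  ratio <- b / a
  tibble::tibble(
    field = field, mean_from = a, mean_to = b, ratio = ratio,
    label = sprintf("%s-fold", format(signif(ratio, 2)))
  )
}

# Split a trace pair into pm / er coordinate matrices with input checks.
#' @noRd
split_pair <- function(pair) {
  if (is.data.frame(pair) && "membrane" %in% names(pair)) {
    pm <- as_xy(pair[pair$membrane == "PM", c("x_nm", "y_nm")])
    er <- as_xy(pair[pair$membrane == "ER", c("x_nm", "y_nm")])
  } else if (is.list(pair) && !is.null(pair$pm) && !is.null(pair$er)) {
    pm <- as_xy(pair$pm)
    er <- as_xy(pair$er)
  } else {
    stop("`pair` must have PM/ER rows or `pm` and `er` elements", call. = FALSE)
  }
  if (nrow(pm) < 2L || nrow(er) < 2L) {
    stop("each membrane trace needs at least 2 points", call. = FALSE)
  }
  if (polyline_arclength(pm) <= 0 || polyline_arclength(er) <= 0) {
    stop("zero-length membrane trace (all points identical)", call. = FALSE)
  }
  list(pm = pm, er = er)
}
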