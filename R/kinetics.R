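#' Background-subtracted R/R0 ratio traces
#'
#' Per frame and ROI, subtracts the mean background fluorescence from each
#' channel and forms the Fura-2 ratio `R = (F340 - bg340) / (F380 - bg380)`.
#' R0 is the mean R over the baseline window (default: all frames before the
#' first protocol event) and the trace is returned as R/R0, so the baseline
#' mean is 1 by construction. R is invariant under common scaling of both
#' channels and their backgrounds.
#'
#' Frames with non-positive background-subtracted F380 are dropped (not
#' interpolated) and counted per ROI in attribute `n_dropped`; a recording
#' whose R0 is not positive is rejected.
#'
#' @param rec A [fura2_recording()] object.
#' @param rois ROI ids to process (default: all cell ROIs).
#' @param baseline_window Length-2 numeric `c(t0, t1)` in seconds; default
#'   `c(0, first event)`.
#' @return A tibble of class `ratio_trace` with `time_s`, `roi_id`, `R`,
#'   `R_over_R0`; attributes `R0` (named per ROI), `baseline_window`,
#'   `events`, `n_dropped`.
#' @export
ratio_trace <- function(rec, rois = NULL, baseline_window = NULL) {
  stopifnot(inherits(rec, "fura2_recording"))
  d <- rec$data
  rois <- rois %||% setdiff(unique(d$roi_id), "background")
  if (!all(c("F340", "F380") %in% d$channel)) {
    stop("recording must contain F340 and F380 channels", call. = FALSE)
  }
  bg <- d |>
    dplyr::filter(.data$roi_id == "background") |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(bg = mean(.data$value), .groups = "drop")
  bg340 <- bg$bg[bg$channel == "F340"]
  bg380 <- bg$bg[bg$channel == "F380"]
  if (length(bg340) != 1L || length(bg380) != 1L) {
    stop("background ROI must cover F340 and F380", call. = FALSE)
  }
  if (is.null(baseline_window)) {
    t_end <- if (length(rec$events)) min(rec$events) else max(d$time_s)
    baseline_window <- c(min(d$time_s), t_end)
  }

  wide <- d |>
    dplyr::filter(.data$roi_id %in% rois, .data$channel %in% c("F340", "F380")) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")

  dropped <- integer(0)
  out <- wide |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(df, key) {
      f380 <- df$F380 - bg380
      bad <- f380 <= 0
      dropped[[key$roi_id]] <<- sum(bad)
      df <- df[!bad, , drop = FALSE]
      R <- (df$F340 - bg340) / (df$F380 - bg380)
      in_base <- df$time_s >= baseline_window[1] & df$time_s < baseline_window[2]
      if (!any(in_base)) in_base <- df$time_s <= baseline_window[2]
      R0 <- mean(R[in_base])
      if (!is.finite(R0) || R0 <= 0) {
        stop(sprintf("ROI %s: baseline R0 is not positive; recording rejected",
                     key$roi_id), call. = FALSE)
      }
      tibble::tibble(time_s = df$time_s, R = R, R_over_R0 = R / R0,
                     .R0 = R0)
    }) |>
    dplyr::ungroup()

  r0s <- out |> dplyr::distinct(.data$roi_id, .data$.R0)
  res <- out |> dplyr::select(!".R0") |>
    dplyr::relocate("time_s", "roi_id")
  attr(res, "R0") <- stats::setNames(r0s$.R0, r0s$roi_id)
  attr(res, "baseline_window") <- baseline_window
  attr(res, "events") <- rec$events
  attr(res, "n_dropped") <- dropped
  class(res) <- c("ratio_trace", class(res))
  res
}

# Centred moving average whose window shrinks symmetrically at the ends, so
# the output has the same length as the input and no NA padding.
#' @noRd
moving_average <- function(v, w) {
  if (w <= 1L) return(v)
  h <- (as.integer(w) - 1L) %/% 2L
  n <- length(v)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  (cs[i + hh + 1L] - cs[i - hh]) / (2L * hh + 1L)
}

#' Derivative-guided slope extraction
#'
#' Formalisation of the slope-measurement procedure used on Ca2+ recordings:
#' the trace is smoothed by a centred moving average (`w` frames), its
#' discrete first derivative (central differences) is computed, the extremum
#' of the derivative in the requested direction is located within the segment
#' (earliest extremum on ties), the regression region is the maximal
#' contiguous run of frames around that extremum where the directed
#' derivative is at least `alpha` times the extremum, and an ordinary
#' least-squares line is fitted to the *raw* values over that region.
#'
#' `alpha` trades window width against curvature bias: 0.5 (the default) is
#' appropriate for piecewise-linear protocols (the whole linear rise is
#' captured, and the fitted slope is exact on a noiseless clamped ramp);
#' values near 1 shrink the window towards the point of maximum slope, which
#' is what is wanted when the target is the instantaneous maximal slope of a
#' smooth sigmoid (for a logistic rise the fitted slope then approaches
#' A k / 4).
#'
#' @param data A data frame with a time column and a value column (e.g. one
#'   ROI of a [ratio_trace()]).
#' @param segment Length-2 numeric `c(t0, t1)` in seconds delimiting the
#'   analysed segment (default: whole trace). Must contain at least 5 frames.
#' @param direction `"rising"` or `"falling"`.
#' @param w Smoothing window in frames (odd; default 5).
#' @param alpha Derivative fraction defining the regression region, in (0, 1].
#' @param time_col,value_col Column names (defaults `time_s`, `R_over_R0`).
#' @param kind Label stored in the result (`entry`, `extrusion`, `quench`,
#'   or `slope`).
#' @return A one-row tibble of class `rate_estimate`: `kind`, `direction`,
#'   `slope_per_s` (signed OLS slope), `r_squared`, `t_start`, `t_end`,
#'   `n_points`, `flat` (TRUE when the segment has no usable derivative
#'   extremum; the slope is then 0 and `r_squared` NA).
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 100, 0.5),
#'                      R_over_R0 = pmin(1 + 0.02 * pmax(time_s - 20, 0), 1.5))
#' slope_from_derivative(tr, direction = "rising")
#' @export
slope_from_derivative <- function(data,
                                  segment = NULL,
                                  direction = c("rising", "falling"),
                                  w = 5,
                                  alpha = 0.5,
                                  time_col = "time_s",
                                  value_col = "R_over_R0",
                                  kind = "slope") {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(data), alpha > 0, alpha <= 1, w >= 1)
  t <- data[[time_col]]
  v <- data[[value_col]]
  if (is.null(t) || is.null(v)) stop("time/value columns not found", call. = FALSE)
  if (!is.null(segment)) {
    sel <- t >= segment[1] & t <= segment[2]
    t <- t[sel]; v <- v[sel]
  }
  n <- length(t)
  if (n < 5L) stop("segment must contain at least 5 frames", call. = FALSE)
  if (n < w) stop("segment shorter than the smoothing window", call. = FALSE)

  sm <- moving_average(v, w)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  dd <- if (direction == "rising") d else -d
  if (all(!is.finite(dd) | dd <= 0)) {
    # no slope in the requested direction: flat (or opposing) trace
    return(tibble::tibble(
      kind = kind, direction = direction, slope_per_s = 0,
      r_squared = NA_real_, t_start = t[1], t_end = t[n],
      n_points = n, flat = TRUE
    ) |> as_rate_estimate())
  }
  i0 <- which.max(replace(dd, !is.finite(dd), -Inf))  # earliest max on ties
  thr <- alpha * dd[i0]
  ok <- is.finite(dd) & dd >= thr
  lo <- i0; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- i0; while (hi < n && ok[hi + 1L]) hi <- hi + 1L
  if (hi - lo + 1L < 3L) { lo <- max(1L, i0 - 1L); hi <- min(n, i0 + 1L) }

  tt <- t[lo:hi]; vv <- v[lo:hi]
  fit <- stats::lm.fit(cbind(1, tt), vv)
  slope <- unname(fit$coefficients[2])
  ssr <- sum(fit$residuals^2)
  sst <- sum((vv - mean(vv))^2)
  tibble::tibble(
    kind = kind, direction = direction, slope_per_s = slope,
    r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
    t_start = tt[1], t_end = tt[length(tt)],
    n_points = length(tt), flat = FALSE
  ) |> as_rate_estimate()
}

#' @noRd
as_rate_estimate <- function(x) {
  class(x) <- c("rate_estimate", class(x))
  x
}

# Segment from a named event to the next event (or the end of the trace).
#' @noRd
event_segment <- function(events, event, t_max) {
  if (!event %in% names(events)) {
    stop(sprintf("event '%s' not present in `events`", event), call. = FALSE)
  }
  t0 <- unname(events[[event]])
  later <- events[events > t0]
  c(t0, if (length(later)) min(later) else t_max)
}

#' Store-operated Ca2+ entry rate
#'
#' Applies [slope_from_derivative()] (direction rising) to the segment from
#' the Ca2+-readmission event to the next protocol event (or the end of the
#' recording), per ROI. Slopes are in R/R0 units per second.
#'
#' @param trace A [ratio_trace()] tibble (one or several ROIs).
#' @param events Named event vector; defaults to the trace's `events`
#'   attribute. Must contain `Ca_readd`.
#' @param ... Passed to [slope_from_derivative()] (`w`, `alpha`).
#' @return A `rate_estimate` tibble, one row per ROI, `kind = "entry"`.
#' @export
entry_rate <- function(trace, events = NULL, ...) {
  events <- events %||% attr(trace, "events")
  seg <- event_segment(events, "Ca_readd", max(trace$time_s))
  per_roi(trace, function(df) {
    slope_from_derivative(df, segment = seg, direction = "rising",
                          kind = "entry", ...)
  })
}

#' Ca2+ extrusion rate after Ca2+ removal
#'
#' Quantifies the clearance of cytosolic Ca2+ after external Ca2+ removal
#' (plasma-membrane Ca2+-ATPase activity) on the post-removal segment. The
#' decay is treated as a single exponential towards the resting baseline:
#' the rate constant is the OLS slope of `log(R/R0 - asymptote)` over the
#' window where the decaying amplitude remains above `floor_frac` of its
#' initial value. For an exponential this window is exactly the region where
#' the first derivative exceeds `floor_frac` of its extremum, evaluated on
#' the model rather than on the noisy numerical derivative; recovery of the
#' rate constant is exact on noiseless data.
#'
#' Sign convention: `slope_per_s` is the (negative) fitted log-slope;
#' `rate_per_s` is its positive magnitude, the decay rate constant in 1/s.
#'
#' @inheritParams entry_rate
#' @param asymptote Decay asymptote in R/R0 units (default 1, the resting
#'   baseline by construction of R/R0).
#' @param floor_frac Amplitude fraction defining the fitted window (0-1).
#' @return A `rate_estimate` tibble with an extra `rate_per_s` column,
#'   one row per ROI, `kind = "extrusion"`.
#' @export
extrusion_rate <- function(trace, events = NULL, asymptote = 1, floor_frac = 0.25) {
  events <- events %||% attr(trace, "events")
  seg <- event_segment(events, "Ca_removal", max(trace$time_s))
  per_roi(trace, function(df) {
    decay_rate_fit(df$time_s, df$R_over_R0, seg, asymptote, floor_frac,
                   kind = "extrusion")
  })
}

#' Mn2+ quench rate at the isosbestic wavelength
#'
#' Mn2+ entering through store-operated channels quenches Fura-2 fluorescence
#' measured at the Ca2+-insensitive 360 nm excitation; the quench rate
#' reports channel activity independently of Ca2+ gradients. F360 is
#' background-subtracted, normalised to its mean over the pre-Mn2+ window,
#' and the decay rate constant of the normalised signal (asymptote 0) is
#' fitted as in [extrusion_rate()]. Fold comparisons between conditions are
#' ratios of `rate_per_s` values.
#'
#' @param rec A [fura2_recording()] with an F360 channel.
#' @param rois ROI ids (default: all cell ROIs).
#' @param events Named event vector containing `Mn_add`; defaults to the
#'   recording's events.
#' @param floor_frac Amplitude fraction defining the fitted window.
#' @return A `rate_estimate` tibble, one row per ROI, `kind = "quench"`;
#'   `slope_per_s` is the signed (non-positive) log-slope and `rate_per_s`
#'   the quench rate constant in 1/s.
#' @export
quench_rate <- function(rec, rois = NULL, events = NULL, floor_frac = 0.25) {
  stopifnot(inherits(rec, "fura2_recording"))
  if (!"F360" %in% rec$data$channel) {
    stop("recording has no F360 channel; Mn2+ quench unsupported", call. = FALSE)
  }
  events <- events %||% rec$events
  rois <- rois %||% setdiff(unique(rec$data$roi_id), "background")
  t_mn <- event_segment(events, "Mn_add", max(rec$data$time_s))
  bg360 <- rec$data |>
    dplyr::filter(.data$roi_id == "background", .data$channel == "F360") |>
    dplyr::pull("value") |> mean()

  f360 <- rec$data |>
    dplyr::filter(.data$roi_id %in% rois, .data$channel == "F360")
  per_roi(f360, function(df) {
    v <- df$value - bg360
    pre <- df$time_s < t_mn[1]
    if (!any(pre)) stop("no pre-Mn2+ frames to normalise against", call. = FALSE)
    norm0 <- mean(v[pre])
    if (!is.finite(norm0) || norm0 <= 0) {
      stop("pre-Mn2+ F360 level is not positive", call. = FALSE)
    }
    decay_rate_fit(df$time_s, v / norm0, t_mn, asymptote = 0,
                   floor_frac = floor_frac, kind = "quench")
  })
}

# Exponential decay rate constant: OLS on log(signal - asymptote) over the
# leading window where the smoothed amplitude stays above floor_frac of its
# initial value. Flat signals give rate 0 (flagged).
#' @noRd
decay_rate_fit <- function(t, v, segment, asymptote, floor_frac, kind, w = 5) {
  stopifnot(floor_frac > 0, floor_frac < 1)
  sel <- t >= segment[1] & t <= segment[2]
  t <- t[sel]; v <- v[sel]
  n <- length(t)
  if (n < 5L) stop("decay segment must contain at least 5 frames", call. = FALSE)
  sig <- v - asymptote
  sm <- moving_average(sig, w)
  a0 <- sm[1]
  if (!is.finite(a0) || a0 <= 0) {
    stop("decay amplitude at the segment start is not positive", call. = FALSE)
  }
  hi <- n
  below <- which(sm < floor_frac * a0)
  if (length(below)) hi <- max(3L, below[1] - 1L)
  tt <- t[1:hi]; ss <- sig[1:hi]
  pos <- ss > 0
  if (sum(pos) < 3L) stop("too few positive decay frames to fit", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, tt[pos]), log(ss[pos]))
  slope <- unname(fit$coefficients[2])
  ssr <- sum(fit$residuals^2)
  sst <- sum((log(ss[pos]) - mean(log(ss[pos])))^2)
  flat <- sst < .Machine$double.eps * length(ss)
  if (flat) slope <- 0
  tibble::tibble(
    kind = kind, direction = "falling",
    slope_per_s = min(slope, 0),
    rate_per_s = max(-slope, 0),
    r_squared = if (!flat && sst > 0) 1 - ssr / sst else NA_real_,
    t_start = tt[1], t_end = tt[sum(pos)],
    n_points = sum(pos), flat = flat
  ) |> as_rate_estimate()
}

#' Peak amplitude of an evoked Ca2+ response
#'
#' Maximum of R/R0 in the segment following a protocol event, minus the mean
#' baseline R/R0 (1 by construction when the baseline window defines R0).
#' When several transients fall in the segment the global maximum is used.
#' A non-positive amplitude (monotonically decreasing segment) is flagged.
#'
#' @inheritParams entry_rate
#' @param event Name of the triggering event (e.g. `"ATP"`, `"Tg"`).
#' @param baseline_window Window used for the baseline mean; default: all
#'   frames before the first event.
#' @return A tibble with one row per ROI: `roi_id`, `peak_amplitude`,
#'   `t_peak`, `nonpositive` flag.
#' @export
peak_amplitude <- function(trace, event, events = NULL, baseline_window = NULL) {
  events <- events %||% attr(trace, "events")
  seg <- event_segment(events, event, max(trace$time_s))
  baseline_window <- baseline_window %||%
    c(min(trace$time_s), if (length(events)) min(events) else max(trace$time_s))
  trace |>
    dplyr::filter(.data$roi_id != "background") |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(df, key) {
      in_seg <- df$time_s >= seg[1] & df$time_s <= seg[2]
      if (!any(in_seg)) stop("empty post-event segment", call. = FALSE)
      in_base <- df$time_s >= baseline_window[1] & df$time_s < baseline_window[2]
      base <- if (any(in_base)) mean(df$R_over_R0[in_base]) else 1
      i <- which(in_seg)[which.max(df$R_over_R0[in_seg])]
      amp <- df$R_over_R0[i] - base
      tibble::tibble(peak_amplitude = amp, t_peak = df$time_s[i],
                     nonpositive = amp <= 0)
    }) |>
    dplyr::ungroup()
}

# Apply a per-ROI estimator over a long tibble with a roi_id column.
#' @noRd
per_roi <- function(data, fn) {
  data |>
    dplyr::filter(.data$roi_id != "background") |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(df, key) fn(df)) |>
    dplyr::ungroup() |>
    as_rate_estimate()
}
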