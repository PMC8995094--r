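#' Simulate a multi-ROI Fura-2 recording
#'
#' Builds a ratiometric Ca2+-imaging recording emulating the store-depletion /
#' Ca2+-readmission protocol: a flat baseline; a single-exponential release
#' transient after SERCA inhibition (`Tg`); a linear rise at a known
#' store-operated entry slope after Ca2+ readmission (`Ca_readd`), saturating
#' by hard clamp at a plateau; an exponential decay towards baseline after
#' Ca2+ removal (`Ca_removal`); and, when an `Mn_add` event is given, an
#' exponential quench of the isosbestic 360 nm channel at a known rate. The
#' hard clamp makes the maximum first derivative of the noiseless rise equal
#' exactly to `entry_slope_per_s`.
#'
#' The true ratio trace R(t) is built in F340/F380 units, per-ROI Gaussian
#' noise is added to it, and raw channels are then synthesised as
#' `F380 = bg + C`, `F340 = bg + R(t) * C`, `F360 = bg + C * q(t)` with
#' constant background ROIs, so that background subtraction and ratioing
#' recover the constructed trace exactly when `noise_sd = 0`.
#'
#' @param n_rois Number of cell ROIs (each gets independent noise).
#' @param frame_interval_s Acquisition interval in seconds, > 0.
#' @param duration_s Total recording duration in seconds.
#' @param baseline_R Baseline F340/F380 ratio.
#' @param release_amplitude Peak height of the Tg-release transient, in R
#'   units above baseline.
#' @param release_decay_s Exponential decay time constant of the transient (s).
#' @param entry_slope_per_s True store-operated entry slope in R/R0 units per
#'   second (the generated R rises at `entry_slope_per_s * baseline_R` per
#'   second so that the R/R0 slope is exact).
#' @param plateau_R_over_R0 Saturation level of the rise, in R/R0 units.
#' @param extrusion_rate_per_s Exponential rate of the post-removal decay (1/s).
#' @param quench_rate_per_s Exponential Mn2+ quench rate of F360 (1/s).
#' @param noise_sd Gaussian noise sd added to R/R0 (and to normalised F360).
#' @param events Named numeric vector of protocol event times (s), strictly
#'   increasing, inside the recording. Recognised names: `Tg`, `Ca_readd`,
#'   `Ca_removal`, `Mn_add`, `ATP`; absent events simply skip their segment.
#' @param background Named channel backgrounds (arbitrary units).
#' @param f380_level Background-subtracted F380 level (arbitrary units).
#' @param seed Integer seed.
#'
#' @return An object of class `fura2_recording`: a list with `data` (long
#'   tibble: `time_s`, `roi_id`, `channel`, `value`, including a
#'   `"background"` ROI), `events`, `frame_interval_s` and `truth` (the
#'   generating parameters, with the true R/R0 entry slope, plateau,
#'   extrusion and quench rates, and release amplitude in R/R0 units).
#'
#' @examples
#' rec <- simulate_fura2_recording(n_rois = 2, seed = 1)
#' rt <- ratio_trace(rec)
#' entry_rate(rt, events = rec$events)
#' @export
simulate_fura2_recording <- function(n_rois = 1,
                                     frame_interval_s = 0.5,
                                     duration_s = 900,
                                     baseline_R = 1,
                                     release_amplitude = 0.8,
                                     release_decay_s = 30,
                                     entry_slope_per_s = 0.02,
                                     plateau_R_over_R0 = 1.5,
                                     extrusion_rate_per_s = 0.05,
                                     quench_rate_per_s = 0,
                                     noise_sd = 0.005,
                                     events = c(Tg = 60, Ca_readd = 660, Ca_removal = 780),
                                     background = c(F340 = 50, F380 = 50, F360 = 50),
                                     f380_level = 800,
                                     seed = 1L) {
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    stop("`frame_interval_s` must be > 0", call. = FALSE)
  }
  stopifnot(n_rois >= 1, duration_s > 0, baseline_R > 0,
            release_amplitude >= 0, release_decay_s > 0,
            entry_slope_per_s >= 0, plateau_R_over_R0 > 0,
            extrusion_rate_per_s >= 0, quench_rate_per_s >= 0, noise_sd >= 0)
  if (length(events) > 0) {
    if (is.null(names(events)) || any(names(events) == "")) {
      stop("`events` must be a named vector", call. = FALSE)
    }
    if (any(diff(events) <= 0)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
    if (any(events <= 0) || any(events >= duration_s)) {
      stop("event times must lie inside the recording", call. = FALSE)
    }
  }

  t <- seq(0, duration_s, by = frame_interval_s)
  n <- length(t)
  ev <- function(name) if (name %in% names(events)) unname(events[[name]]) else NA_real_
  t_tg <- ev("Tg"); t_re <- ev("Ca_readd"); t_rm <- ev("Ca_removal")
  t_mn <- ev("Mn_add"); t_atp <- ev("ATP")

  # true ratio in R units; each segment starts from the level reached so far
  R <- rep(baseline_R, n)
  if (!is.na(t_tg)) {
    i <- t >= t_tg
    R[i] <- baseline_R + release_amplitude * exp(-(t[i] - t_tg) / release_decay_s)
  }
  if (!is.na(t_atp)) {                 # agonist transient, same shape as Tg
    i <- t >= t_atp
    R[i] <- baseline_R + release_amplitude * exp(-(t[i] - t_atp) / release_decay_s)
  }
  if (!is.na(t_re)) {
    i <- t >= t_re
    r0 <- R[which(i)[1]]
    R[i] <- pmin(r0 + entry_slope_per_s * baseline_R * (t[i] - t_re),
                 plateau_R_over_R0 * baseline_R)
  }
  if (!is.na(t_rm)) {
    i <- t >= t_rm
    r0 <- R[which(i)[1]]
    R[i] <- baseline_R + (r0 - baseline_R) * exp(-extrusion_rate_per_s * (t[i] - t_rm))
  }
  # isosbestic channel, normalised shape
  q <- rep(1, n)
  if (!is.na(t_mn)) {
    i <- t >= t_mn
    q[i] <- exp(-quench_rate_per_s * (t[i] - t_mn))
  }

  noise <- with_fixed_seed(seed, {
    matrix(stats::rnorm(2L * n_rois * n, sd = noise_sd), ncol = 2L * n_rois)
  })

  rois <- sprintf("roi%02d", seq_len(n_rois))
  per_roi <- purrr::map(seq_len(n_rois), function(k) {
    r_over_r0 <- R / baseline_R + noise[, 2L * k - 1L]
    qk <- q + noise[, 2L * k]
    tibble::tibble(
      time_s = rep(t, 3),
      roi_id = rois[k],
      channel = rep(c("F340", "F380", "F360"), each = n),
      value = c(background[["F340"]] + r_over_r0 * baseline_R * f380_level,
                background[["F380"]] + rep(f380_level, n),
                background[["F360"]] + f380_level * qk)
    )
  })
  bg <- tibble::tibble(
    time_s = rep(t, 3),
    roi_id = "background",
    channel = rep(c("F340", "F380", "F360"), each = n),
    value = rep(c(background[["F340"]], background[["F380"]], background[["F360"]]),
                each = n)
  )

  out <- list(
    data = dplyr::bind_rows(per_roi, list(bg)),
    events = events,
    frame_interval_s = frame_interval_s,
    n_rois = n_rois,
    truth = list(
      baseline_R = baseline_R,
      release_amplitude_R_over_R0 = release_amplitude / baseline_R,
      release_decay_s = release_decay_s,
      entry_slope_per_s = entry_slope_per_s,
      plateau_R_over_R0 = plateau_R_over_R0,
      extrusion_rate_per_s = extrusion_rate_per_s,
      quench_rate_per_s = quench_rate_per_s,
      noise_sd = noise_sd, seed = as.integer(seed),
      rng = "Mersenne-Twister/Inversion"
    )
  )
  class(out) <- "fura2_recording"
  out
}

#' Assemble a Fura-2 recording from raw data
#'
#' Constructor for real (non-simulated) recordings: validates the long-format
#' intensity table and the protocol events and returns the same
#' `fura2_recording` structure produced by [simulate_fura2_recording()].
#'
#' @param data Long tibble with `time_s`, `roi_id`, `channel` (`F340`,
#'   `F380`, optionally `F360`) and `value`; must include a `"background"`
#'   ROI.
#' @param events Named numeric vector of protocol event times (s).
#' @param frame_interval_s Optional; inferred from the time base if missing.
#' @return A `fura2_recording` object.
#' @export
fura2_recording <- function(data, events, frame_interval_s = NULL) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "roi_id", "channel", "value") %in% names(data)))
  if (!"background" %in% data$roi_id) {
    stop("`data` must contain a 'background' ROI", call. = FALSE)
  }
  tt <- sort(unique(data$time_s))
  if (any(diff(tt) <= 0)) stop("time base must be strictly increasing", call. = FALSE)
  if (length(events) > 0 &&
      (any(events < min(tt)) || any(events > max(tt)))) {
    stop("event times must lie inside the recording", call. = FALSE)
  }
  structure(list(
    data = tibble::as_tibble(data),
    events = events,
    frame_interval_s = frame_interval_s %||% stats::median(diff(tt)),
    n_rois = length(setdiff(unique(data$roi_id), "background")),
    truth = NULL
  ), class = "fura2_recording")
}

#' @export
print.fura2_recording <- function(x, ...) {
  cat(sprintf(
    "<fura2_recording> %d ROI(s), %d frames at %.3g s, events: %s\n",
    x$n_rois, length(unique(x$data$time_s)), x$frame_interval_s,
    if (length(x$events)) paste(sprintf("%s=%gs", names(x$events), x$events),
                                collapse = ", ") else "none"
  ))
  if (!is.null(x$truth)) cat("  (synthetic; ground truth attached)\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.fura2_recording <- function(x, ...) x$data
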