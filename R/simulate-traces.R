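#' Simulate a traced PM/cER membrane pair
#'
#' Generates a pair of 2-D membrane traces emulating hand-traced transmission
#' EM membranes at an ER-PM contact site: a plasma-membrane (PM) polyline and
#' a cortical-ER (cER) polyline offset from it by a known gap distance along
#' the local normal. With `curvature = 0` the traces are parallel straight
#' lines; with `curvature > 0` they are concentric arcs of radii `1/curvature`
#' (PM) and `1/curvature - gap_nm` (cER), so the radial separation is exactly
#' `gap_nm` everywhere. The PM trace overhangs the cER extent on both sides,
#' as a real PM trace would. Optional isotropic Gaussian jitter emulates
#' tracing noise.
#'
#' Geometry is generated in continuous nm coordinates; estimators that emulate
#' pixel-based measurement resample at `pixel_size_nm`.
#'
#' @param gap_nm True PM-cER separation (nm), > 0.
#' @param length_nm True cER extent measured along the cER curve (nm);
#'   must be at least `point_spacing_nm`.
#' @param curvature Reciprocal radius of the PM arc in 1/nm; 0 = straight.
#' @param point_spacing_nm Vertex sampling interval along each trace (nm).
#' @param noise_sd_nm Standard deviation of independent Gaussian jitter added
#'   to each vertex coordinate (nm).
#' @param pm_overhang_nm Extra PM extent beyond each cER end (nm).
#' @param pixel_size_nm Calibration recorded with the trace (nm/pixel).
#' @param structure_id,condition,tether Labels carried on every vertex row.
#' @param seed Integer seed; identical seeds give identical traces.
#'
#' @return A tibble of class `trace_pair` with one row per vertex and columns
#'   `structure_id`, `membrane` (`"PM"`/`"ER"`), `x_nm`, `y_nm`, `condition`,
#'   `tether`. The generating parameters are attached as attribute `truth`
#'   and the calibration as attribute `pixel_size_nm`.
#'
#' @examples
#' tp <- simulate_trace_pair(gap_nm = 17, length_nm = 66, seed = 1)
#' gap_distance(tp)
#' @export
simulate_trace_pair <- function(gap_nm,
                                length_nm,
                                curvature = 0,
                                point_spacing_nm = 10,
                                noise_sd_nm = 0,
                                pm_overhang_nm = 0.15 * length_nm,
                                pixel_size_nm = 0.5,
                                structure_id = "S1",
                                condition = "NT",
                                tether = "none",
                                seed = 1L) {
  if (!is.numeric(gap_nm) || gap_nm <= 0) {
    stop("`gap_nm` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(length_nm) || length_nm <= 0) {
    stop("`length_nm` must be a positive number", call. = FALSE)
  }
  if (length_nm < point_spacing_nm) {
    stop("`length_nm` must be at least `point_spacing_nm`", call. = FALSE)
  }
  if (curvature < 0) stop("`curvature` must be >= 0", call. = FALSE)
  if (noise_sd_nm < 0) stop("`noise_sd_nm` must be >= 0", call. = FALSE)
  if (curvature > 0 && gap_nm >= 1 / curvature) {
    stop("`gap_nm` must be smaller than the PM radius `1/curvature`", call. = FALSE)
  }

  n_pts <- function(len) max(2L, as.integer(ceiling(len / point_spacing_nm)) + 1L)
  pm_len <- length_nm + 2 * pm_overhang_nm

  if (curvature == 0) {
    # PM along y = 0, ER parallel at y = gap_nm spanning [0, length_nm]
    pm <- cbind(seq(-pm_overhang_nm, length_nm + pm_overhang_nm,
                    length.out = n_pts(pm_len)), 0)
    er <- cbind(seq(0, length_nm, length.out = n_pts(length_nm)), gap_nm)
  } else {
    r_pm <- 1 / curvature
    r_er <- r_pm - gap_nm           # cER on the concave (cytosolic) side
    th_pm <- pm_len / r_pm
    th_er <- length_nm / r_er
    a_pm <- pi / 2 + seq(-th_pm / 2, th_pm / 2, length.out = n_pts(pm_len))
    a_er <- pi / 2 + seq(-th_er / 2, th_er / 2, length.out = n_pts(length_nm))
    pm <- cbind(r_pm * cos(a_pm), r_pm * sin(a_pm))
    er <- cbind(r_er * cos(a_er), r_er * sin(a_er))
  }

  if (noise_sd_nm > 0) {
    jitter <- with_fixed_seed(seed, {
      stats::rnorm((nrow(pm) + nrow(er)) * 2, sd = noise_sd_nm)
    })
    pm <- pm + matrix(jitter[seq_len(2 * nrow(pm))], ncol = 2)
    er <- er + matrix(jitter[-seq_len(2 * nrow(pm))], ncol = 2)
  }

  out <- tibble::tibble(
    structure_id = structure_id,
    membrane = rep(c("PM", "ER"), c(nrow(pm), nrow(er))),
    x_nm = c(pm[, 1], er[, 1]),
    y_nm = c(pm[, 2], er[, 2]),
    condition = condition,
    tether = tether
  )
  attr(out, "truth") <- list(
    gap_nm = gap_nm, length_nm = length_nm, curvature = curvature,
    point_spacing_nm = point_spacing_nm, noise_sd_nm = noise_sd_nm,
    seed = as.integer(seed), rng = "Mersenne-Twister/Inversion"
  )
  attr(out, "pixel_size_nm") <- pixel_size_nm
  class(out) <- c("trace_pair", class(out))
  out
}

#' Simulate a population of cortical-ER structures with a gap plateau
#'
#' Draws per-structure (gap, length) records with the statistical structure of
#' gap-versus-length scatter data at ER-PM contact sites: lengths follow a
#' log-normal law; structures longer than `plateau_onset_nm` ("long"
#' structures, e.g. tether-anchored cER sheets) have gaps drawn around the
#' asymptotic plateau gap, while shorter structures have broadly distributed
#' gaps. All gaps are truncated to the cortical interval (0, 30] nm. Cleft
#' volumes are computed with [cleft_volume()].
#'
#' @param n_structures Number of records to draw (0 gives an empty tibble).
#' @param plateau_gap_nm Asymptotic mean gap for long structures (nm).
#' @param plateau_gap_sd_nm Gap spread of the long subpopulation (nm).
#' @param short_gap_mean_nm,short_gap_sd_nm Gap distribution of short
#'   structures (nm).
#' @param plateau_onset_nm Length above which a structure is "long" (nm).
#' @param length_meanlog,length_sdlog Parameters of the log-normal length law
#'   (log-nm scale).
#' @param condition,tether Labels attached to every record.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `structure_id`, `condition`, `tether`,
#'   `gap_nm`, `length_nm`, `cleft_volume_nm3`, `long` (logical ground-truth
#'   subpopulation label); the generating parameters are attached as
#'   attribute `truth`.
#'
#' @examples
#' pop <- simulate_cer_population(200, plateau_gap_nm = 5.2, seed = 3)
#' plateau_gap(pop, length_threshold_nm = 300)
#' @export
simulate_cer_population <- function(n_structures = 500,
                                    plateau_gap_nm = 5.2,
                                    plateau_gap_sd_nm = 1.2,
                                    short_gap_mean_nm = 17,
                                    short_gap_sd_nm = 6,
                                    plateau_onset_nm = 300,
                                    length_meanlog = log(150),
                                    length_sdlog = 1,
                                    condition = "CF",
                                    tether = "MAPPER-L",
                                    seed = 1L) {
  stopifnot(n_structures >= 0, plateau_gap_nm > 0, plateau_onset_nm > 0,
            plateau_gap_sd_nm >= 0, short_gap_sd_nm >= 0)
  if (plateau_gap_nm > 30 || short_gap_mean_nm > 30) {
    stop("mean gaps must lie in the cortical interval (0, 30] nm", call. = FALSE)
  }
  truth <- list(
    n_structures = n_structures, plateau_gap_nm = plateau_gap_nm,
    plateau_gap_sd_nm = plateau_gap_sd_nm,
    short_gap_mean_nm = short_gap_mean_nm, short_gap_sd_nm = short_gap_sd_nm,
    plateau_onset_nm = plateau_onset_nm,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    seed = as.integer(seed), rng = "Mersenne-Twister/Inversion"
  )
  if (n_structures == 0) {
    out <- tibble::tibble(
      structure_id = character(), condition = character(), tether = character(),
      gap_nm = numeric(), length_nm = numeric(), cleft_volume_nm3 = numeric(),
      long = logical()
    )
    attr(out, "truth") <- truth
    return(out)
  }
  dat <- with_fixed_seed(seed, {
    len <- stats::rlnorm(n_structures, length_meanlog, length_sdlog)
    long <- len > plateau_onset_nm
    gap <- numeric(n_structures)
    gap[long] <- rnorm_trunc(sum(long), plateau_gap_nm, plateau_gap_sd_nm, 0, 30)
    gap[!long] <- rnorm_trunc(sum(!long), short_gap_mean_nm, short_gap_sd_nm, 0, 30)
    list(len = len, gap = gap, long = long)
  })
  out <- tibble::tibble(
    structure_id = sprintf("S%04d", seq_len(n_structures)),
    condition = condition,
    tether = tether,
    gap_nm = dat$gap,
    length_nm = dat$len,
    cleft_volume_nm3 = cleft_volume(dat$gap, dat$len),
    long = dat$long
  )
  attr(out, "truth") <- truth
  out
}

# Truncated normal draw on (lo, hi] by rejection; degenerates to the mean when
# sd = 0 (the mean must then be inside the interval).
#' @noRd
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric())
  if (sd == 0) {
    if (mean <= lo || mean > hi) stop("degenerate mean outside truncation interval")
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out > hi)
  tries <- 0L
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] > hi]
    tries <- tries + 1L
    if (tries > 1000L) stop("truncated-normal rejection failed to converge")
  }
  out
}
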