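# Polyline primitives shared by the trace simulator and the morphometry
# estimators. All coordinates are 2-D, in nm, stored as two-column matrices.

#' @keywords internal
#' @noRd
as_xy <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("x_nm", "y_nm"), names(x))
    if (length(cols) == 2L) x <- x[, cols] else x <- x[, 1:2]
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || ncol(x) != 2L) {
    stop("a polyline must be a two-column matrix or data frame", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("polyline coordinates must be finite", call. = FALSE)
  x
}

#' @noRd
segment_lengths <- function(xy) {
  d <- diff(xy)
  sqrt(rowSums(d^2))
}

#' @noRd
polyline_arclength <- function(xy) sum(segment_lengths(xy))

# Resample a polyline at (near-)uniform arc-length spacing. Both endpoints are
# always kept; the realised spacing is total length / ceiling(length/spacing),
# i.e. never larger than requested.
#' @noRd
resample_polyline <- function(xy, spacing) {
  xy <- as_xy(xy)
  if (nrow(xy) < 2L) stop("polyline needs at least 2 points", call. = FALSE)
  seg <- segment_lengths(xy)
  total <- sum(seg)
  if (total <= 0) stop("zero-length polyline (all points identical)", call. = FALSE)
  keep <- c(TRUE, seg > 0)        # drop duplicated vertices for interpolation
  xy <- xy[keep, , drop = FALSE]
  s <- c(0, cumsum(segment_lengths(xy)))
  n_out <- max(2L, as.integer(ceiling(total / spacing)) + 1L)
  at <- seq(0, total, length.out = n_out)
  cbind(
    stats::approx(s, xy[, 1], xout = at)$y,
    stats::approx(s, xy[, 2], xout = at)$y
  )
}

# Minimum Euclidean distance from each query point to a polyline, using true
# point-to-segment distances (not point-to-vertex).
#' @noRd
min_dist_to_polyline <- function(points, poly) {
  points <- as_xy(points)
  poly <- as_xy(poly)
  if (nrow(poly) < 2L) stop("polyline needs at least 2 points", call. = FALSE)
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1            # degenerate segments: distance to the vertex
  np <- nrow(points)
  out <- numeric(np)
  # vectorised over segments for each query point; trace sizes are small
  for (i in seq_len(np)) {
    apx <- points[i, 1] - a[, 1]
    apy <- points[i, 2] - a[, 2]
    t <- pmin(1, pmax(0, (apx * ab[, 1] + apy * ab[, 2]) / len2))
    dx <- apx - t * ab[, 1]
    dy <- apy - t * ab[, 2]
    out[i] <- sqrt(min(dx * dx + dy * dy))
  }
  out
}

# All stochastic generators funnel through this so that outputs are pure
# functions of their seed, independent of the caller's RNG state.
#' @noRd
with_fixed_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
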