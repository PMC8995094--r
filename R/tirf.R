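#' Simulate a TIRF image with disc-shaped puncta
#'
#' Renders a single-channel TIRF-like image: a cell footprint (elliptical by
#' default, or a user-supplied binary mask), `n_puncta` disc-shaped puncta of
#' a stated physical area placed fully inside the footprint without overlap,
#' optional Gaussian PSF blur, and Gaussian read noise. Ground truth
#' (centroids, per-punctum area, coverage) is attached; the true coverage is
#' `n_puncta * punctum_area_um2 / cell_area`.
#'
#' @param shape_px Image size `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param n_puncta Number of puncta (0 gives a uniform background image).
#' @param punctum_area_um2 True area of each punctum (default 0.3, the
#'   apparent size of tether-protein puncta in the TIRF plane).
#' @param cell_area_um2 Target footprint area for the default elliptical
#'   mask; ignored when `mask` is supplied.
#' @param mask Optional logical matrix (same shape) defining the footprint.
#' @param psf_sigma_px Gaussian PSF sigma in pixels (default 0: crisp discs,
#'   so segmented areas differ from truth only by pixel quantization; with
#'   blur the segmented area depends on where the threshold cuts the blurred
#'   edge profile).
#' @param background_level,punctum_amplitude,noise_sd Intensity parameters
#'   (arbitrary units).
#' @param min_separation_px Minimum distance between punctum centres;
#'   default keeps discs disjoint.
#' @param seed Integer seed.
#' @return An object of class `tirf_image`: list with `image` (numeric
#'   matrix), `mask` (logical matrix), `pixel_size_um`, `truth` (tibble of
#'   punctum centres and areas with attributes `coverage_fraction` and
#'   `cell_area_um2`) and `params`.
#' @examples
#' im <- simulate_tirf_image(n_puncta = 10, seed = 1)
#' segment_puncta(im)
#' @export
simulate_tirf_image <- function(shape_px = c(128, 128),
                                pixel_size_um = 0.1,
                                n_puncta = 10,
                                punctum_area_um2 = 0.3,
                                cell_area_um2 = 60,
                                mask = NULL,
                                psf_sigma_px = 0,
                                background_level = 100,
                                punctum_amplitude = 1000,
                                noise_sd = 10,
                                min_separation_px = NULL,
                                seed = 1L) {
  stopifnot(length(shape_px) == 2, all(shape_px >= 8), pixel_size_um > 0,
            n_puncta >= 0, punctum_area_um2 > 0, psf_sigma_px >= 0,
            noise_sd >= 0)
  nr <- as.integer(shape_px[1]); nc <- as.integer(shape_px[2])

  if (is.null(mask)) {
    # centred ellipse of the requested area, aspect ratio 3:4
    ab_ratio <- 0.75
    a <- sqrt(cell_area_um2 / (pi * ab_ratio)) / pixel_size_um  # semi-major, px
    b <- a * ab_ratio
    if (2 * a > nc - 4 || 2 * b > nr - 4) {
      stop("requested cell area does not fit in the image", call. = FALSE)
    }
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    yy <- matrix(seq_len(nr), nr, nc)
    xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
  } else {
    mask <- mask > 0
    if (!all(dim(mask) == c(nr, nc))) {
      stop("`mask` must match `shape_px`", call. = FALSE)
    }
  }
  mask_px <- sum(mask)
  if (mask_px == 0) stop("empty cell mask", call. = FALSE)
  cell_area <- mask_px * pixel_size_um^2
  if (punctum_area_um2 >= cell_area) {
    stop("punctum larger than the cell mask", call. = FALSE)
  }

  r_px <- sqrt(punctum_area_um2 / pi) / pixel_size_um
  min_sep <- min_separation_px %||% (2 * r_px + 2)

  placed <- with_fixed_seed(seed, {
    centres <- matrix(numeric(0), ncol = 2)
    candidates <- which(mask, arr.ind = TRUE)
    tries <- 0L
    while (nrow(centres) < n_puncta) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("could not place all puncta without overlap; reduce n_puncta",
             call. = FALSE)
      }
      k <- sample.int(nrow(candidates), 1L)
      cy0 <- candidates[k, 1] + stats::runif(1, -0.5, 0.5)
      cx0 <- candidates[k, 2] + stats::runif(1, -0.5, 0.5)
      # disc must sit fully inside the mask (checked on the bounding square)
      ys <- max(1L, floor(cy0 - r_px)):min(nr, ceiling(cy0 + r_px))
      xs <- max(1L, floor(cx0 - r_px)):min(nc, ceiling(cx0 + r_px))
      sub <- expand.grid(y = ys, x = xs)
      inside <- (sub$y - cy0)^2 + (sub$x - cx0)^2 <= r_px^2
      if (any(!mask[cbind(sub$y, sub$x)][inside])) next
      if (nrow(centres) > 0 &&
          min((centres[, 1] - cy0)^2 + (centres[, 2] - cx0)^2) < min_sep^2) next
      centres <- rbind(centres, c(cy0, cx0))
    }
    noise <- matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
    list(centres = centres, noise = noise)
  })

  img <- matrix(background_level, nr, nc)
  if (n_puncta > 0) {
    yy <- matrix(seq_len(nr), nr, nc)
    xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(n_puncta)) {
      disc <- (yy - placed$centres[i, 1])^2 + (xx - placed$centres[i, 2])^2 <= r_px^2
      img[disc] <- background_level + punctum_amplitude
    }
  }
  if (psf_sigma_px > 0) {
    img <- EBImage::imageData(EBImage::gblur(EBImage::as.Image(img),
                                             sigma = psf_sigma_px))
  }
  img <- img + placed$noise

  truth <- tibble::tibble(
    punctum = seq_len(n_puncta),
    y_px = if (n_puncta) placed$centres[, 1] else numeric(),
    x_px = if (n_puncta) placed$centres[, 2] else numeric(),
    area_um2 = rep(punctum_area_um2, n_puncta)
  )
  attr(truth, "coverage_fraction") <- n_puncta * punctum_area_um2 / cell_area
  attr(truth, "cell_area_um2") <- cell_area

  structure(list(
    image = img, mask = mask, pixel_size_um = pixel_size_um, truth = truth,
    params = list(n_puncta = n_puncta, punctum_area_um2 = punctum_area_um2,
                  psf_sigma_px = psf_sigma_px,
                  background_level = background_level,
                  punctum_amplitude = punctum_amplitude, noise_sd = noise_sd,
                  seed = as.integer(seed), rng = "Mersenne-Twister/Inversion")
  ), class = "tirf_image")
}

#' Segment fluorescent puncta in a TIRF image
#'
#' Estimates the background within the cell footprint, thresholds the image,
#' groups suprathreshold pixels by 8-connected components, removes components
#' below a minimum pixel area, and reports per-punctum areas (um^2),
#' centroids and mean intensities plus the fractional coverage of the
#' footprint. The default threshold is `median + k * MAD` of the in-mask
#' intensities (robust to the puncta themselves); Otsu's method on the
#' in-mask histogram is available as an alternative.
#'
#' @param image A `tirf_image` object, or a numeric matrix.
#' @param mask Logical matrix footprint (taken from `image` when it is a
#'   `tirf_image`).
#' @param pixel_size_um Pixel size (taken from `image` when possible).
#' @param method `"mad"` (default) or `"otsu"`.
#' @param k_mad Multiplier for the MAD threshold (default 5).
#' @param min_area_px Minimum component size in pixels (default 4),
#'   suppressing shot-noise singletons.
#' @return An object of class `puncta_set`: list with `puncta` (tibble:
#'   `label`, `area_um2`, `y_px`, `x_px`, `mean_intensity`),
#'   `coverage_fraction` (clipped at 1), `cell_area_um2`, `threshold`,
#'   `pixel_size_um`, `n_removed_small`.
#' @export
segment_puncta <- function(image, mask = NULL, pixel_size_um = NULL,
                           method = c("mad", "otsu"), k_mad = 5,
                           min_area_px = 4) {
  method <- match.arg(method)
  if (inherits(image, "tirf_image")) {
    mask <- mask %||% image$mask
    pixel_size_um <- pixel_size_um %||% image$pixel_size_um
    image <- image$image
  }
  stopifnot(is.matrix(image), is.matrix(mask) || is.logical(mask),
            all(dim(image) == dim(mask)), pixel_size_um > 0)
  mask <- mask > 0
  if (!any(mask)) stop("empty cell mask", call. = FALSE)

  vals <- image[mask]
  saturated <- mean(vals == max(vals)) > 0.01 && length(unique(vals)) > 2
  if (saturated) warning("image looks saturated inside the mask", call. = FALSE)

  if (method == "mad") {
    thr <- stats::median(vals) + k_mad * stats::mad(vals)
  } else {
    rng <- range(vals)
    scaled <- (image - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    thr01 <- EBImage::otsu(EBImage::as.Image(scaled * as.numeric(mask)))
    thr <- rng[1] + thr01 * (rng[2] - rng[1])
  }

  fg <- image > thr & mask
  lab <- label_components8(fg)
  n_lab <- max(lab)
  puncta <- tibble::tibble(label = integer(), area_um2 = numeric(),
                           y_px = numeric(), x_px = numeric(),
                           mean_intensity = numeric())
  n_removed <- 0L
  if (n_lab > 0) {
    idx <- which(lab > 0)
    l <- lab[idx]
    sz <- tabulate(l, n_lab)
    keep <- which(sz >= min_area_px)
    n_removed <- n_lab - length(keep)
    if (length(keep) > 0) {
      rc <- arrayInd(idx, dim(lab))
      kmap <- match(l, keep)
      ok <- !is.na(kmap)
      puncta <- tibble::tibble(
        label = seq_along(keep),
        area_um2 = sz[keep] * pixel_size_um^2,
        y_px = as.numeric(tapply(rc[ok, 1], kmap[ok], mean)),
        x_px = as.numeric(tapply(rc[ok, 2], kmap[ok], mean)),
        mean_intensity = as.numeric(tapply(image[idx][ok], kmap[ok], mean))
      )
    }
  }
  cell_area <- sum(mask) * pixel_size_um^2
  structure(list(
    puncta = puncta,
    coverage_fraction = min(1, sum(puncta$area_um2) / cell_area),
    cell_area_um2 = cell_area,
    threshold = thr,
    pixel_size_um = pixel_size_um,
    n_removed_small = n_removed
  ), class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf(
    "<puncta_set> %d puncta, coverage %.2f%% of %.1f um^2 (threshold %.3g)\n",
    nrow(x$puncta), 100 * x$coverage_fraction, x$cell_area_um2, x$threshold))
  invisible(x)
}

# 8-connected component labelling of a logical matrix (breadth-first flood
# fill over foreground pixels). Written here because the installed image
# packages only provide 4-connected labelling and the punctum counting
# convention is fixed at 8-connectivity.
#' @noRd
label_components8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  todo <- which(fg)
  if (length(todo) == 0) return(lab)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  cur <- 0L
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    lab[start] <- cur
    while (length(frontier) > 0) {
      rows <- ((frontier - 1L) %% nr) + 1L
      nbrs <- rep(frontier, each = 8L) + rep(offs, length(frontier))
      nbr_row_ok <- rep(rows, each = 8L) +
        rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L), length(frontier))
      ok <- nbrs >= 1L & nbrs <= nr * nc & nbr_row_ok >= 1L & nbr_row_ok <= nr
      nbrs <- unique(nbrs[ok])
      nbrs <- nbrs[fg[nbrs] & lab[nbrs] == 0L]
      lab[nbrs] <- cur
      frontier <- nbrs
    }
  }
  lab
}

#' Multi-channel intensity profile along a line
#'
#' Samples one or several co-registered channels along a straight line with
#' bilinear interpolation, averaging over `width_px` parallel lines offset
#' perpendicular to it. All channels share an identical sampling grid, so
#' profiles are directly comparable across channels (as when profiling
#' juxtaposed clusters of different proteins).
#'
#' Coordinates are `c(x, y)` in pixel units, `x` = column, `y` = row, with
#' pixel centres at integers (1-based).
#'
#' @param images A numeric matrix or a named list of same-sized matrices.
#' @param from,to Line endpoints `c(x, y)`; must lie inside the image(s).
#' @param width_px Odd number of parallel 1 px-spaced lines to average.
#' @param spacing_px Sampling interval along the line (default 0.5 px).
#' @param pixel_size_um Optional; adds a `position_um` column.
#' @return A tibble with `position_px` (distance along the line), optionally
#'   `position_um`, and one intensity column per channel.
#' @export
line_profile <- function(images, from, to, width_px = 1, spacing_px = 0.5,
                         pixel_size_um = NULL) {
  if (is.matrix(images)) images <- list(intensity = images)
  stopifnot(is.list(images), length(images) >= 1,
            width_px >= 1, width_px %% 2 == 1, spacing_px > 0)
  dims <- dim(images[[1]])
  for (im in images) stopifnot(is.matrix(im), all(dim(im) == dims))
  from <- as.numeric(from); to <- as.numeric(to)
  len <- sqrt(sum((to - from)^2))
  if (len == 0) stop("zero-length profile line", call. = FALSE)
  inside <- function(p) p[1] >= 1 && p[1] <= dims[2] && p[2] >= 1 && p[2] <= dims[1]
  if (!inside(from) || !inside(to)) {
    stop("line endpoints must lie inside the image", call. = FALSE)
  }
  u <- (to - from) / len                 # along-line unit vector
  v <- c(-u[2], u[1])                    # perpendicular
  pos <- seq(0, len, by = spacing_px)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)

  bilinear <- function(im, x, y) {
    x <- pmin(pmax(x, 1), dims[2]); y <- pmin(pmax(y, 1), dims[1])
    x0 <- pmin(floor(x), dims[2] - 1); y0 <- pmin(floor(y), dims[1] - 1)
    fx <- x - x0; fy <- y - y0
    im[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      im[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      im[cbind(y0 + 1, x0)] * (1 - fx) * fy +
      im[cbind(y0 + 1, x0 + 1)] * fx * fy
  }

  out <- tibble::tibble(position_px = pos)
  if (!is.null(pixel_size_um)) out$position_um <- pos * pixel_size_um
  for (ch in names(images)) {
    acc <- 0
    for (o in offs) {
      x <- from[1] + pos * u[1] + o * v[1]
      y <- from[2] + pos * u[2] + o * v[2]
      acc <- acc + bilinear(images[[ch]], x, y)
    }
    out[[ch]] <- acc / length(offs)
  }
  out
}
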