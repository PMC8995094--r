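# Readers and writers for the package's plain-text exchange formats.
# CSV dialect: UTF-8, comma separator, '.' decimal, mandatory header row.
# File-level metadata travels in '#key,value' comment lines above the header.

#' Write / read membrane trace CSV
#'
#' One row per trace vertex (`structure_id`, `membrane`, `x_nm`, `y_nm`,
#' `condition`, `tether`), with `pixel_size_nm` stored in a `#`-comment
#' header line. Reading recovers the vertex table and the calibration
#' attribute, so write/read round-trips are lossless.
#'
#' @param traces Vertex-level tibble (e.g. from [simulate_trace_pair()]).
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns the vertex tibble with attribute `pixel_size_nm`.
#' @export
write_trace_csv <- function(traces, path) {
  px <- attr(traces, "pixel_size_nm") %||% 0.5
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#pixel_size_nm,%.17g", px), con)
  utils::write.csv(as.data.frame(traces)[, intersect(
    c("structure_id", "membrane", "x_nm", "y_nm", "condition", "tether"),
    names(traces))], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 5)
  px <- 0.5
  meta <- grep("^#", hdr, value = TRUE)
  for (m in meta) {
    kv <- strsplit(sub("^#", "", m), ",")[[1]]
    if (kv[1] == "pixel_size_nm") px <- as.numeric(kv[2])
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(out, "pixel_size_nm") <- px
  out
}

#' Write / read structure-level morphometry CSV
#'
#' One row per cortical-ER structure with all morphometric fields.
#' @param structures Structure-level tibble.
#' @param path File path.
#' @export
write_structures_csv <- function(structures, path) {
  readr::write_csv(structures, path)
  invisible(path)
}

#' @rdname write_structures_csv
#' @export
read_structures_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a Fura-2 recording (CSV + events sidecar JSON)
#'
#' The intensity table goes to `path` in long format (`time_s`, `roi_id`,
#' `channel`, `value`); protocol event times and the frame interval go to a
#' JSON sidecar `<path>.events.json`. Reading reassembles a
#' [fura2_recording()].
#'
#' @param rec A `fura2_recording`.
#' @param path CSV file path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "fura2_recording"))
  readr::write_csv(rec$data, path)
  jsonlite::write_json(
    list(events = as.list(rec$events), frame_interval_s = rec$frame_interval_s),
    paste0(path, ".events.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  side <- paste0(path, ".events.json")
  if (!file.exists(side)) stop("missing events sidecar: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  fura2_recording(d, events = unlist(meta$events),
                  frame_interval_s = meta$frame_interval_s)
}

#' Write / read a TIRF image as TIFF
#'
#' Thin wrappers over the tiff package; intensities are stored as 32-bit
#' floats scaled to `[0, 1]` by `scale` (default: the image maximum,
#' recorded in nothing — pass an explicit scale for lossless round-trips).
#'
#' @param image Numeric matrix.
#' @param path TIFF path.
#' @param scale Intensity corresponding to 1.0 in the file.
#' @export
write_tirf_tiff <- function(image, path, scale = max(image)) {
  stopifnot(is.matrix(image), scale > 0)
  tiff::writeTIFF(pmin(pmax(image / scale, 0), 1), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_tirf_tiff
#' @export
read_tirf_tiff <- function(path, scale = 1) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * scale
}

#' Write a puncta set (CSV + JSON summary)
#' @param ps A [segment_puncta()] result.
#' @param path CSV path for the per-punctum table; a `<path>.summary.json`
#'   sidecar receives coverage, cell area and threshold.
#' @export
write_puncta_csv <- function(ps, path) {
  stopifnot(inherits(ps, "puncta_set"))
  readr::write_csv(ps$puncta, path)
  jsonlite::write_json(
    list(coverage_fraction = ps$coverage_fraction,
         cell_area_um2 = ps$cell_area_um2,
         threshold = ps$threshold,
         pixel_size_um = ps$pixel_size_um,
         n_removed_small = ps$n_removed_small),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
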