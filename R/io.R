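# Standard-format I/O: multi-page 8-bit TIFF stacks with a JSON metadata
# sidecar (frame interval, start time, pixel size), ROI JSON, and ground
# truth JSON. TIFF tag conventions vary too much across acquisition
# software to rely on, so calibration always travels in the sidecar.

default_metadata <- function() {
  list(frame_interval = 2, t_start = 240, pixel_size = 0.15)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Save a time-lapse stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are written as 8-bit grey levels; the temporal and spatial
#' calibration goes into `<stem>.json` next to the TIFF.
#'
#' @param stack a [time_lapse_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  pages <- lapply(seq_len(n_frames(stack)),
                  function(f) clip8(stack$frames[, , f]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(frame_interval = stack$frame_interval, t_start = stack$t_start,
               pixel_size = stack$pixel_size)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a time-lapse stack from a multi-page TIFF
#'
#' Frames are read in acquisition order. Calibration metadata is taken from
#' the JSON sidecar `<stem>.json` when present, else from the `metadata`
#' argument, else from the package defaults (2 min/frame from 240 min,
#' 0.15 µm/px) with a warning.
#'
#' @param path TIFF path.
#' @param metadata optional list overriding any of `frame_interval`,
#'   `t_start`, `pixel_size`.
#' @return a [time_lapse_stack()].
#' @export
load_stack <- function(path, metadata = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("cannot read stack: '", path, "' is missing or empty")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1) stop("mixed frame shapes in '", path, "'")
  frames <- array(0, dim = c(dims[[1]][1], dims[[1]][2], length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- round(pages[[f]] * 255)
  meta <- default_metadata()
  sc <- sidecar_path(path)
  from_file <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  if (is.null(from_file) && is.null(metadata)) {
    warning("no metadata sidecar for '", path, "'; using defaults ",
            "(2 min/frame from 240 min, 0.15 um/px)")
  }
  for (nm in names(meta)) {
    meta[[nm]] <- metadata[[nm]] %||% from_file[[nm]] %||% meta[[nm]]
  }
  time_lapse_stack(frames, meta$frame_interval, meta$t_start, meta$pixel_size)
}

#' Save cell ROIs as JSON
#' @param rois list of [cell_roi()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_rois <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    list(id = r$id, role = r$role, polygon = r$polygon,
         axis = list(ventral = r$axis$ventral, dorsal = r$axis$dorsal),
         leading_edge = r$leading_edge)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load cell ROIs from JSON
#' @param path JSON path written by [save_rois()].
#' @return named list of [cell_roi()].
#' @export
load_rois <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(payload, function(r) {
    cell_roi(id = r$id, role = r$role, polygon = r$polygon,
             axis = list(ventral = unlist(r$axis$ventral),
                         dorsal = unlist(r$axis$dorsal)),
             leading_edge = list(row = r$leading_edge$row,
                                 col_start = r$leading_edge$col_start,
                                 col_end = r$leading_edge$col_end))
  })
  stats::setNames(rois, vapply(rois, function(r) r$id, character(1)))
}
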