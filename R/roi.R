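#' Cell region of interest
#'
#' A cell's spatial footprint plus the two geometric references every
#' measurement anchors on: the ventral-dorsal axis (a directed segment from
#' the ventral to the dorsal edge of the cell) and the leading-edge segment
#' (the ventral boundary from which protrusions extend). All coordinates are
#' 1-based pixel indices with row 1 = dorsal-most (image top); the row index
#' increases ventrally.
#'
#' @param id cell identifier (character).
#' @param role one of `"leading-cell"`, `"pocket-cell"`, `"other"`.
#' @param polygon data.frame/list with numeric `row`, `col`: vertices of a
#'   simple polygon tracing the footprint.
#' @param axis list with `ventral = c(row, col)` and `dorsal = c(row, col)`;
#'   the profile is sampled from `ventral` to `dorsal`.
#' @param leading_edge list with `row`, `col_start`, `col_end`: the ventral
#'   boundary segment.
#' @return object of class `cell_roi`.
#' @export
cell_roi <- function(id, role = c("leading-cell", "pocket-cell", "other"),
                     polygon, axis, leading_edge) {
  role <- match.arg(role)
  polygon <- as.data.frame(polygon)
  stopifnot(all(c("row", "col") %in% names(polygon)), nrow(polygon) >= 3)
  stopifnot(is.list(axis), length(axis$ventral) == 2L, length(axis$dorsal) == 2L)
  if (all(axis$ventral == axis$dorsal)) stop("degenerate ventral-dorsal axis")
  structure(list(id = as.character(id), role = role, polygon = polygon,
                 axis = axis, leading_edge = leading_edge),
            class = "cell_roi")
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf("cell_roi '%s' (%s): %d-vertex footprint, axis (%g,%g)->(%g,%g)\n",
              x$id, x$role, nrow(x$polygon),
              x$axis$ventral[1], x$axis$ventral[2],
              x$axis$dorsal[1], x$axis$dorsal[2]))
  invisible(x)
}

# Even-odd scanline polygon fill; returns logical H x W mask.
#' @keywords internal
#' @noRd
rasterize_polygon <- function(polygon, dim_hw) {
  H <- dim_hw[1]; W <- dim_hw[2]
  ry <- polygon$row; cx <- polygon$col
  n <- length(ry)
  mask <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      y1 <- ry[i]; y2 <- ry[j]
      if ((y1 <= r && y2 > r) || (y2 <= r && y1 > r)) {
        xs <- c(xs, cx[i] + (r - y1) / (y2 - y1) * (cx[j] - cx[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c1 <- max(1L, ceiling(xs[k])); c2 <- min(W, floor(xs[k + 1]))
        if (c1 <= c2) mask[r, c1:c2] <- TRUE
      }
    }
  }
  mask
}

#' Footprint mask of a cell ROI
#'
#' Rasterizes the footprint polygon onto the frame grid.
#'
#' @param roi a [cell_roi()].
#' @param dim_hw `c(H, W)` frame size in pixels.
#' @return logical `H x W` matrix, `TRUE` inside the footprint.
#' @export
roi_mask <- function(roi, dim_hw) {
  rasterize_polygon(roi$polygon, dim_hw)
}

#' Embryo mask from a set of ROIs
#'
#' Union of all footprint polygons, used to exclude embryo pixels when
#' estimating the camera background.
#'
#' @param rois list of [cell_roi()].
#' @param dim_hw `c(H, W)` frame size in pixels.
#' @param dilate_rows rows added ventrally below each footprint so the
#'   protrusion zone just beyond the front is also excluded.
#' @return logical `H x W` matrix, `TRUE` on embryo pixels.
#' @export
embryo_mask <- function(rois, dim_hw, dilate_rows = 8) {
  mask <- matrix(FALSE, dim_hw[1], dim_hw[2])
  for (roi in rois) {
    m <- roi_mask(roi, dim_hw)
    if (dilate_rows > 0) {
      cols <- which(apply(m, 2, any))
      for (cc in cols) {
        bottom <- max(which(m[, cc]))
        m[bottom:min(dim_hw[1], bottom + dilate_rows), cc] <- TRUE
      }
    }
    mask <- mask | m
  }
  mask
}

# Rectangle helper used by the generator and by tests.
#' @keywords internal
#' @noRd
rect_polygon <- function(row_top, row_bottom, col_left, col_right) {
  data.frame(row = c(row_top - 0.5, row_top - 0.5, row_bottom + 0.5, row_bottom + 0.5),
             col = c(col_left - 0.5, col_right + 0.5, col_right + 0.5, col_left - 0.5))
}
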