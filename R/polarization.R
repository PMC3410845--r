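# Leading-edge F-actin quantitation: preprocessing, ROI intensity,
# ventral-dorsal line profiles, threshold peak counting, half assignment,
# the 20-frame ventral:dorsal polarization ratio, and the enrichment-offset
# measurement.

#' Linear contrast stretch of a stack
#'
#' Camera background is pushed to the lowest grey levels by a single linear
#' map applied identically to all frames: the stack's low anchor (default
#' 1st percentile) maps to 0 and the high anchor (99th percentile) to 255,
#' with clipping and rounding to 8-bit levels. The map is monotone, so pixel
#' ordering is preserved up to rounding.
#'
#' @param stack a [time_lapse_stack()].
#' @param lower,upper anchor quantiles in \[0, 1\].
#' @return a stretched [time_lapse_stack()]. A constant stack is returned
#'   unchanged with a warning.
#' @export
contrast_stretch <- function(stack, lower = 0.01, upper = 0.99) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  v <- stats::quantile(stack$frames, c(lower, upper), names = FALSE)
  if (v[2] <= v[1]) {
    warning("constant stack: contrast stretch is the identity")
    return(stack)
  }
  stack$frames <- clip8((stack$frames - v[1]) / (v[2] - v[1]) * 255)
  stack
}

#' Estimate the camera background of a frame
#'
#' Modal grey level of the pixels outside the embryo mask (whole frame when
#' no mask is given). The mode is robust against the bright foreground and
#' matches the flat additive background of the camera model.
#'
#' @param frame intensity matrix.
#' @param mask optional logical matrix, `TRUE` on embryo pixels to exclude.
#' @return modal background intensity (grey levels). Ties take the lowest
#'   level.
#' @export
estimate_background <- function(frame, mask = NULL) {
  v <- if (is.null(mask)) frame else frame[!mask]
  if (!length(v)) stop("no background pixels to estimate from")
  v <- round(v)
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

#' Mean intensity in the leading-edge measurement box
#'
#' Arithmetic mean of a `box_px` x `box_px` window anchored on the leading
#' edge: the box is centered horizontally on the midpoint of the cell's
#' leading-edge segment and extends dorsally from the front row. With the
#' default 36-px box and 0.15 µm/px calibration the box covers about a
#' third of the cell length.
#'
#' @param frame intensity matrix.
#' @param roi a [cell_roi()].
#' @param box_px box side in pixels.
#' @param front_row row of the current protrusive front; defaults to the
#'   ROI's static leading-edge row (appropriate once migration is complete;
#'   pass the detected per-frame front for earlier time points).
#' @return mean intensity (grey levels).
#' @export
leading_edge_roi_mean <- function(frame, roi, box_px = 36, front_row = NULL) {
  front_row <- front_row %||% roi$leading_edge$row
  mid_col <- round((roi$leading_edge$col_start + roi$leading_edge$col_end) / 2)
  rows <- seq.int(front_row - box_px + 1L, front_row)
  cols <- seq.int(mid_col - floor((box_px - 1) / 2), mid_col + ceiling((box_px - 1) / 2))
  if (min(rows) < 1 || max(rows) > nrow(frame) ||
      min(cols) < 1 || max(cols) > ncol(frame)) {
    stop("measurement box for cell '", roi$id, "' exceeds the frame bounds")
  }
  mean(frame[rows, cols])
}

#' Line profile container
#'
#' Ordered intensity samples along a ventral-to-dorsal axis. Position 0 is
#' the ventral end; positions increase dorsally in 1-px steps.
#'
#' @param intensities numeric vector of sampled intensities (length >= 2).
#' @param pixel_size µm per pixel.
#' @return object of class `line_profile` with `positions_px`,
#'   `positions_um`, `intensities` and `cell_length_um` (axis span).
#' @export
line_profile <- function(intensities, pixel_size = 0.15) {
  if (length(intensities) < 2) stop("a line profile needs at least 2 samples")
  n <- length(intensities)
  structure(list(positions_px = 0:(n - 1),
                 positions_um = (0:(n - 1)) * pixel_size,
                 intensities = as.numeric(intensities),
                 cell_length_um = (n - 1) * pixel_size,
                 pixel_size = pixel_size),
            class = "line_profile")
}

#' Extract the ventral-to-dorsal intensity profile of a cell
#'
#' Samples the frame along the ROI's ventral-dorsal axis at 1-px steps by
#' bilinear interpolation, ordered from the ventral end to the dorsal end.
#'
#' @param frame intensity matrix.
#' @param roi a [cell_roi()].
#' @param pixel_size µm per pixel (use the stack's calibration).
#' @return a [line_profile()].
#' @export
extract_vd_profile <- function(frame, roi, pixel_size = 0.15) {
  v <- roi$axis$ventral; d <- roi$axis$dorsal
  len <- sqrt(sum((d - v)^2))
  if (len < 2) stop("ventral-dorsal axis shorter than 2 px")
  t <- 0:floor(len)
  rows <- v[1] + t / len * (d[1] - v[1])
  cols <- v[2] + t / len * (d[2] - v[2])
  line_profile(bilinear_sample(frame, rows, cols), pixel_size)
}

#' Count intensity peaks along a profile
#'
#' A peak is a maximal contiguous run of profile positions whose intensity
#' is at least `background + threshold` (inclusive); one run is one peak
#' regardless of internal structure. The apex is the run maximum (the most
#' ventral position on ties).
#'
#' @param profile a [line_profile()].
#' @param background background intensity (grey levels).
#' @param threshold grey levels above background required for a peak
#'   (default 10).
#' @return data.frame of class `peak_set` with columns `start`, `end`
#'   (1-based profile indices), `apex_idx`, `apex_um` (from the ventral
#'   end), `apex_height`. Zero rows when nothing exceeds the threshold.
#' @export
detect_peaks <- function(profile, background, threshold = 10) {
  stopifnot(inherits(profile, "line_profile"), threshold > 0)
  above <- profile$intensities >= background + threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$apex_idx <- vapply(seq_len(nrow(out)), function(i) {
    seg <- profile$intensities[out$start[i]:out$end[i]]
    out$start[i] + which.max(seg) - 1L
  }, integer(1))
  out$apex_um <- profile$positions_um[out$apex_idx]
  out$apex_height <- profile$intensities[out$apex_idx]
  class(out) <- c("peak_set", class(out))
  out
}

#' Assign peaks to the ventral or dorsal half of the cell
#'
#' A peak belongs to the half that contains its apex; an apex exactly at
#' half the cell's length counts as ventral (a documented tie rule).
#'
#' @param peaks a `peak_set` from [detect_peaks()].
#' @param profile the [line_profile()] the peaks came from.
#' @return list with `ventral` and `dorsal` counts and `peaks` (the input
#'   with a `half` column added).
#' @export
assign_halves <- function(peaks, profile) {
  mid <- profile$cell_length_um / 2
  half <- ifelse(peaks$apex_um <= mid, "ventral", "dorsal")
  peaks$half <- half
  list(ventral = sum(half == "ventral"), dorsal = sum(half == "dorsal"),
       peaks = peaks)
}

#' Ventral:dorsal polarization ratio over a frame window
#'
#' Applies [detect_peaks()] and [assign_halves()] to the cell's
#' ventral-dorsal profile in each frame of a window (default 20 frames =
#' 40 minutes at 2-minute sampling, starting at leading-edge enrichment),
#' sums the per-frame half counts, and divides total ventral by total
#' dorsal count.
#'
#' @param stack a [time_lapse_stack()].
#' @param roi a [cell_roi()].
#' @param start_frame first frame of the window (1-based).
#' @param n_frames window length in frames.
#' @param threshold peak threshold in grey levels above background.
#' @param background fixed background intensity; when `NULL` it is
#'   estimated per frame with [estimate_background()] using `mask`.
#' @param mask optional embryo mask for background estimation.
#' @return list of class `vd_ratio_result`: `n_frames`, `n_ventral`,
#'   `n_dorsal`, `ratio` (`NA` with `undefined = TRUE` when the dorsal
#'   total is zero).
#' @export
vd_ratio_over_window <- function(stack, roi, start_frame, n_frames = 20,
                                 threshold = 10, background = NULL,
                                 mask = NULL) {
  Tn <- dim(stack$frames)[3]
  if (start_frame < 1 || start_frame + n_frames - 1 > Tn) {
    stop("window [", start_frame, ", ", start_frame + n_frames - 1,
         "] out of range for a ", Tn, "-frame stack")
  }
  nv <- 0L; nd <- 0L
  for (f in seq.int(start_frame, start_frame + n_frames - 1L)) {
    frame <- stack$frames[, , f]
    bg <- background %||% estimate_background(frame, mask)
    prof <- extract_vd_profile(frame, roi, stack$pixel_size)
    h <- assign_halves(detect_peaks(prof, bg, threshold), prof)
    nv <- nv + h$ventral; nd <- nd + h$dorsal
  }
  structure(list(n_frames = n_frames, n_ventral = nv, n_dorsal = nd,
                 ratio = if (nd > 0) nv / nd else NA_real_,
                 undefined = nd == 0L),
            class = "vd_ratio_result")
}

#' @export
print.vd_ratio_result <- function(x, ...) {
  cat(sprintf("V:D peak ratio over %d frames: %d ventral / %d dorsal = %s\n",
              x$n_frames, x$n_ventral, x$n_dorsal,
              if (x$undefined) "undefined (no dorsal peaks)" else
                format(x$ratio, digits = 4)))
  invisible(x)
}

#' Distance from the protrusive front to the intensity apex
#'
#' Along the cell's ventral-dorsal profile, the front is the ventral-most
#' position whose intensity is strictly above background, and the apex is
#' the profile's global maximum. The offset is the distance from front to
#' apex in µm (how far "behind" the front the highest F-actin enrichment
#' sits).
#'
#' @param frame intensity matrix.
#' @param roi a [cell_roi()].
#' @param background background intensity; when `NULL`, estimated from the
#'   frame with [estimate_background()] using `mask`.
#' @param pixel_size µm per pixel.
#' @param mask optional embryo mask for background estimation.
#' @return offset in µm (>= 0 when the apex is dorsal to the front).
#' @export
enrichment_offset <- function(frame, roi, background = NULL,
                              pixel_size = 0.15, mask = NULL) {
  bg <- background %||% estimate_background(frame, mask)
  prof <- extract_vd_profile(frame, roi, pixel_size)
  above <- which(prof$intensities > bg)
  if (!length(above)) stop("no above-background pixel on the axis of cell '",
                           roi$id, "'")
  front_idx <- min(above)
  apex_idx <- which.max(prof$intensities)
  prof$positions_um[apex_idx] - prof$positions_um[front_idx]
}

# Robust per-frame front row of a cell: the ventral-most (largest) row
# whose median intensity across the footprint's columns is at least
# `margin` grey levels above background. The median ignores the few bright
# protrusion columns, so the cell-body front is recovered even while
# protrusions extend beyond it.
#' @keywords internal
#' @noRd
front_row_of <- function(frame, roi, background, margin = 2.5) {
  cols <- seq.int(max(1L, floor(min(roi$polygon$col) + 0.5)),
                  min(ncol(frame), ceiling(max(roi$polygon$col) - 0.5)))
  med <- apply(frame[, cols, drop = FALSE], 1, stats::median)
  hit <- which(med >= background + margin)
  if (!length(hit)) return(NA_integer_)
  max(hit)
}
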