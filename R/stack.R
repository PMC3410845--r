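#' Time-lapse image stack
#'
#' The container quantified by every imaging operation: a `H x W x T` array
#' of grey-level intensities plus the temporal and spatial calibration.
#' Frame `i` (1-based) was acquired at `t_start + (i - 1) * frame_interval`
#' minutes after first cleavage. Row 1 is the dorsal-most image row; row
#' index increases ventrally.
#'
#' @param frames numeric array with dim `c(H, W, T)` (a single matrix is
#'   promoted to `T = 1`); values are 8-bit grey levels.
#' @param frame_interval minutes between frames (> 0).
#' @param t_start minutes after first cleavage at frame 1.
#' @param pixel_size µm per pixel.
#' @return object of class `time_lapse_stack`.
#' @export
time_lapse_stack <- function(frames, frame_interval = 2, t_start = 240,
                             pixel_size = 0.15) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] < 1) stop("stack must contain at least one frame")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(frames = frames, frame_interval = frame_interval,
                 t_start = t_start, pixel_size = pixel_size),
            class = "time_lapse_stack")
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "time_lapse_stack: %d frames of %d x %d px, %.3g min/frame from t = %g min, %.3g um/px\n",
    d[3], d[1], d[2], x$frame_interval, x$t_start, x$pixel_size))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [time_lapse_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Acquisition time of a frame
#' @param stack a [time_lapse_stack()].
#' @param frame 1-based frame index (vectorized).
#' @return minutes after first cleavage.
#' @export
frame_time <- function(stack, frame) {
  stack$t_start + (frame - 1) * stack$frame_interval
}

#' Frame index at or after a given time
#' @param stack a [time_lapse_stack()].
#' @param minutes time in minutes after first cleavage.
#' @return 1-based index of the first frame acquired at or after `minutes`.
#' @export
frame_at <- function(stack, minutes) {
  as.integer(ceiling((minutes - stack$t_start) / stack$frame_interval)) + 1L
}

#' Extract one frame as a matrix
#' @param stack a [time_lapse_stack()].
#' @param frame 1-based frame index.
#' @return `H x W` intensity matrix.
#' @export
get_frame <- function(stack, frame) {
  T <- n_frames(stack)
  if (frame < 1 || frame > T) stop("frame index out of range (1..", T, ")")
  stack$frames[, , frame]
}
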