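# Protrusion lifetime tracking and morphogenetic event timing.

# Per-frame protrusion instances of one cell: connected above-background
# components beyond the cell-body front that extend at least min_extent_px
# ventrally and are attached to the front (their dorsal-most pixel lies
# within attach_px rows of it).
#' @keywords internal
#' @noRd
protrusion_instances <- function(frame, roi, background, threshold = 10,
                                 min_extent_px = 3, max_reach_px = 12,
                                 attach_px = 3) {
  front <- front_row_of(frame, roi, background)
  if (is.na(front) || front >= nrow(frame)) {
    return(list(front = front, instances = list()))
  }
  rows <- seq.int(front + 1L, min(nrow(frame), front + max_reach_px))
  cols <- seq.int(max(1L, floor(min(roi$polygon$col) + 0.5)),
                  min(ncol(frame), ceiling(max(roi$polygon$col) - 0.5)))
  sub <- frame[rows, cols, drop = FALSE] >= background + threshold
  if (!any(sub)) return(list(front = front, instances = list()))
  lab <- EBImage::bwlabel(sub + 0)
  instances <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    rr <- rows[idx[, 1]]; cc <- cols[idx[, 2]]
    if (max(rr) - front >= min_extent_px && min(rr) <= front + attach_px) {
      instances[[length(instances) + 1L]] <-
        list(row_range = range(rr), col_range = range(cc),
             extent_px = max(rr) - front)
    }
  }
  list(front = front, instances = instances)
}

#' Detect and track leading-edge protrusions
#'
#' Per frame, connected components of above-background pixels extending at
#' least `min_extent_px` beyond the cell-body front (and attached to it) are
#' protrusion instances; instances in consecutive frames whose bounding
#' boxes overlap are linked into one track. A disappearance ends the track
#' (no gap tolerance): retraction is scored at first absence. A protrusion
#' seen in one frame lasts one frame interval, so
#' `duration = (last - first + 1) * frame_interval`.
#'
#' @param stack a [time_lapse_stack()].
#' @param roi a [cell_roi()].
#' @param min_extent_px minimum ventral extent beyond the front, in pixels.
#' @param threshold grey levels above background defining protrusion pixels.
#' @param background fixed background; when `NULL`, estimated per frame with
#'   [estimate_background()] using `mask`.
#' @param mask optional embryo mask for background estimation.
#' @return data.frame with one row per track: `cell`, `first_frame`,
#'   `last_frame`, `duration_min`, `max_extent_um`. Zero rows when the cell
#'   never protrudes.
#' @export
detect_protrusions <- function(stack, roi, min_extent_px = 3, threshold = 10,
                               background = NULL, mask = NULL) {
  Tn <- dim(stack$frames)[3]
  tracks <- list()        # finished tracks
  active <- list()        # each: list(first, last, inst, max_extent)
  for (f in seq_len(Tn)) {
    frame <- stack$frames[, , f]
    bg <- background %||% estimate_background(frame, mask)
    pi_f <- protrusion_instances(frame, roi, bg, threshold, min_extent_px)
    matched_active <- rep(FALSE, length(active))
    new_active <- list()
    for (inst in pi_f$instances) {
      hit <- 0L
      for (a in seq_along(active)) {
        if (matched_active[a]) next
        prev <- active[[a]]$inst
        if (prev$col_range[1] <= inst$col_range[2] &&
            inst$col_range[1] <= prev$col_range[2] &&
            prev$row_range[1] <= inst$row_range[2] &&
            inst$row_range[1] <= prev$row_range[2]) { hit <- a; break }
      }
      if (hit > 0L) {
        matched_active[hit] <- TRUE
        tr <- active[[hit]]
        tr$last <- f; tr$inst <- inst
        tr$max_extent <- max(tr$max_extent, inst$extent_px)
        new_active[[length(new_active) + 1L]] <- tr
      } else {
        new_active[[length(new_active) + 1L]] <-
          list(first = f, last = f, inst = inst, max_extent = inst$extent_px)
      }
    }
    for (a in seq_along(active)) {
      if (!matched_active[a]) tracks[[length(tracks) + 1L]] <- active[[a]]
    }
    active <- new_active
  }
  tracks <- c(tracks, active)
  if (!length(tracks)) {
    return(data.frame(cell = character(0), first_frame = integer(0),
                      last_frame = integer(0), duration_min = numeric(0),
                      max_extent_um = numeric(0)))
  }
  out <- data.frame(
    cell = roi$id,
    first_frame = vapply(tracks, function(t) t$first, integer(1)),
    last_frame = vapply(tracks, function(t) t$last, integer(1)),
    max_extent_um = vapply(tracks, function(t) t$max_extent, numeric(1)) *
      stack$pixel_size
  )
  out$duration_min <- (out$last_frame - out$first_frame + 1) * stack$frame_interval
  out <- out[order(out$first_frame, out$cell), ]
  rownames(out) <- NULL
  out[, c("cell", "first_frame", "last_frame", "duration_min", "max_extent_um")]
}

#' Mean protrusion duration
#'
#' Arithmetic mean of track durations in minutes, with the standard error
#' of the mean across tracks.
#'
#' @param tracks data.frame from [detect_protrusions()] (tracks from several
#'   movies may be row-bound before calling).
#' @return list with `mean_min`, `sem_min` (`NA` for a single track) and
#'   `n_tracks`.
#' @export
mean_protrusion_duration <- function(tracks) {
  if (is.null(tracks) || nrow(tracks) == 0) {
    stop("no protrusion tracks: mean duration is undefined")
  }
  d <- tracks$duration_min
  list(mean_min = mean(d),
       sem_min = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
       n_tracks = length(d))
}

#' Detect the four morphogenetic events of ventral enclosure
#'
#' Times, in minutes after first cleavage, of: the first pocket-cell
#' protrusion; leading-edge F-actin enrichment in a leading cell (first
#' frame where the leading-edge box mean reaches `enrichment_factor` times
#' the whole-cell mean); the first leading-cell protrusion; and the meeting
#' of the leading cells (front reaching the ventral meeting line). Events
#' that never occur in the movie are returned as `NA`, not errors.
#'
#' @param stack a [time_lapse_stack()].
#' @param rois list of [cell_roi()] including at least one pocket cell and
#'   the leading cells.
#' @param enrichment_factor leading-edge-to-whole-cell mean ratio declaring
#'   enrichment (the literature gives no numeric criterion; 1.2 is the
#'   package default).
#' @param meeting_row ventral meeting line (row); defaults to the ventral
#'   boundary of the leading-cell footprints.
#' @param box_px leading-edge box side in pixels.
#' @param threshold protrusion threshold in grey levels above background.
#' @param min_extent_px minimum protrusion extent in pixels.
#' @param mask optional embryo mask; defaults to the union of the ROI
#'   footprints.
#' @return object of class `event_timeline`: named list with
#'   `t_pocket_protrusion`, `t_lc_enrichment`, `t_lc_protrusion`,
#'   `t_lc_meeting` (minutes, `NA` when missing).
#' @export
detect_events <- function(stack, rois, enrichment_factor = 1.2,
                          meeting_row = NULL, box_px = 36, threshold = 10,
                          min_extent_px = 3, mask = NULL) {
  roles <- vapply(rois, function(r) r$role, character(1))
  if (!any(roles == "pocket-cell") || !any(roles == "leading-cell")) {
    stop("detect_events needs at least one pocket cell and one leading cell")
  }
  dim_hw <- dim(stack$frames)[1:2]
  mask <- mask %||% embryo_mask(rois, dim_hw)
  Tn <- dim(stack$frames)[3]
  lcs <- rois[roles == "leading-cell"]
  pockets <- rois[roles == "pocket-cell"]
  meeting_row <- meeting_row %||%
    max(vapply(lcs, function(r) floor(max(r$polygon$row)), numeric(1)))

  first_track_frame <- function(cells) {
    firsts <- unlist(lapply(cells, function(r) {
      tr <- detect_protrusions(stack, r, min_extent_px = min_extent_px,
                               threshold = threshold, mask = mask)
      tr$first_frame
    }))
    if (length(firsts)) min(firsts) else NA_integer_
  }
  f_pocket <- first_track_frame(pockets)
  f_lcprot <- first_track_frame(lcs)

  f_enrich <- NA_integer_
  f_meet <- NA_integer_
  for (f in seq_len(Tn)) {
    frame <- stack$frames[, , f]
    bg <- estimate_background(frame, mask)
    for (r in lcs) {
      front <- front_row_of(frame, r, bg)
      if (is.na(front)) next
      if (is.na(f_meet) && front >= meeting_row) f_meet <- f
      if (is.na(f_enrich)) {
        box_mean <- leading_edge_roi_mean(frame, r, box_px, front_row = front)
        fp <- roi_mask(r, dim_hw)
        fp[seq_len(nrow(fp)) > front, ] <- FALSE
        if (box_mean >= enrichment_factor * mean(frame[fp])) f_enrich <- f
      }
    }
    if (!is.na(f_enrich) && !is.na(f_meet)) break
  }

  t_of <- function(f) if (is.na(f)) NA_real_ else frame_time(stack, f)
  structure(list(t_pocket_protrusion = t_of(f_pocket),
                 t_lc_enrichment = t_of(f_enrich),
                 t_lc_protrusion = t_of(f_lcprot),
                 t_lc_meeting = t_of(f_meet)),
            class = "event_timeline")
}

#' @export
print.event_timeline <- function(x, ...) {
  cat("event_timeline (min after first cleavage):\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm,
                                   if (is.na(x[[nm]])) "missing" else x[[nm]]))
  invisible(x)
}

#' Event times relative to pocket-protrusion onset
#'
#' Re-expresses an [detect_events()] timeline with time 0 at the first
#' pocket-cell protrusion, the conventional reference point for comparing
#' genotypes.
#'
#' @param timeline an `event_timeline`.
#' @return named numeric vector of minutes since pocket-protrusion onset
#'   (`NA` entries stay `NA`).
#' @export
event_intervals <- function(timeline) {
  t0 <- timeline$t_pocket_protrusion
  if (is.na(t0)) stop("pocket-protrusion onset is missing: intervals undefined")
  vapply(timeline, function(t) t - t0, numeric(1))
}
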