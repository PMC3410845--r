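# Synthetic enclosure-movie generator.
#
# Lateral-view simplification: a horizontal epidermal band whose ventral
# (leading) edge advances down the image. Two leading cells (LCs) sit
# anteriorly (left), two pocket cells posteriorly. Row index increases
# ventrally; "meeting" of the leading edge is the front crossing a fixed
# ventral meeting line. All structure placed by the generator is recorded in
# a ground-truth object so every measurement operation can be tested against
# what was actually rendered.

# Fixed embryo layout (pixels, 1-based). Cell length 107 px = 16.05 um at
# the default 0.15 um/px, so the 36-px measurement box spans about a third
# of the cell.
movie_layout <- function() {
  cells <- data.frame(
    id = c("lc1", "lc2", "pocket1", "pocket2"),
    role = c("leading-cell", "leading-cell", "pocket-cell", "pocket-cell"),
    col_left = c(14L, 54L, 94L, 134L),
    col_right = c(53L, 93L, 133L, 173L),
    stringsAsFactors = FALSE
  )
  cells$axis_col <- round((cells$col_left + cells$col_right) / 2)
  list(cells = cells, band_top = 21L, front0 = 128L, meet_row = 150L,
       site_offset = 10L, protrusion_extent = 6L, mid_row = 85.5,
       puncta_amplitude = 40, ridge_amplitudes = c(95, 110, 125, 110, 95),
       baseline_offset = 5)
}

# First 1-based frame index at or after an absolute time; NA propagates.
event_frame <- function(t_event, t_start, frame_interval) {
  if (is.na(t_event)) return(NA_integer_)
  max(1L, as.integer(ceiling((t_event - t_start) / frame_interval)) + 1L)
}

# Two-point integer frame-lifetime draw whose mean (in minutes) equals the
# preset mean exactly: frames in {floor(m), ceiling(m)} with
# P(ceiling) = m - floor(m), m = mean_duration / frame_interval.
draw_lifetime_frames <- function(n, mean_duration, frame_interval) {
  m <- mean_duration / frame_interval
  lo <- floor(m)
  lo + stats::rbinom(n, 1L, m - lo)
}

# Schedule protrusion episodes for one site: first episode starts exactly at
# the window-start frame (that is what event detection times), later
# episodes follow after a >= 1 frame retraction gap. Episodes are only
# started at frames from which the longest possible lifetime still fits
# inside the movie, so the realized lifetimes are an unbiased sample.
schedule_site <- function(first_frame, n_frames, mean_duration, frame_interval) {
  m <- mean_duration / frame_interval
  hi <- ceiling(m)
  last_start <- n_frames - (hi - 1L)
  first <- integer(0); last <- integer(0)
  t <- first_frame
  while (!is.na(t) && t <= last_start) {
    L <- draw_lifetime_frames(1L, mean_duration, frame_interval)
    first <- c(first, t); last <- c(last, t + L - 1L)
    t <- t + L + 1L + stats::rgeom(1L, 0.6)
  }
  data.frame(first_frame = first, last_frame = last)
}

# Greedy placement of puncta rows with a minimum separation, from a
# shuffled candidate list; returns at most n rows.
place_rows <- function(candidates, n, min_sep = 6L) {
  if (n <= 0L || !length(candidates)) return(integer(0))
  cand <- sample(candidates)
  chosen <- integer(0)
  for (r in cand) {
    if (length(chosen) == n) break
    if (!length(chosen) || all(abs(chosen - r) >= min_sep)) chosen <- c(chosen, r)
  }
  chosen
}

#' Generate a synthetic enclosure movie with ground truth
#'
#' Renders a seeded time-lapse movie of the enclosure stage: an epidermal
#' cell band whose leading (ventral) edge advances from LC-protrusion onset
#' until the leading cells meet the ventral line; disk-shaped F-actin puncta
#' placed along each leading cell's ventral-dorsal axis with a configurable
#' ventral bias; a leading-edge intensity ridge whose apex sits
#' `enrichment_offset` µm dorsal to the protrusive front from enrichment
#' onset onward; and finger-like protrusions beyond the front whose integer
#' frame-lifetimes follow a two-point distribution calibrated so the mean
#' lifetime in minutes equals the preset value exactly. Additive Gaussian
#' camera noise is applied last and clipped to 8-bit grey levels.
#'
#' Everything placed is recorded in a ground-truth object, so downstream
#' measurements (peak counts, V:D ratios, protrusion tracks, event times,
#' front positions) can be validated pixel for pixel.
#'
#' @param spec a [movie_spec()].
#' @return list with elements
#'   \describe{
#'     \item{stack}{[time_lapse_stack()] of rendered frames.}
#'     \item{ground_truth}{list with `event_times` (named minutes, `NA` when
#'       the event is never rendered), `protrusions` (data.frame `cell`,
#'       `site_col`, `first_frame`, `last_frame`), `peaks` (data.frame
#'       `frame`, `cell`, `row`, `col`, `half`), `front_row` (per-frame
#'       front row), and the layout.}
#'     \item{rois}{list of [cell_roi()] for the two leading cells and two
#'       pocket cells.}
#'   }
#' @examples
#' mv <- generate_movie(movie_spec("wild_type", n_frames = 5, seed = 1))
#' dim(mv$stack$frames)
#' @export
generate_movie <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  p <- spec$preset
  if (!is.na(p$mean_protrusion_duration) &&
      p$mean_protrusion_duration < spec$frame_interval) {
    stop("mean_protrusion_duration shorter than frame_interval cannot be realized")
  }
  lay <- movie_layout()
  H <- spec$height; W <- spec$width; Tn <- spec$n_frames
  bg <- spec$background_level
  base_off <- max(1, round(lay$baseline_offset * p$baseline_intensity_scale))
  offset_px <- round(p$enrichment_offset / spec$pixel_size)

  f_pocket <- event_frame(p$t_pocket_protrusion, spec$t_start, spec$frame_interval)
  f_enrich <- event_frame(p$t_lc_enrichment, spec$t_start, spec$frame_interval)
  f_lcprot <- event_frame(p$t_lc_protrusion, spec$t_start, spec$frame_interval)
  f_meet <- event_frame(p$t_lc_meeting, spec$t_start, spec$frame_interval)

  # Front row per frame: static until LC protrusion onset, then advances
  # linearly (floored to the pixel grid) to reach the meeting line exactly
  # at the meeting frame.
  front_row <- rep(lay$front0, Tn)
  if (!is.na(f_lcprot) && !is.na(f_meet) && f_meet > f_lcprot) {
    f <- seq_len(Tn)
    adv <- floor((lay$meet_row - lay$front0) * (f - f_lcprot) / (f_meet - f_lcprot))
    front_row <- lay$front0 + pmin(pmax(adv, 0), lay$meet_row - lay$front0)
  }

  out <- with_local_seed(spec$seed, {
    # --- protrusion schedule (fixed cell/site order for determinism) ---
    prot <- list()
    for (i in seq_len(nrow(lay$cells))) {
      cell <- lay$cells[i, ]
      fs <- if (cell$role == "pocket-cell") f_pocket else f_lcprot
      if (is.na(fs) || is.na(p$mean_protrusion_duration)) next
      for (s in c(-1, 1)) {
        site_col <- cell$axis_col + s * lay$site_offset
        start <- if (s == -1) fs else fs + sample(0:2, 1L)
        ep <- schedule_site(start, Tn, p$mean_protrusion_duration, spec$frame_interval)
        if (nrow(ep)) {
          ep$cell <- cell$id; ep$site_col <- site_col
          prot[[length(prot) + 1L]] <- ep
        }
      }
    }
    prot <- if (length(prot)) do.call(rbind, prot) else
      data.frame(first_frame = integer(0), last_frame = integer(0),
                 cell = character(0), site_col = integer(0))
    prot <- prot[, c("cell", "site_col", "first_frame", "last_frame")]

    # --- puncta placement, per frame per leading cell ---
    lcs <- lay$cells[lay$cells$role == "leading-cell", ]
    peaks <- list()
    for (f in seq_len(Tn)) {
      fr <- front_row[f]
      ridge_on <- !is.na(f_enrich) && f >= f_enrich
      ridge_c <- fr - offset_px
      for (i in seq_len(nrow(lcs))) {
        k <- stats::rpois(1L, p$peak_rate)
        if (k == 0L) next
        ventral <- stats::rbinom(k, 1L, p$ventral_peak_fraction) == 1L
        v_zone <- seq.int(ceiling(lay$mid_row) + 4L, fr - 4L)
        if (ridge_on) {
          v_zone <- setdiff(v_zone, seq.int(ridge_c - 8L, ridge_c + 8L))
        }
        d_zone <- seq.int(lay$band_top + 4L, floor(lay$mid_row) - 4L)
        rv <- place_rows(v_zone, sum(ventral))
        rd <- place_rows(d_zone, sum(!ventral))
        if (length(rv) + length(rd)) {
          peaks[[length(peaks) + 1L]] <- data.frame(
            frame = f, cell = lcs$id[i],
            row = c(rv, rd), col = lcs$axis_col[i],
            half = c(rep("ventral", length(rv)), rep("dorsal", length(rd))))
        }
      }
    }
    peaks <- if (length(peaks)) do.call(rbind, peaks) else
      data.frame(frame = integer(0), cell = character(0), row = integer(0),
                 col = integer(0), half = character(0))

    # --- render ---
    frames <- array(0, dim = c(H, W, Tn))
    emb_cols <- seq.int(min(lay$cells$col_left), max(lay$cells$col_right))
    lc_cols <- seq.int(min(lcs$col_left), max(lcs$col_right))
    kern <- data.frame(dr = c(0, 1, -1, 0, 0, 1, 1, -1, -1, 2, -2, 0, 0),
                       dc = c(0, 0, 0, 1, -1, 1, -1, 1, -1, 0, 0, 2, -2),
                       w = c(1, .6, .6, .6, .6, .4, .4, .4, .4, .2, .2, .2, .2))
    for (f in seq_len(Tn)) {
      M <- matrix(bg, H, W)
      fr <- front_row[f]
      M[lay$band_top:fr, emb_cols] <- bg + base_off
      if (!is.na(f_enrich) && f >= f_enrich) {
        ridge_c <- fr - offset_px
        for (j in -2:2) {
          M[ridge_c + j, lc_cols] <- pmax(M[ridge_c + j, lc_cols],
                                          bg + lay$ridge_amplitudes[j + 3])
        }
      }
      pk <- peaks[peaks$frame == f, , drop = FALSE]
      for (q in seq_len(nrow(pk))) {
        rr <- pk$row[q] + kern$dr; cc <- pk$col[q] + kern$dc
        val <- bg + lay$puncta_amplitude * kern$w
        M[cbind(rr, cc)] <- pmax(M[cbind(rr, cc)], val)
      }
      act <- prot[prot$first_frame <= f & prot$last_frame >= f, , drop = FALSE]
      for (q in seq_len(nrow(act))) {
        rows <- seq.int(fr + 1L, min(H, fr + lay$protrusion_extent))
        cols <- act$site_col[q] + (-1:1)
        M[rows, cols] <- bg + base_off + 31
      }
      if (spec$noise_sigma > 0) {
        M <- M + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
      }
      frames[, , f] <- clip8(M)
    }
    list(frames = frames, prot = prot, peaks = peaks)
  })

  time_of <- function(f) {
    if (is.na(f) || f > Tn) NA_real_ else spec$t_start + (f - 1) * spec$frame_interval
  }
  first_prot_time <- function(role) {
    ids <- lay$cells$id[lay$cells$role == role]
    rows <- out$prot[out$prot$cell %in% ids, , drop = FALSE]
    if (!nrow(rows)) NA_real_ else time_of(min(rows$first_frame))
  }
  meet_f <- if (any(front_row == lay$meet_row)) min(which(front_row == lay$meet_row)) else NA_integer_
  event_times <- c(
    pocket_protrusion = first_prot_time("pocket-cell"),
    lc_enrichment = time_of(f_enrich),
    lc_protrusion = first_prot_time("leading-cell"),
    lc_meeting = time_of(meet_f)
  )

  rois <- lapply(seq_len(nrow(lay$cells)), function(i) {
    cell <- lay$cells[i, ]
    cell_roi(
      id = cell$id, role = cell$role,
      polygon = rect_polygon(lay$band_top, lay$meet_row, cell$col_left, cell$col_right),
      axis = list(ventral = c(lay$meet_row, cell$axis_col),
                  dorsal = c(lay$band_top, cell$axis_col)),
      leading_edge = list(row = lay$meet_row, col_start = cell$col_left,
                          col_end = cell$col_right)
    )
  })
  names(rois) <- lay$cells$id

  stack <- time_lapse_stack(out$frames, spec$frame_interval, spec$t_start,
                            spec$pixel_size)
  ground_truth <- list(event_times = event_times, protrusions = out$prot,
                       peaks = out$peaks, front_row = front_row,
                       meet_row = lay$meet_row, layout = lay, spec = spec)
  list(stack = stack, ground_truth = ground_truth, rois = rois)
}

#' Ground-truth ventral:dorsal peak-count ratio
#'
#' Tallies the recorded puncta placements of a generated movie over a frame
#' window; the oracle against which the measured V:D ratio is checked.
#'
#' @param ground_truth the `ground_truth` element of [generate_movie()].
#' @param frames frame indices of the window (default: all frames).
#' @return list with `n_ventral`, `n_dorsal` and `ratio` (`NA` when no
#'   dorsal peak was placed).
#' @export
gt_vd_ratio <- function(ground_truth, frames = NULL) {
  pk <- ground_truth$peaks
  if (!is.null(frames)) pk <- pk[pk$frame %in% frames, , drop = FALSE]
  nv <- sum(pk$half == "ventral"); nd <- sum(pk$half == "dorsal")
  list(n_ventral = nv, n_dorsal = nd,
       ratio = if (nd > 0) nv / nd else NA_real_)
}
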