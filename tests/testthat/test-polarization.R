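# Helpers local to this file -------------------------------------------------

# ROI with a vertical axis down column `col`, ventral at `row_v`.
vertical_roi <- function(id, row_v, row_d, col, half_width = 4,
                         role = "leading-cell") {
  cell_roi(id, role,
           polygon = data.frame(row = c(row_d - 0.5, row_d - 0.5, row_v + 0.5, row_v + 0.5),
                                col = c(col - half_width, col + half_width,
                                        col + half_width, col - half_width)),
           axis = list(ventral = c(row_v, col), dorsal = c(row_d, col)),
           leading_edge = list(row = row_v, col_start = col - half_width,
                               col_end = col + half_width))
}

# ----------------------------------------------------------------------------

test_that("contrast stretch is monotone, idempotent on full-range data, and warns on constant stacks", {
  two_level <- array(c(rep(0, 600), rep(255, 400)), dim = c(10, 10, 10))
  st <- time_lapse_stack(two_level)
  expect_equal(contrast_stretch(st)$frames, two_level)
  set.seed(5)
  noisy <- array(runif(2000, 10, 90), dim = c(20, 10, 10))
  out <- contrast_stretch(time_lapse_stack(noisy))$frames
  o <- order(noisy)
  expect_true(all(diff(out[o]) >= 0))            # order preserved
  expect_equal(range(out), c(0, 255))
  expect_warning(res <- contrast_stretch(time_lapse_stack(array(40, c(5, 5, 2)))),
                 "constant")
  expect_equal(res$frames, array(40, c(5, 5, 2)))
})

test_that("background is the modal intensity outside the embryo", {
  expect_equal(estimate_background(matrix(20, 10, 10)), 20)
  f <- matrix(20, 10, 10); f[1, 1] <- 200  # 99% at 20
  expect_equal(estimate_background(f), 20)
  mv <- wt_noiseless()
  expect_equal(estimate_background(mv$stack$frames[, , 1], movie_mask(mv)), 30)
})

test_that("leading-edge box mean matches direct pixel averages", {
  roi <- vertical_roi("c1", row_v = 50, row_d = 10, col = 28, half_width = 18)
  expect_equal(leading_edge_roi_mean(matrix(7, 60, 60), roi), 7)
  checker <- outer(1:60, 1:60, function(r, c) ((r + c) %% 2) * 10)
  expect_equal(leading_edge_roi_mean(checker, roi), 5)
  f <- matrix(rpois(3600, 20), 60, 60)
  expect_equal(leading_edge_roi_mean(f + 3, roi),
               leading_edge_roi_mean(f, roi) + 3)
  shallow <- vertical_roi("c2", row_v = 20, row_d = 5, col = 28)
  expect_error(leading_edge_roi_mean(matrix(0, 60, 60), shallow), "c2")
})

test_that("at enrichment onset the leading-edge box outshines the whole cell", {
  mv <- wt_noiseless()
  f_en <- frame_at(mv$stack, mv$ground_truth$event_times[["lc_enrichment"]])
  frame <- mv$stack$frames[, , f_en]
  roi <- mv$rois$lc1
  front <- mv$ground_truth$front_row[f_en]
  box <- leading_edge_roi_mean(frame, roi, front_row = front)
  # direct pixel-sum oracle for the whole-cell mean
  fp <- roi_mask(roi, dim(frame))
  fp[seq_len(nrow(frame)) > front, ] <- FALSE
  expect_gt(box, mean(frame[fp]))
  expect_gt(box, 1.2 * mean(frame[fp]))
})

test_that("profiles sample the axis exactly on pixel columns and match a rotated analytic oracle", {
  f <- matrix(0, 12, 9); f[3:5, 4] <- c(10, 9, 8)
  roi <- vertical_roi("c", row_v = 5, row_d = 3, col = 4)
  expect_equal(extract_vd_profile(f, roi)$intensities, c(8, 9, 10))
  long <- vertical_roi("c", row_v = 11, row_d = 2, col = 4)
  expect_equal(length(extract_vd_profile(f, long)$intensities), 10)
  expect_error(extract_vd_profile(f, vertical_roi("c", row_v = 4, row_d = 3, col = 4)),
               "shorter")

  # analytic Gaussian field, rendered unrotated and rotated by 30 degrees;
  # profiles along the corresponding axes must agree to interpolation error
  field <- function(r, c) {
    40 + 60 * exp(-((r - 24)^2 + (c - 30)^2) / 32) +
      50 * exp(-((r - 36)^2 + (c - 30)^2) / 50)
  }
  grid <- expand.grid(r = 1:60, c = 1:60)
  A <- matrix(field(grid$r, grid$c), 60, 60)
  th <- 30 * pi / 180; ctr <- c(30, 30)
  rot_back <- function(r, c) {
    dr <- r - ctr[1]; dc <- c - ctr[2]
    list(r = ctr[1] + cos(th) * dr - sin(th) * dc,
         c = ctr[2] + sin(th) * dr + cos(th) * dc)
  }
  pb <- rot_back(grid$r, grid$c)
  B <- matrix(field(pb$r, pb$c), 60, 60)
  rot_fwd <- function(p) {
    d <- p - ctr
    ctr + c(cos(th) * d[1] + sin(th) * d[2], -sin(th) * d[1] + cos(th) * d[2])
  }
  axA <- list(v = c(45, 30), d = c(15, 30))
  roiA <- vertical_roi("a", 45, 15, 30, half_width = 10)
  roiB <- cell_roi("b", "leading-cell",
                   polygon = data.frame(row = c(1, 1, 60, 60), col = c(1, 60, 60, 1)),
                   axis = list(ventral = rot_fwd(axA$v), dorsal = rot_fwd(axA$d)),
                   leading_edge = list(row = 45, col_start = 20, col_end = 40))
  pa <- extract_vd_profile(A, roiA)$intensities
  pb2 <- extract_vd_profile(B, roiB)$intensities
  expect_equal(length(pa), length(pb2))
  expect_lt(max(abs(pa - pb2)), 2)
})

test_that("peak detection counts maximal supra-threshold runs, matching a brute-force scanner", {
  prof <- line_profile(c(5, 5, 20, 5, 16, 5))
  pk <- detect_peaks(prof, background = 5)
  expect_equal(pk$apex_idx, c(3, 5))
  expect_equal(nrow(detect_peaks(line_profile(c(5, 14, 5)), background = 5)), 0)
  plateau <- detect_peaks(line_profile(c(0, 15, 15, 15, 0)), background = 0)
  expect_equal(nrow(plateau), 1)
  expect_equal(plateau$apex_idx, 2)  # leftmost (most ventral) on ties
  set.seed(1234)
  for (i in 1:1000) {
    v <- sample(0:40, sample(5:40, 1), replace = TRUE)
    bg <- sample(0:10, 1)
    pk <- detect_peaks(line_profile(v), background = bg, threshold = 10)
    expect_identical(nrow(pk), scan_runs(v, bg + 10))
  }
})

test_that("peaks are assigned to halves by apex position with ventral midpoint ties", {
  v <- rep(0, 11); v[3] <- 20; v[9] <- 20  # ~20% and ~80% of the span
  prof <- line_profile(v)
  h <- assign_halves(detect_peaks(prof, 0), prof)
  expect_equal(c(h$ventral, h$dorsal), c(1, 1))
  v <- rep(0, 11); v[6] <- 20  # apex exactly at half the length
  prof <- line_profile(v)
  h <- assign_halves(detect_peaks(prof, 0), prof)
  expect_equal(c(h$ventral, h$dorsal), c(1, 0))
  # generator movie with every punctum placed ventrally
  mv <- generate_movie(movie_spec(puncta_only_preset(p = 1), n_frames = 5, seed = 3))
  mask <- movie_mask(mv)
  for (f in 1:5) {
    frame <- mv$stack$frames[, , f]
    bg <- estimate_background(frame, mask)
    for (cell in c("lc1", "lc2")) {
      prof <- extract_vd_profile(frame, mv$rois[[cell]])
      h <- assign_halves(detect_peaks(prof, bg), prof)
      placed <- mv$ground_truth$peaks
      k <- sum(placed$frame == f & placed$cell == cell)
      expect_equal(h$ventral, k)
      expect_equal(h$dorsal, 0)
    }
  }
})

test_that("the V:D ratio sums half counts over the window and flags a zero dorsal count", {
  H <- 40; W <- 10
  mk_frame <- function(vrows, drows) {
    f <- matrix(0, H, W)
    f[c(vrows, drows), 5] <- 50
    f
  }
  frames <- array(0, dim = c(H, W, 4))
  for (f in 1:4) frames[, , f] <- mk_frame(c(30, 26, 22), 5)
  st <- time_lapse_stack(frames, frame_interval = 2, t_start = 0)
  roi <- vertical_roi("c", row_v = 35, row_d = 2, col = 5)
  res <- vd_ratio_over_window(st, roi, 1, 4, background = 0)
  expect_equal(c(res$n_ventral, res$n_dorsal), c(12, 4))
  expect_equal(res$ratio, 3.0)
  # frame order inside the window is irrelevant
  perm <- time_lapse_stack(frames[, , c(3, 1, 4, 2)], 2, 0)
  res2 <- vd_ratio_over_window(perm, roi, 1, 4, background = 0)
  expect_equal(res2$ratio, res$ratio)
  # no dorsal peaks -> undefined, not an error
  for (f in 1:4) frames[, , f] <- mk_frame(c(30, 24), integer(0))
  res3 <- vd_ratio_over_window(time_lapse_stack(frames, 2, 0), roi, 1, 4,
                               background = 0)
  expect_true(res3$undefined)
  expect_true(is.na(res3$ratio))
  expect_error(vd_ratio_over_window(st, roi, 3, 4, background = 0), "out of range")
})

test_that("measured V:D ratio approaches p/(1-p) for generated movies", {
  for (p in c(0.5, 0.75)) {
    nv <- 0L; nd <- 0L; tv <- 0L; td <- 0L
    for (s in 1:2) {
      mv <- generate_movie(movie_spec(puncta_only_preset(p = p), n_frames = 20,
                                      seed = 100 + s))
      mask <- movie_mask(mv)
      for (cell in c("lc1", "lc2")) {
        r <- vd_ratio_over_window(mv$stack, mv$rois[[cell]], 1, 20, mask = mask)
        nv <- nv + r$n_ventral; nd <- nd + r$n_dorsal
      }
      g <- gt_vd_ratio(mv$ground_truth)
      tv <- tv + g$n_ventral; td <- td + g$n_dorsal
    }
    expect_equal(c(nv, nd), c(tv, td))  # measured == placed
    ci <- ratio_ci(nv + nd, p)
    expect_gte(nv / nd, ci[1])
    expect_lte(nv / nd, ci[2])
  }
})

test_that("enrichment offset measures apex distance behind the front, scale-invariantly", {
  f <- matrix(0, 40, 10)
  f[10:30, 5] <- 20; f[30, 5] <- 100  # ridge right at the front
  roi <- vertical_roi("c", row_v = 35, row_d = 5, col = 5)
  expect_equal(enrichment_offset(f, roi, background = 0), 0)
  f2 <- f; f2[22, 5] <- 120  # apex 8 px behind the front
  expect_equal(enrichment_offset(f2, roi, background = 0), 8 * 0.15)
  expect_equal(enrichment_offset(f2 * 2, roi, background = 0),
               enrichment_offset(f2, roi, background = 0))
  expect_error(enrichment_offset(matrix(0, 40, 10), roi, background = 0),
               "above-background")
})
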