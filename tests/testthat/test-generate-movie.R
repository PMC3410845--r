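test_that("identical spec and seed give bit-identical movies", {
  sp <- movie_spec("wild_type", n_frames = 8, seed = 7)
  a <- generate_movie(sp)
  b <- generate_movie(sp)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$ground_truth$protrusions, b$ground_truth$protrusions)
  expect_identical(a$ground_truth$peaks, b$ground_truth$peaks)
})

test_that("with no puncta, protrusions or noise the frame is background outside the cell band", {
  pr <- genotype_preset("flat", NA, NA, NA, NA, mean_protrusion_duration = 2,
                        ventral_peak_fraction = 0.5, peak_rate = 0)
  mv <- generate_movie(movie_spec(pr, n_frames = 3, noise_sigma = 0,
                                  background_level = 30))
  lay <- mv$ground_truth$layout
  for (f in 1:3) {
    frame <- mv$stack$frames[, , f]
    outside <- frame[-(lay$band_top:lay$front0), ]
    expect_true(all(frame[1:(lay$band_top - 1), ] == 30))
    expect_true(all(frame[(lay$front0 + 1):nrow(frame), ] == 30))
    expect_true(all(frame[, 1:(min(lay$cells$col_left) - 1)] == 30))
  }
  expect_equal(nrow(mv$ground_truth$peaks), 0)
  expect_equal(nrow(mv$ground_truth$protrusions), 0)
})

test_that("recorded ventral fraction of placed puncta obeys the binomial law", {
  # pool placements over seeds until well over 200 puncta
  nv <- 0L; nd <- 0L
  for (s in 1:3) {
    mv <- generate_movie(movie_spec(puncta_only_preset(p = 0.75),
                                    n_frames = 20, seed = s))
    g <- gt_vd_ratio(mv$ground_truth)
    nv <- nv + g$n_ventral; nd <- nd + g$n_dorsal
  }
  N <- nv + nd
  expect_gt(N, 200)
  ci <- ratio_ci(N, 0.75)
  expect_gte(nv / nd, ci[1])
  expect_lte(nv / nd, ci[2])
})

test_that("ground-truth event times match first appearance of the rendered structures", {
  mv <- wt_noiseless()
  gt <- mv$ground_truth
  st <- mv$stack
  lay <- gt$layout
  # enrichment: first frame where any pixel exceeds the puncta ceiling
  ridge_frames <- which(apply(st$frames, 3, max) > 30 + lay$puncta_amplitude)
  expect_equal(frame_time(st, min(ridge_frames)), gt$event_times[["lc_enrichment"]])
  # meeting: first frame where the cell body occupies the meeting row,
  # inspected on an LC axis column (protrusion sites sit off-axis, so
  # protrusion tips crossing the row earlier do not count)
  axis_col <- mv$rois$lc1$axis$ventral[2]
  meet_frames <- which(st$frames[gt$meet_row, axis_col, ] > 30)
  expect_equal(frame_time(st, min(meet_frames)), gt$event_times[["lc_meeting"]])
  # pocket protrusion: first frame with above-band pixels under a pocket cell
  pocket_cols <- 94:173
  below <- st$frames[(lay$front0 + 1):nrow(st$frames[, , 1]), pocket_cols, ]
  prot_frames <- which(apply(below, 3, max) > 30)
  expect_equal(frame_time(st, min(prot_frames)), gt$event_times[["pocket_protrusion"]])
  # and the recorded schedule is internally consistent
  expect_true(all(gt$protrusions$first_frame <= gt$protrusions$last_frame))
})

test_that("drawn frame-lifetimes form the calibrated two-point mixture", {
  sp <- movie_spec("wild_type", seed = 1)
  m <- sp$preset$mean_protrusion_duration / sp$frame_interval  # 1.25 frames
  durations_frames <- c()
  for (s in 1:10) {
    mv <- generate_movie(movie_spec("wild_type", seed = s))
    gt <- mv$ground_truth$protrusions
    durations_frames <- c(durations_frames, gt$last_frame - gt$first_frame + 1L)
  }
  expect_setequal(sort(unique(durations_frames)), c(floor(m), ceiling(m)))
  # mean within 3 SE of the exact expectation
  se <- sd(durations_frames) / sqrt(length(durations_frames))
  expect_lt(abs(mean(durations_frames) - m), 3 * se + 1e-12)
})

test_that("unrealizable protrusion lifetimes are rejected at generation", {
  pr <- genotype_preset("fast", 250, NA, NA, NA, mean_protrusion_duration = 1,
                        ventral_peak_fraction = 0.5, peak_rate = 1)
  expect_error(movie_spec(pr, frame_interval = 2), "cannot be realized")
})
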