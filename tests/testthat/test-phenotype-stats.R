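test_that("tallies reproduce printed phenotype-table rows", {
  # double mutant at restrictive temperature
  s <- tally(phenotype_counts("unc-40;sax-3", 25.5, 143, 58, 104))
  expect_equal(c(s$pct_wildtype, s$pct_full, s$pct_partial, s$pct_total_lethality),
               c(47, 19, 34, 53))
  # fully penetrant enclosure failure
  s <- tally(phenotype_counts("wve-1", 20, 0, 308, 0))
  expect_equal(c(s$pct_wildtype, s$pct_full, s$pct_partial, s$pct_total_lethality),
               c(0, 100, 0, 100))
  s <- tally(phenotype_counts("sax-3", 20, 311, 17, 238))
  expect_equal(c(s$pct_wildtype, s$pct_full, s$pct_partial, s$pct_total_lethality),
               c(55, 3, 42, 45))
  s <- tally(phenotype_counts("clean", 20, 10, 0, 0))
  expect_equal(c(s$pct_wildtype, s$pct_total_lethality), c(100, 0))
  expect_error(tally(phenotype_counts("none", 20, 0, 0, 0)), "n = 0")
})

test_that("near-complete percentages display as >99 and <1", {
  s <- tally(phenotype_counts("N2", 20, 999, 0, 1))
  expect_equal(s$display[["wildtype"]], ">99")
  expect_equal(s$display[["partial"]], "<1")
  expect_equal(s$display[["total_lethality"]], "<1")
  expect_equal(s$display[["full"]], "0")
})

test_that("tally percentages are label-equivariant and sum to ~100", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:500, 3, replace = TRUE)
    s <- tally(phenotype_counts("x", 20, n[1], n[2], n[3]))
    p <- tally(phenotype_counts("x", 20, n[2], n[3], n[1]))
    expect_setequal(c(s$pct_wildtype, s$pct_full, s$pct_partial),
                    c(p$pct_wildtype, p$pct_full, p$pct_partial))
    expect_lte(abs(s$pct_wildtype + s$pct_full + s$pct_partial - 100), 1)
  }
})

test_that("SEM is the sample SD over root n", {
  expect_equal(sem(c(1, 2, 3)), 1 / sqrt(3))
  expect_equal(sem(rep(4, 10)), 0)
  expect_error(sem(5), "at least 2")
})

test_that("one-way ANOVA has the textbook F and edge-case behaviour", {
  a <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # two groups: F equals the squared pooled two-sample t statistic
  set.seed(21)
  for (i in 1:20) {
    g1 <- rnorm(sample(3:9, 1)); g2 <- rnorm(sample(3:9, 1), mean = runif(1))
    a <- one_way_anova(list(g1, g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  }
  z <- one_way_anova(list(c(0, 0), c(1, 1)))
  expect_true(z$zero_within)
  expect_equal(z$F, Inf)
  expect_equal(z$p, 0)
})

test_that("one-way ANOVA is invariant to shifts and scale-equivariant in F", {
  set.seed(3)
  gs <- list(rnorm(6), rnorm(5, 1), rnorm(7, 2))
  a <- one_way_anova(gs)
  b <- one_way_anova(lapply(gs, function(x) x + 11))
  d <- one_way_anova(lapply(gs, function(x) x * 3.7))
  expect_equal(b$F, a$F, tolerance = 1e-10)
  expect_equal(d$F, a$F, tolerance = 1e-10)
  expect_equal(d$p, a$p, tolerance = 1e-10)
})

test_that("Tukey HSD matches the ANOVA p for two groups and the stats reference for more", {
  set.seed(33)
  g1 <- rnorm(6); g2 <- rnorm(6, 1)
  tk <- tukey_hsd(list(a = g1, b = g2))
  aov1 <- one_way_anova(list(g1, g2))
  expect_equal(tk$p_adj, aov1$p, tolerance = 1e-8)
  expect_equal(tk$q, sqrt(2) * abs(t.test(g1, g2, var.equal = TRUE)$statistic),
               tolerance = 1e-10, ignore_attr = TRUE)
  # identical group means -> p_adj = 1
  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(same$p_adj, 1)
  # scaling all data leaves every q unchanged
  gs <- list(a = rnorm(5), b = rnorm(4, 1), c = rnorm(6, 2))
  expect_equal(tukey_hsd(lapply(gs, function(x) 5 * x))$q, tukey_hsd(gs)$q,
               tolerance = 1e-10)
  # cross-check against stats::TukeyHSD on a balanced design
  gs <- list(a = rnorm(6), b = rnorm(6, 0.5), c = rnorm(6, 1.5))
  tk <- tukey_hsd(gs)
  y <- unlist(gs); g <- factor(rep(names(gs), each = 6))
  ref <- stats::TukeyHSD(stats::aov(y ~ g))$g
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-10)
  # p_adj shrinks as the separation grows, variances held fixed
  base <- c(-1, 0, 1)
  ps <- vapply(c(0.5, 1, 2, 4), function(d)
    tukey_hsd(list(a = base, b = base + d))$p_adj, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("two-way ANOVA decomposes sums of squares like the direct projection oracle", {
  set.seed(44)
  A <- factor(rep(c("a1", "a2"), each = 6))
  B <- factor(rep(rep(c("b1", "b2"), each = 3), 2))
  y <- rnorm(12, mean = as.integer(A) + 2 * as.integer(B))
  res <- two_way_anova_bonferroni(y, A, B)
  # brute-force SS computation
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ssA <- 6 * sum((mA - grand)^2)
  ssB <- 6 * sum((mB - grand)^2)
  cellm <- ave(y, A, B)
  ssAB <- sum((cellm - ave(y, A) - ave(y, B) + grand)^2)
  ssE <- sum((y - cellm)^2)
  eff <- setNames(res$effects$sum_sq, res$effects$term)
  expect_equal(eff[["A"]], ssA, tolerance = 1e-10)
  expect_equal(eff[["B"]], ssB, tolerance = 1e-10)
  expect_equal(eff[["A:B"]], ssAB, tolerance = 1e-10)
  expect_equal(eff[["Residuals"]], ssE, tolerance = 1e-10)
})

test_that("purely additive data have zero interaction and Bonferroni scales p linearly", {
  A <- factor(rep(c("a1", "a2"), each = 4))
  B <- factor(rep(rep(c("b1", "b2"), each = 2), 2))
  y <- as.integer(A) * 2 + as.integer(B) * 5 + rep(c(-0.1, 0.1), 4)
  res <- two_way_anova_bonferroni(y, A, B)
  expect_equal(res$effects$sum_sq[res$effects$term == "A:B"], 0,
               tolerance = 1e-10)
  expect_equal(res$comparisons$p_adj,
               pmin(1, nrow(res$comparisons) * res$comparisons$p))
  expect_error(two_way_anova_bonferroni(y[-1], A[-1], B[-1]), "unbalanced")
})

test_that("ANOVA type-I error is calibrated at the nominal 5% under the null", {
  set.seed(1357)
  reps <- 1000
  hits <- 0L
  for (i in seq_len(reps)) {
    p <- one_way_anova(list(rnorm(8), rnorm(8), rnorm(8)))$p
    if (p < 0.05) hits <- hits + 1L
  }
  mc_err <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(hits / reps - 0.05), mc_err)
})

test_that("significance stars follow the printed convention", {
  expect_equal(significance_stars(c(0.04, 0.004, 4e-4, 4e-5, 0.2)),
               c("*", "**", "***", "****", "ns"))
})
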