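# Phenotype-distribution tables and the statistical tests used on them:
# SEM, one-way ANOVA with Tukey HSD, two-way ANOVA with Bonferroni.

#' Embryo phenotype counts for one genotype
#'
#' Tallied embryo classes from scoring a cross: wild-type (encloses and
#' elongates), Full Gex (complete enclosure failure, internal organs
#' extruded) and Partial Gex (incomplete enclosure).
#'
#' @param genotype genotype label.
#' @param temperature cultivation temperature in °C.
#' @param n_wildtype,n_full_gex,n_partial_gex class counts (>= 0).
#' @return object of class `phenotype_counts` with an `n` total.
#' @export
phenotype_counts <- function(genotype, temperature = 20,
                             n_wildtype, n_full_gex, n_partial_gex) {
  counts <- c(n_wildtype, n_full_gex, n_partial_gex)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("class counts must be non-negative integers")
  }
  structure(list(genotype = genotype, temperature = temperature,
                 n_wildtype = n_wildtype, n_full_gex = n_full_gex,
                 n_partial_gex = n_partial_gex, n = sum(counts)),
            class = "phenotype_counts")
}

# Display convention for printed phenotype tables: integer percents, with
# values strictly between 99 and 100 shown as ">99" and strictly between
# 0 and 1 shown as "<1".
#' @keywords internal
#' @noRd
format_percent <- function(exact) {
  ifelse(exact > 99 & exact < 100, ">99",
         ifelse(exact > 0 & exact < 1, "<1",
                as.character(round_half_up(exact))))
}

#' Summarize phenotype counts as printed percentages
#'
#' Converts class counts to the percent columns of a phenotype table:
#' percent wild-type, Full Gex, Partial Gex, and total lethality
#' (Full + Partial share), each rounded to the nearest integer (half away
#' from zero). Display strings render values in (99, 100) as ">99" and in
#' (0, 1) as "<1", as printed tables do.
#'
#' @param counts a [phenotype_counts()].
#' @return list of class `phenotype_summary`: `pct_wildtype`, `pct_full`,
#'   `pct_partial`, `pct_total_lethality` (rounded numerics), `display`
#'   (named character vector) and the exact percentages in `exact`.
#' @examples
#' tally(phenotype_counts("wve-1(zu496)", 20, 0, 308, 0))$pct_total_lethality
#' @export
tally <- function(counts) {
  stopifnot(inherits(counts, "phenotype_counts"))
  if (counts$n < 1) stop("cannot tally an empty table (n = 0)")
  exact <- 100 * c(
    wildtype = counts$n_wildtype,
    full = counts$n_full_gex,
    partial = counts$n_partial_gex,
    total_lethality = counts$n_full_gex + counts$n_partial_gex
  ) / counts$n
  structure(list(
    genotype = counts$genotype, temperature = counts$temperature,
    n = counts$n,
    pct_wildtype = round_half_up(exact[["wildtype"]]),
    pct_full = round_half_up(exact[["full"]]),
    pct_partial = round_half_up(exact[["partial"]]),
    pct_total_lethality = round_half_up(exact[["total_lethality"]]),
    display = format_percent(exact), exact = exact
  ), class = "phenotype_summary")
}

#' @export
print.phenotype_summary <- function(x, ...) {
  cat(sprintf("%s (%g degC, n = %d): %s%% wild-type, %s%% Full Gex, %s%% Partial Gex, %s%% total lethality\n",
              x$genotype, x$temperature, x$n,
              x$display[["wildtype"]], x$display[["full"]],
              x$display[["partial"]], x$display[["total_lethality"]]))
  invisible(x)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by the square root
#' of the number of values.
#'
#' @param values numeric vector with at least 2 values.
#' @return the SEM.
#' @export
sem <- function(values) {
  if (length(values) < 2) stop("SEM needs at least 2 values")
  stats::sd(values) / sqrt(length(values))
}

# Normalize group input: named list of numeric vectors.
#' @keywords internal
#' @noRd
as_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(vapply(groups, length, integer(1)) < 1)) {
    stop("every group needs at least one value")
  }
  if (sum(vapply(groups, length, integer(1)) - 1L) < 1L) {
    stop("at least one group needs at least two values")
  }
  groups
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition, fitted with [stats::lm()];
#' `F = MS_between / MS_within` with the upper-tail p-value from the F
#' distribution. A design with zero within-group variance but distinct
#' means is reported as `F = Inf`, `p = 0` with `zero_within = TRUE`.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups).
#' @return list with `F`, `df_between`, `df_within`, `p`, `ms_between`,
#'   `ms_within`, `group_means`, and the `zero_within` flag.
#' @export
one_way_anova <- function(groups) {
  groups <- as_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  # a perfect fit (zero within-group variance) is handled below via the
  # zero_within flag, so anova.lm's unreliable-F warning is redundant here
  a <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  ms_b <- a["g", "Mean Sq"]; ms_w <- a["Residuals", "Mean Sq"]
  df_b <- a["g", "Df"]; df_w <- a["Residuals", "Df"]
  zero_within <- ms_w <= .Machine$double.eps * max(1, abs(mean(y)))^2
  if (zero_within) {
    Fv <- if (ms_b > 0) Inf else 0
    p <- if (ms_b > 0) 0 else 1
  } else {
    Fv <- ms_b / ms_w
    p <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  list(F = Fv, df_between = df_b, df_within = df_w, p = p,
       ms_between = ms_b, ms_within = ms_w,
       group_means = vapply(groups, mean, numeric(1)),
       zero_within = zero_within)
}

#' Tukey HSD post-test
#'
#' All pairwise comparisons after a one-way ANOVA:
#' `q_ij = |mean_i - mean_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))`
#' (the Tukey-Kramer statistic for unequal group sizes), with the adjusted
#' p-value from the studentized-range distribution with `k` groups and the
#' within-group degrees of freedom ([stats::ptukey()]).
#'
#' @param groups list of numeric vectors, one per group.
#' @return data.frame with `group1`, `group2`, `diff` (mean difference),
#'   `q`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  groups <- as_groups(groups)
  a <- one_way_anova(groups)
  k <- length(groups)
  ns <- lengths(groups)
  means <- a$group_means
  pairs <- utils::combn(names(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  out$diff <- means[out$group2] - means[out$group1]
  se <- sqrt(a$ms_within / 2 * (1 / ns[out$group1] + 1 / ns[out$group2]))
  out$q <- ifelse(se > 0, abs(out$diff) / se, ifelse(out$diff == 0, 0, Inf))
  out$p_adj <- ifelse(is.infinite(out$q), 0,
                      stats::ptukey(out$q, k, a$df_within, lower.tail = FALSE))
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA with Bonferroni post-test
#'
#' Standard two-way decomposition (main effects and interaction) on a
#' balanced replicated design, fitted with [stats::lm()], followed by
#' pairwise comparisons of factor-A levels within each level of factor B
#' using the pooled residual mean square; per-comparison
#' `p_adj = min(1, m * p)`.
#'
#' @param values numeric response vector.
#' @param A,B factors (coerced) of the same length as `values`.
#' @param m number of comparisons for the Bonferroni correction; defaults
#'   to the number of post-test comparisons performed.
#' @return list with `effects` (data.frame: term, df, sum_sq, mean_sq, F, p)
#'   and `comparisons` (data.frame: B level, A pair, difference, t, p,
#'   p_adj).
#' @export
two_way_anova_bonferroni <- function(values, A, B, m = NULL) {
  A <- factor(A); B <- factor(B)
  stopifnot(length(values) == length(A), length(values) == length(B))
  cell_n <- table(A, B)
  if (any(cell_n == 0)) stop("unbalanced design: empty cells")
  if (length(unique(as.vector(cell_n))) != 1) {
    stop("unbalanced design: unequal cell sizes (balanced-only scope)")
  }
  if (cell_n[1] < 2) stop("replicates required in every cell")
  fit <- stats::lm(values ~ A * B)
  a <- stats::anova(fit)
  effects <- data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                        mean_sq = a$`Mean Sq`, F = a$`F value`, p = a$`Pr(>F)`)
  ms_res <- a["Residuals", "Mean Sq"]
  df_res <- a["Residuals", "Df"]
  n_cell <- as.vector(cell_n)[1]
  cmp <- list()
  pairsA <- utils::combn(levels(A), 2)
  for (b in levels(B)) {
    for (j in seq_len(ncol(pairsA))) {
      a1 <- pairsA[1, j]; a2 <- pairsA[2, j]
      d <- mean(values[A == a2 & B == b]) - mean(values[A == a1 & B == b])
      tt <- if (ms_res > 0) d / sqrt(ms_res * 2 / n_cell) else
        ifelse(d == 0, 0, Inf * sign(d))
      p <- if (is.finite(tt)) 2 * stats::pt(abs(tt), df_res, lower.tail = FALSE)
           else if (tt == 0) 1 else 0
      cmp[[length(cmp) + 1L]] <- data.frame(B = b, group1 = a1, group2 = a2,
                                            diff = d, t = tt, p = p)
    }
  }
  cmp <- do.call(rbind, cmp)
  m <- m %||% nrow(cmp)
  cmp$p_adj <- pmin(1, m * cmp$p)
  list(effects = effects, comparisons = cmp)
}

#' Significance stars for printed tables
#'
#' Maps p-values to the conventional asterisk codes: `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `****` p < 0.0001; `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}
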