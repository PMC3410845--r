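# Non-imaging synthetic inputs: unit-test line profiles, phenotype count
# tables, blot band-intensity series and fractionation series with known
# ground truth.

#' Generate a spike line profile
#'
#' A flat background profile with single-position spikes of height
#' `peak_height` above background at the given positions; the elementary
#' fixture for peak-detection tests.
#'
#' @param positions number of profile samples.
#' @param background background intensity.
#' @param peak_positions 1-based indices of the spikes (must be distinct).
#' @param peak_height spike height above background.
#' @param pixel_size µm per pixel.
#' @return a [line_profile()].
#' @examples
#' generate_profile(6, 5, 3, 15)$intensities  # 5 5 20 5 5 5
#' @export
generate_profile <- function(positions, background, peak_positions = integer(0),
                             peak_height = 15, pixel_size = 0.15) {
  if (anyDuplicated(peak_positions)) stop("overlapping peak positions")
  if (length(peak_positions) &&
      (min(peak_positions) < 1 || max(peak_positions) > positions)) {
    stop("peak positions out of range")
  }
  v <- rep(background, positions)
  v[peak_positions] <- background + peak_height
  line_profile(v, pixel_size)
}

#' Draw a synthetic phenotype count table
#'
#' Multinomial draw of embryo phenotype classes (wild-type, Full Gex,
#' Partial Gex) emulating a scored cross.
#'
#' @param class_probs length-3 probabilities (wild-type, full, partial)
#'   summing to 1.
#' @param n number of embryos scored (>= 1).
#' @param seed RNG seed.
#' @param genotype,temperature labels carried into the result.
#' @return a [phenotype_counts()] object.
#' @export
generate_phenotype_counts <- function(class_probs, n, seed = NULL,
                                      genotype = "synthetic", temperature = 20) {
  stopifnot(length(class_probs) == 3, n >= 1)
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  draw <- with_local_seed(seed, stats::rmultinom(1, n, class_probs)[, 1])
  phenotype_counts(genotype, temperature,
                   n_wildtype = draw[1], n_full_gex = draw[2],
                   n_partial_gex = draw[3])
}

#' Generate a synthetic western-blot band series
#'
#' Emits one (band, loading control) intensity pair per sample such that the
#' noise-free normalized-relative levels ([normalize_relative()] with the
#' first sample as reference) equal `true_ratios` exactly. Noise is
#' mean-one multiplicative (lognormal with coefficient of variation
#' `noise_cv`) applied to the non-reference bands; the reference lane is the
#' calibration lane and is left noise-free, so the expected recovered ratio
#' equals the truth.
#'
#' @param true_ratios non-negative relative levels; the first entry is the
#'   reference and should be 1.
#' @param control_level loading-control intensity.
#' @param noise_cv coefficient of variation of the band noise (0 = exact).
#' @param seed RNG seed.
#' @param labels sample labels (default `wild_type`, `sample2`, ...).
#' @return data.frame with columns `sample`, `band`, `control`.
#' @export
generate_blot_series <- function(true_ratios, control_level = 100,
                                 noise_cv = 0, seed = NULL, labels = NULL) {
  stopifnot(all(true_ratios >= 0), control_level > 0)
  k <- length(true_ratios)
  labels <- labels %||% c("wild_type", if (k > 1) paste0("sample", 2:k))
  stopifnot(length(labels) == k)
  band <- control_level * true_ratios
  if (noise_cv > 0 && k > 1) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    f <- with_local_seed(seed, stats::rlnorm(k - 1, -sdlog^2 / 2, sdlog))
    band[-1] <- band[-1] * f
  }
  data.frame(sample = labels, band = band, control = control_level)
}

#' Generate a synthetic subcellular-fractionation series
#'
#' Band intensities proportional to the given shares of total protein across
#' the eight fractions of a sequential-spin protocol (S1, P1, ..., S4, P4;
#' spins 1K/10 min, 10K/10 min, 30K/20 min, 100K/90 min, with each pellet
#' resuspended to the volume of its partner supernatant so S and P load
#' comparably).
#'
#' @param fraction_shares length-8 non-negative shares summing to 1, in the
#'   order S1, P1, S2, P2, S3, P3, S4, P4.
#' @param total total band intensity distributed across fractions.
#' @param noise_cv optional mean-one multiplicative noise on each band.
#' @param seed RNG seed.
#' @return a [fractionation_series()].
#' @export
generate_fractionation_series <- function(fraction_shares, total = 1000,
                                          noise_cv = 0, seed = NULL) {
  if (length(fraction_shares) != 8) stop("eight fraction shares are required")
  if (any(fraction_shares < 0)) stop("fraction shares must be non-negative")
  if (abs(sum(fraction_shares) - 1) > 1e-8) stop("fraction shares must sum to 1")
  x <- fraction_shares * total
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    x <- x * with_local_seed(seed, stats::rlnorm(8, -sdlog^2 / 2, sdlog))
  }
  fractionation_series(x)
}
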