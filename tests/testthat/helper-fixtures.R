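# Shared fixtures, memoized so expensive movies render once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Noiseless wild-type movie: the reference for exact-recovery tests.
wt_noiseless <- function() {
  memo("wt_noiseless", generate_movie(movie_spec("wild_type", noise_sigma = 0, seed = 42)))
}

movie_mask <- function(mv) {
  embryo_mask(mv$rois, dim(mv$stack$frames)[1:2])
}

# Preset with puncta only (no protrusions, no enrichment, no migration):
# isolates the peak-counting statistics.
puncta_only_preset <- function(p = 0.75, rate = 4) {
  genotype_preset("puncta_only", NA, NA, NA, NA,
                  mean_protrusion_duration = 2.5,
                  ventral_peak_fraction = p, peak_rate = rate)
}

# Two-sided 95% binomial CI for the V:D ratio implied by V ~ Bin(N, p).
ratio_ci <- function(N, p = 0.75) {
  v <- stats::qbinom(c(0.025, 0.975), N, p)
  c(v[1] / (N - v[1]), v[2] / (N - v[2]))
}

all_tracks <- function(mv, mask = movie_mask(mv)) {
  do.call(rbind, lapply(mv$rois, function(r)
    detect_protrusions(mv$stack, r, mask = mask)))
}

# Brute-force run scanner: the independent oracle for detect_peaks.
scan_runs <- function(intensities, cutoff) {
  peaks <- 0L; inside <- FALSE
  for (v in intensities) {
    if (v >= cutoff && !inside) { peaks <- peaks + 1L; inside <- TRUE }
    if (v < cutoff) inside <- FALSE
  }
  peaks
}
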