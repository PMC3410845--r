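# Densitometry arithmetic: loading-control normalization relative to a
# reference sample, RNAi depletion percentage, and subcellular-fractionation
# percentages. Band quantitation itself (gel image -> intensity) is out of
# scope; inputs are intensity tables.

#' Normalize band intensities to a loading control, relative to a reference
#'
#' For each sample, the band intensity is divided by its loading-control
#' intensity (e.g. tubulin or HSP90), and the result is expressed relative
#' to the reference sample:
#' `r_i = (band_i / control_i) / (band_ref / control_ref)`.
#' The reference maps to 1 by construction, and per-lane exposure scaling
#' (multiplying one lane's band and control by the same constant) cancels.
#'
#' @param records data.frame with columns `sample`, `band`, `control`.
#' @param reference label of the reference sample (default `"wild_type"`).
#' @return named numeric vector of relative levels.
#' @export
normalize_relative <- function(records, reference = "wild_type") {
  stopifnot(all(c("sample", "band", "control") %in% names(records)))
  if (any(records$control <= 0)) stop("loading-control intensities must be positive")
  if (any(records$band < 0)) stop("band intensities must be non-negative")
  i <- match(reference, records$sample)
  if (is.na(i)) stop("reference sample '", reference, "' not found")
  if (records$band[i] <= 0) stop("reference band intensity is zero")
  ratio <- records$band / records$control
  stats::setNames(ratio / ratio[i], records$sample)
}

#' Percent depletion relative to a reference level
#'
#' `100 * (1 - treated / reference)`: the percent loss of a protein after a
#' treatment (e.g. RNAi knockdown) given normalized levels. A treated level
#' above the reference would give a negative loss; it is clamped to 0 and
#' flagged with a warning and a `clamped` attribute.
#'
#' @param reference_level reference (untreated) level (> 0).
#' @param treated_level treated level (>= 0).
#' @return percent loss in \[0, 100\].
#' @export
depletion_percent <- function(reference_level, treated_level) {
  if (reference_level <= 0) stop("reference level must be positive")
  pct <- 100 * (1 - treated_level / reference_level)
  if (pct < 0) {
    warning("treated level exceeds reference; depletion clamped to 0%")
    return(structure(0, clamped = TRUE))
  }
  pct
}

#' Subcellular fractionation series
#'
#' Band intensities across the eight fractions of the sequential-spin
#' protocol, in loading order S1, P1, S2, P2, S3, P3, S4, P4. Equal volumes
#' of each supernatant/pellet pair are loaded (pellets resuspended to the
#' partner supernatant volume), so intensities are comparable across all
#' eight lanes.
#'
#' @param intensities numeric vector of 8 non-negative band intensities;
#'   names default to the fraction labels.
#' @return object of class `fractionation_series` carrying the spin scheme
#'   (1K/10 min, 10K/10 min, 30K/20 min, 100K/90 min) as an attribute.
#' @export
fractionation_series <- function(intensities) {
  if (length(intensities) != 8) stop("a fractionation series has 8 fractions")
  if (any(intensities < 0)) stop("band intensities must be non-negative")
  labs <- c("S1", "P1", "S2", "P2", "S3", "P3", "S4", "P4")
  x <- stats::setNames(as.numeric(intensities), labs)
  structure(x, class = "fractionation_series",
            spins = c(S1 = "1K rpm / 10 min", S2 = "10K rpm / 10 min",
                      S3 = "30K rpm / 20 min", S4 = "100K rpm / 90 min"))
}

#' Relative percentage of total protein in each fraction
#'
#' `p_i = 100 * I_i / sum(I)` over all eight loaded fractions jointly (the
#' supernatants are sequential, so percentages describe loaded material,
#' not a conserved mass balance). Percentages sum to 100 exactly before
#' rounding and are invariant under global intensity scaling.
#'
#' @param series a [fractionation_series()] (a plain length-8 vector is
#'   accepted).
#' @param digits rounding for the returned percentages (default 1; the
#'   printed convention is integers, `digits = 0`).
#' @return named numeric vector of percentages.
#' @export
fraction_percentages <- function(series, digits = 1) {
  if (!inherits(series, "fractionation_series")) {
    series <- fractionation_series(series)
  }
  total <- sum(series)
  if (total <= 0) stop("all-zero fractionation series")
  round_half_up(100 * as.numeric(series) / total, digits) |>
    stats::setNames(names(unclass(series)))
}
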