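#' Genotype preset for the synthetic movie generator
#'
#' A preset bundles the per-genotype timing and dynamics constants used to
#' schedule a synthetic enclosure movie: when the pocket cells first
#' protrude, when F-actin becomes enriched at the leading-cell (LC) leading
#' edge, when LC protrusions start, when the migrating front reaches the
#' ventral meeting line, the mean lifetime of leading-edge protrusions, and
#' the ventral bias of F-actin puncta.
#'
#' Event times are minutes after first cleavage; `NA` means the event never
#' happens for that genotype (e.g. enclosure failure). Events that are
#' defined must be ordered pocket protrusion <= LC enrichment <=
#' LC protrusion <= LC meeting.
#'
#' @param name genotype label.
#' @param t_pocket_protrusion minutes; first pocket-cell protrusion.
#' @param t_lc_enrichment minutes or `NA`; leading-edge F-actin enrichment.
#' @param t_lc_protrusion minutes or `NA`; first LC protrusion.
#' @param t_lc_meeting minutes or `NA`; front reaches the ventral meeting line.
#' @param mean_protrusion_duration minutes; mean protrusion lifetime (> 0).
#' @param ventral_peak_fraction probability in \[0, 1\] that a puncta-like
#'   intensity peak is placed in the ventral half of an LC.
#' @param peak_rate expected puncta per leading cell per frame (Poisson).
#' @param enrichment_offset µm; distance of the intensity ridge apex dorsal
#'   ("behind") the protrusive front.
#' @param baseline_intensity_scale dimensionless multiplier on the cell-body
#'   baseline intensity above background.
#' @return an object of class `genotype_preset`.
#' @seealso [builtin_presets()]
#' @export
genotype_preset <- function(name,
                            t_pocket_protrusion,
                            t_lc_enrichment,
                            t_lc_protrusion,
                            t_lc_meeting,
                            mean_protrusion_duration,
                            ventral_peak_fraction,
                            peak_rate,
                            enrichment_offset = 2,
                            baseline_intensity_scale = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  times <- c(t_pocket_protrusion, t_lc_enrichment, t_lc_protrusion, t_lc_meeting)
  defined <- times[!is.na(times)]
  if (length(defined) > 1L && any(diff(defined) < 0)) {
    stop("event times must be ordered: pocket protrusion <= LC enrichment <= ",
         "LC protrusion <= LC meeting")
  }
  if (!is.na(mean_protrusion_duration) && mean_protrusion_duration <= 0) {
    stop("mean_protrusion_duration must be positive")
  }
  if (ventral_peak_fraction < 0 || ventral_peak_fraction > 1) {
    stop("ventral_peak_fraction must lie in [0, 1]")
  }
  if (peak_rate < 0) stop("peak_rate must be non-negative")
  structure(list(
    name = name,
    t_pocket_protrusion = t_pocket_protrusion,
    t_lc_enrichment = t_lc_enrichment,
    t_lc_protrusion = t_lc_protrusion,
    t_lc_meeting = t_lc_meeting,
    mean_protrusion_duration = mean_protrusion_duration,
    ventral_peak_fraction = ventral_peak_fraction,
    peak_rate = peak_rate,
    enrichment_offset = enrichment_offset,
    baseline_intensity_scale = baseline_intensity_scale
  ), class = "genotype_preset")
}

#' Built-in genotype presets
#'
#' Presets for the wild type and the five morphogenesis mutants whose
#' enclosure dynamics the package emulates. Timing and protrusion-lifetime
#' constants are the published values: pocket-cell protrusions start at
#' 250 min after first cleavage in all genotypes; the wild-type front meets
#' the ventral midline at 320 min; wild-type protrusions last 2.5 min on
#' average while gex-3, sax-3 and vab-1 protrusions last 9, 6 and 6 min;
#' leading-edge enrichment is measured at ~260 (wild type, unc-6), ~270
#' (unc-40, vab-1) and ~275 (sax-3) min. gex-3 never enriches actin at the
#' leading edge, makes no LC protrusions and never encloses.
#'
#' Mutant meeting times (delayed relative to wild type) and the puncta
#' parameters `peak_rate` and `ventral_peak_fraction` are not printed
#' anywhere; they are package choices that respect the qualitative ordering
#' of ventral polarization (vab-1 < sax-3 < wild type) and are documented in
#' the methods vignette.
#'
#' @return named list of [genotype_preset()] objects with entries
#'   `wild_type`, `gex-3`, `unc-40`, `unc-6`, `sax-3`, `vab-1`.
#' @examples
#' builtin_presets()$wild_type$mean_protrusion_duration  # 2.5
#' @export
builtin_presets <- function() {
  list(
    wild_type = genotype_preset("wild_type", 250, 260, 262, 320,
                                mean_protrusion_duration = 2.5,
                                ventral_peak_fraction = 0.75, peak_rate = 3),
    `gex-3` = genotype_preset("gex-3", 250, NA, NA, NA,
                              mean_protrusion_duration = 9,
                              ventral_peak_fraction = 0.50, peak_rate = 1.5),
    `unc-40` = genotype_preset("unc-40", 250, 270, 272, 336,
                               mean_protrusion_duration = 2.5,
                               ventral_peak_fraction = 0.65, peak_rate = 3),
    `unc-6` = genotype_preset("unc-6", 250, 260, 262, 330,
                              mean_protrusion_duration = 3,
                              ventral_peak_fraction = 0.70, peak_rate = 3),
    `sax-3` = genotype_preset("sax-3", 250, 275, 277, 344,
                              mean_protrusion_duration = 6,
                              ventral_peak_fraction = 0.60, peak_rate = 2.5),
    `vab-1` = genotype_preset("vab-1", 250, 270, 272, 340,
                              mean_protrusion_duration = 6,
                              ventral_peak_fraction = 0.55, peak_rate = 2.5)
  )
}

#' Specification of a synthetic enclosure movie
#'
#' Collects everything [generate_movie()] needs: a [genotype_preset()], the
#' frame geometry, the spatial and temporal calibration, the imaging window,
#' and the camera model. Defaults mirror the published acquisition protocol:
#' 2-minute frame interval, imaging from 240 minutes after first cleavage,
#' 8-bit grey levels, and 0.15 µm/pixel (chosen so a 36-pixel measurement
#' box spans about a third of a ~16 µm leading cell).
#'
#' @param preset a [genotype_preset()] or the name of a built-in preset.
#' @param height,width frame size in pixels. The fixed embryo layout needs
#'   at least 160 x 190 pixels.
#' @param pixel_size µm per pixel.
#' @param frame_interval minutes between frames (> 0).
#' @param t_start minutes after first cleavage at the first frame.
#' @param n_frames number of frames (>= 1).
#' @param background_level camera background in grey levels.
#' @param noise_sigma standard deviation of additive Gaussian camera noise,
#'   in grey levels (0 disables noise).
#' @param seed integer RNG seed; the same spec and seed give a bit-identical
#'   movie.
#' @return an object of class `movie_spec`.
#' @export
movie_spec <- function(preset = "wild_type",
                       height = 170, width = 200,
                       pixel_size = 0.15,
                       frame_interval = 2,
                       t_start = 240,
                       n_frames = 45,
                       background_level = 30,
                       noise_sigma = 1,
                       seed = 1) {
  if (is.character(preset)) {
    presets <- builtin_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; see builtin_presets()")
    }
    preset <- presets[[preset]]
  }
  stopifnot(inherits(preset, "genotype_preset"))
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (background_level < 0) stop("background_level must be >= 0")
  if (height < 160 || width < 190) {
    stop("frame must be at least 160 x 190 pixels for the embryo layout")
  }
  if (!is.na(preset$mean_protrusion_duration) &&
      preset$mean_protrusion_duration < frame_interval) {
    stop("mean_protrusion_duration shorter than frame_interval cannot be ",
         "realized at this sampling rate")
  }
  structure(list(
    preset = preset, height = height, width = width,
    pixel_size = pixel_size, frame_interval = frame_interval,
    t_start = t_start, n_frames = n_frames,
    background_level = background_level, noise_sigma = noise_sigma,
    seed = seed
  ), class = "movie_spec")
}
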