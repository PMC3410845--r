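---
title: "Quantifying epidermal F-actin dynamics during ventral enclosure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epidermal F-actin dynamics during ventral enclosure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factinquant)
```

## The measurement problem

During *C. elegans* ventral enclosure, epidermal cells migrate over the
embryo surface and seal it. Two anterior Leading Cells (LCs) on each side
extend actin-rich protrusions that guide this migration; posterior pocket
cells protrude later and close the ventral pocket. Live imaging of an
F-actin reporter in the epidermis, at one frame every 2 minutes from 240
minutes after first cleavage, yields grey-level movies from which several
quantities are scored:

* **Leading-edge intensity** — the mean grey level in a 36 × 36 px box
  anchored at the midpoint of an LC's leading edge and extending dorsally,
  covering roughly a third of the cell length.
* **Ventral:dorsal polarization** — peaks along a ventral-to-dorsal line
  profile through an LC, a peak being a contiguous region at least 10 grey
  levels above background. Peaks are assigned to the ventral or dorsal half
  of the cell; the counts are summed over a 20-frame (40-minute) window
  starting at leading-edge enrichment, and total ventral is divided by
  total dorsal.
* **Enrichment offset** — the distance (µm) from the protrusive front to
  the profile's intensity apex; in the wild type the brightest F-actin sits
  about 2 µm behind the front.
* **Protrusion lifetimes** — how long individual leading-edge protrusions
  persist, in multiples of the 2-minute frame interval; about 2.5 min in
  the wild type versus 9, 6 and 6 min in *gex-3*, *sax-3* and *vab-1*.
* **Event timing** — first pocket-cell protrusion (≈250 min in all
  genotypes), leading-edge enrichment, first LC protrusion, and LC meeting
  (320 min in the wild type; later or never in mutants).
* **Phenotype tables and blot arithmetic** — embryo class percentages
  (wild-type / Full Gex / Partial Gex), ANOVA-based significance, and
  densitometry ratios for western blots and subcellular fractionations.

No raw imaging data are deposited for this kind of experiment, so the
package pairs every measurement with a seeded synthetic movie generator
whose ground truth makes the whole pipeline testable end to end.

## The synthetic movie model

`generate_movie()` renders a lateral-view simplification of the enclosure
stage on a fixed embryo layout:

* a horizontal epidermal band (cell bodies at background + 5 grey levels)
  whose ventral edge — the *front* — starts at a fixed row and, between LC
  protrusion onset and meeting, advances linearly (floored to the pixel
  grid) so that it reaches the ventral meeting line exactly at the preset
  meeting time;
* four cells spanning the band: two leading cells (anterior) and two pocket
  cells (posterior), each 40 px wide and 107 px long (16.05 µm at the
  default calibration), with a vertical ventral-dorsal axis through the
  cell centre;
* disk-shaped F-actin **puncta** (amplitude 40 over background, 5 px wide)
  placed on each LC axis, ventral with probability `ventral_peak_fraction`,
  with a 6 px minimum separation and a 3.5 px guard band around the cell
  midline so every punctum lies unambiguously in one half;
* an **enrichment ridge** — a 5-row triangular intensity crest peaking 125
  grey levels above background — rendered across the LCs from enrichment
  onset, with its apex `enrichment_offset` µm (13 px at defaults) dorsal to
  the current front;
* finger-like **protrusions**: 3 px wide, 6 px long extensions beyond the
  front at two fixed sites per active cell, placed left and right of the
  axis so they never contaminate the axis profile;
* additive Gaussian camera noise, clipped and rounded to 8-bit levels.

Everything placed is recorded: per-frame puncta with their half labels,
the protrusion episode table, the front row per frame, and the realized
event times. Ground-truth event times are defined by first appearance of
the corresponding rendered structure, which the test suite verifies by
direct pixel inspection.

### Protrusion lifetimes are a two-point mixture

Measured lifetimes are quantized to whole frames, so a generator drawing
continuous lifetimes would bias count-based recovery. Lifetimes are drawn
in frames from the two-point distribution on `{floor(m), ceiling(m)}` with
`P(ceiling(m)) = m - floor(m)`, where `m = mean_duration / frame_interval`.
The expected lifetime in minutes then equals the preset mean *exactly*; the
wild-type 2.5 min arises as a mixture of 2- and 4-minute tracks, matching
the scoring rule `duration = (last - first + 1) × interval`. Episodes are
only scheduled at frames from which the longer lifetime still fits inside
the movie, so realized lifetimes are an unbiased sample (no end-of-movie
censoring). A retraction gap of at least one frame separates consecutive
episodes at a site, which is what lets the tracker score retraction at
first absence without gap tolerance.

### What the generator does and does not emulate

The generator reproduces the *statistical structure* the measurements rely
on: puncta counts and their ventral bias, supra-threshold peak geometry,
protrusion lifetime distributions, event schedules, front advance, flat
camera background plus Gaussian noise. It does **not** attempt
photorealism: no 3D embryo curvature, no dorsal intercalation, no
photobleaching, no Poisson shot noise (not characterizable from published
material), no cell-shape changes, and puncta are only rendered in the
leading cells, on the axis the profile samples. Passing recovery tests on
these movies therefore demonstrates that the measurement code implements
its definitions correctly — not that the definitions are robust to every
artefact of real microscopy.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `frame_interval` | 2 | min | acquisition interval of the published protocol |
| `t_start` | 240 | min | imaging start, minutes after first cleavage |
| `pixel_size` | 0.15 | µm/px | makes the 36-px box ≈ a third of a ~16 µm LC |
| `threshold` (peaks) | 10 | grey levels | printed peak criterion, inclusive (≥) |
| `box_px` | 36 | px | printed box side |
| `n_frames` (window) | 20 | frames | printed 40-minute polarization window |
| `enrichment_factor` | 1.2 | — | no numeric criterion is published; box mean ≥ 1.2 × whole-cell mean is this package's operationalization |
| `min_extent_px` | 3 | px | minimum ventral extent for a protrusion |
| `background_level` | 30 | grey levels | flat camera background |
| `noise_sigma` | 1 | grey levels | see below |

The camera noise default is σ = 1 grey level. The published protocol
reduces camera background "to the lowest grey levels" by contrast
stretching before quantitation, and a ≥ 10-grey-level peak criterion is
only meaningful when noise is small compared to the 5-level margin between
the cell-body baseline and the threshold. At σ = 1 that margin is 5σ and
threshold crossings from noise are negligible; the measured peak counts on
default movies equal the placed counts exactly in the test suite.

## Numerical choices and tie rules

* **Background** is the modal intensity outside the embryo mask (the union
  of ROI footprints, dilated ventrally). The published procedure does not
  define "background"; the mode is robust to bright foreground and exact
  for a flat background model.
* **Peak threshold is inclusive**: intensity ≥ background + 10 counts. A
  single supra-threshold run is one peak regardless of internal wiggles
  (the criterion counts "regions"), and the apex takes the most ventral
  position on ties.
* **Half assignment** is by apex position; an apex exactly at half the
  cell length counts as **ventral**. The tie rule is arbitrary but must be
  deterministic and documented; the generator never places a punctum within
  3.5 px of the midline, so the rule never decides a generated comparison.
* **The V:D ratio** is undefined (flagged, not an error) when the dorsal
  total is zero.
* **Front detection** for protrusion scoring and event timing takes, per
  frame, the ventral-most row whose *median* intensity across the cell's
  columns is at least 2.5 grey levels above background. The median ignores
  the few bright protrusion columns, and at σ = 1 the margin is robust; on
  noiseless input the detected front equals the rendered front exactly. The
  `enrichment_offset()` front is deliberately simpler — the ventral-most
  strictly-above-background profile position — because that measurement is
  defined on low-noise enrichment frames.
* **Protrusion instances** must extend ≥ 3 px beyond the front *and* touch
  it (dorsal-most pixel within 3 rows), which excludes isolated noise
  specks; consecutive-frame instances are linked by bounding-box overlap
  with zero gap tolerance.
* **Percent rounding** in phenotype tables is to the nearest integer, half
  away from zero; exact values in (99, 100) display as ">99" and in (0, 1)
  as "<1", as printed tables do.
* **Tukey HSD** uses the Tukey–Kramer statistic with
  `stats::ptukey()` (accuracy well beyond the 1e-6 contract); for two
  groups it reproduces the one-way ANOVA p-value, which the tests assert.
* **Two-way ANOVA** is balanced-replicated only; the post-test compares
  factor-A levels within each factor-B level using the pooled residual
  mean square, with `p_adj = min(1, m·p)`.
* **Fractionation percentages** are computed over all eight loaded
  fractions jointly. The S fractions are sequential supernatants, so these
  are percentages of loaded material, not of a conserved mass balance;
  whether the published percentages were computed per S/P pair or across
  all fractions is not stated, and the all-fraction convention is this
  package's documented choice.
* **Blot-series noise** is mean-one lognormal on the non-reference bands,
  with the reference lane left noise-free. Ratio estimators with a noisy
  denominator are biased upward by ≈ 2·CV²; keeping the calibration lane
  clean makes the expected recovered ratio equal the truth, which is what
  the Monte-Carlo recovery test asserts.

## Open choices the data do not pin down

Per-genotype values for `peak_rate` and `ventral_peak_fraction` are never
printed (published V:D ratios appear only as bar graphs), so the presets
expose them as free parameters with the qualitative ordering
*vab-1* < *sax-3* < wild type for ventral bias, and they are not used as
recovery targets. Mutant meeting times are only described as "later than
wild type"; the presets use 330–344 min so that delayed enclosure falls
inside a default-length movie. The replicate structure behind published
phenotype-table ANOVAs is likewise unstated; the statistics module accepts
per-replicate percentage lists and makes no claim about the original
analysis, and deliberately does not substitute count-based exact tests.

Coordinates are R-native 1-based indices with row 1 = dorsal-most; all
reported distances are in µm via `pixel_size`, so the indexing convention
never reaches the results.

## Problem sizes

The test suite and the acceptance script use 170 × 200 px movies of 45
frames (240–328 min). Lifetime-recovery runs pool 20 seeded movies per
genotype (≈ 2000 wild-type tracks, ≈ 500 *gex-3* tracks), ratio-recovery
runs pool ≈ 300–500 placed puncta per condition, and the ANOVA
calibration uses 1000 null replicates. These sizes give Monte-Carlo
standard errors comfortably below the published precision of each
quantity while a full suite run stays in the minutes range on one CPU.

## Known limitations

* ROIs are inputs (or generator outputs); there is no automatic cell
  segmentation from raw images.
* Event timing has frame-interval resolution by design; no sub-frame
  interpolation is attempted.
* The protrusion criterion is a geometric operationalization of what was
  originally manual scoring; agreement with the generator's ground truth
  does not certify agreement with a human scorer.
* The two-way ANOVA is restricted to balanced designs with replicates.
* `detect_events()` assumes the lateral-view geometry of the generator
  (front advancing toward a meeting line); applying it to differently
  oriented movies requires re-expressing the ROIs in that convention.
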