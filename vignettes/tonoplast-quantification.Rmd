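---
title: "Quantifying vacuole organization and tonoplast motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vacuole organization and tonoplast motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonodyn)
```

## The measurement problem

Plant root epidermis cells build their central vacuole progressively: young
cells near the root tip hold many small vacuolar compartments bounded by a
convoluted tonoplast membrane, which fuse into one large central vacuole as
cells elongate. On top of this slow ontogenetic process, the tonoplast
undergoes rapid, cytoplasmic-streaming-driven motion on the scale of
seconds. `tonodyn` quantifies both aspects from single-plane confocal
images of a fluorescent tonoplast marker:

* **Vacuolar morphology index (VMI)** — the size of the largest vacuolar
  compartment in a cell's optical section, in square micrometers. We
  operationalize it as the product of the maximal Feret diameter of the
  largest-area lumen compartment and its maximal extent perpendicular to
  that diameter. Higher VMI means a more consolidated (more mature) central
  vacuole. VMI is natural-log transformed before testing, which brings its
  right-skewed distribution closer to normal.
* **Tonoplast topology index (TTI)** — the number of tonoplast membrane
  crossings per micrometer along a diagonal transect of the cell rectangle.
  Higher TTI means a more convoluted, fragmented vacuome.
* **Frame-to-first-frame correlation `R(t)`** — the Pearson correlation of
  pixel intensities between a movie's first frame and the frame at time
  `t`, computed per cell on preprocessed recordings. Membrane motion
  decorrelates the image, so faster tonoplast dynamics pull `R(t)` down
  more steeply. The single-number endpoint `r_end` is `R` at the frame
  nearest the 120-second horizon.

Cells are additionally stratified by length into "small" (below the pooled
median) and "large" (above it), a proxy for developmental stage; group
differences are evaluated per stratum with nonparametric tests and
Benjamini–Hochberg (BH) false-discovery-rate correction.

## Preprocessing chain

Motility measurements run the literal preprocessing order used in
interactive confocal workflows:

1. percentile contrast enhancement (default 0.35% of pixels saturated in
   total — the conventional "default" of the Enhance Contrast operation)
   and conversion to 8 bits;
2. rigid-body registration of every frame to the first frame, removing slow
   growth drift;
3. rotation by a user-supplied angle to orient the root vertically (the
   original step is manual, so no auto-detection is attempted);
4. cropping to per-cell rectangular ROIs, whose y-extent times the pixel
   size defines the cell length;
5. per-ROI contrast enhancement with per-ROI percentiles (the default;
   global scaling can be kept by skipping this step).

The registration estimator maximizes valid-pixel Pearson correlation over a
three-level image pyramid: a coarse rotation grid (±12°, 2° steps) combined
with FFT cross-correlation for the residual translation seeds a Nelder–Mead
subpixel refinement; the two best coarse candidates are refined and the
winner is polished at full resolution. On noiseless synthetic warps with
shifts up to 10 px and rotations up to 10° the recovery error stays below
0.5 px and 0.5° (the test suite asserts this over 20 random warps), and
registering an already-registered stack returns near-identity transforms
(≤ 0.25 px / 0.25°). Along a stack, each frame's estimate warm-starts from
the previous frame, which makes slow cumulative drift cheap to track.

## The synthetic ground-truth generator

No real microscope data ships with the package; every claim is exercised on
synthetic images with known ground truth. The generator emulates:

* rectangular cells with dark lumen compartments bounded by bright membrane
  ridges (thickness 3 px by default) on a uniform background;
* compartment shapes: discs deformed by one low-order radial harmonic
  (`r(φ) = r₀(1 + a·cos(kφ + φ₀))`), the minimal family that makes membrane
  convolutedness — and hence TTI — tunable;
* two presets spanning the biological contrast of interest:
  `"consolidated"` (1–2 large, nearly round compartments) and
  `"fragmented"` (6–8 small, wavier compartments, radii 5.5–8 px, separated
  by a ≥ 4 px cytoplasm gap so neighboring membranes stay resolvable after
  blur);
* optics and noise: Gaussian PSF blur (σ = 1 px), Poisson shot noise,
  Gaussian read noise, and global multiplicative bleaching
  (`(1 − rate)^frame`), rendered in float and quantized to 16 bits on
  write;
* motion: slow rigid growth drift accumulating a fixed per-frame transform,
  plus fast membrane motion modeled as a smooth Gaussian-process
  displacement of each compartment (temporal correlation length 3 frames)
  whose per-frame step RMS equals the `membrane_speed` parameter. This
  produces the monotone correlation decay seen in real recordings without
  modeling cytoplasmic streaming physics. Compartments are clamped inside
  their cell with clamp events counted in the ground truth.

Default geometry is 0.11 µm/px, 2 s frame interval and 61 frames (a 0–120 s
horizon). Real recordings' pixel size and frame rate vary by instrument;
these values are conventions chosen once, not measurements.

What the generator does **not** emulate: three-dimensional structure and
out-of-focus light, trichoblast/atrichoblast patterning, nonstationary
streaming (bursts, reversals), membrane-proximal organelles, and detector
artifacts beyond Poisson–Gaussian noise. Passing tests therefore show that
the measurement chain recovers known geometry and motion under realistic
noise — not that biological images are this clean.

## Numerical and design choices

* **Segmentation.** Lumen compartments are the 4-connected components of
  the complement of the Otsu-thresholded, morphologically closed membrane
  mask (closing disc radius 2 px, below the smallest lumen radius so no
  compartment is sealed). The component touching all four ROI edges is the
  extracellular exterior and is removed; components touching some edge are
  kept but flagged, since central vacuoles genuinely abut the cell edge in
  elongated cells. Components under 9 px are discarded as noise specks
  (sub-diffraction regions are not compartments).
* **VMI strategy.** Feret × perpendicular extent is the default; the area
  of the largest compartment is available behind `vmi_strategy = "area"`.
  Both are computed from the same labeled mask.
* **TTI transect.** Top-left to bottom-right diagonal by default; the
  `"both"` mode averages the two diagonals, which halves the geometric
  sampling variance of the crossing count (whether a sparse compartment
  straddles one particular diagonal is chance) and is what the end-to-end
  discrimination analyses use. The profile is sampled at 0.5 px
  with bilinear interpolation and binarized by Otsu. Runs containing either
  transect endpoint are excluded as plasma-membrane contacts. A profile
  whose relative contrast is below 5% (a transect that misses every
  membrane and sees only blur ripple) has no meaningful threshold and is
  flagged degenerate with zero crossings.
* **Crossing parity.** A closed membrane is pierced an even number of times
  by a transversal line; the test suite asserts even crossing counts for
  cells whose diagonal clearly pierces or clearly misses every compartment
  (`diagonal_transversal()`). A transect grazing a ring within the blur
  length merges the two wall crossings into one intensity run — an odd
  count that is correct behavior of the run counter, not a defect, which is
  why parity is only asserted over the transversal subset.
* **Correlation window.** `window = "full"` (global Pearson over the ROI)
  is the default because it is analytically transparent; a tiled
  `window = w` variant averages per-block Pearson over non-overlapping
  `w × w` blocks, skipping zero-variance blocks rather than counting them
  as zero (an undefined correlation should not bias the mean).
* **Median split.** Below-median cells are "small", above-median "large";
  with an odd count, the median cell joins the class of its closest
  neighbor by length, with an exact tie going to "small". The
  closest-neighbor rule compares metric distances, so the median cell's
  assignment is invariant under linear but not general monotone rescaling;
  all other cells' classes depend on ranks only.
* **Tests.** Mann–Whitney uses exact enumeration when the combined sample
  is ≤ 12 without ties, otherwise the tie-corrected normal approximation
  without continuity correction — this makes identical samples give
  exactly p = 1 and preserves the algebraic equivalence with the two-group
  Kruskal–Wallis test. Dunn's post hoc z-statistics are computed from
  pooled mean ranks with the standard tie correction and BH-adjusted across
  pairs. The two-way ANOVA uses type II sums of squares (valid for the
  unbalanced layouts that per-cell attrition produces) with Welch's t for
  two-sample parametric comparisons. Significance bands: `**` for
  p ≤ 0.01, `*` for 0.01 < p ≤ 0.05, `(*)` for 0.05 < p < 0.1, `NS`
  otherwise. BH families span one metric at a time (both strata of one
  metric form one family).

## What the end-to-end checks compute

The acceptance layer (`tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) re-runs the whole chain on generated data at the
study scale: 40 cells per group and 61 frames for motility (speed grid 0,
0.5, 1, 2 px/frame — group-mean `r_end` must decrease strictly with speed,
with motionless cells above 0.95), 20 cells per preset for morphology
(consolidated cells must show the higher median VMI and lower median TTI,
with the TTI contrast — both diagonals averaged — significant after BH), 20 random rigid warps for
registration, 100 random cells for the TTI oracle, 1,000 random p-vectors
for BH, 2,000 null simulations for the stratified comparison's type-I
error, and a drifting motionless movie for the
registration-before-correlation rationale. Those scripts print every number
they assert; this vignette states no result they do not compute.

## A compact example

```{r example, eval = FALSE}
op <- optics_spec()
cells <- generate_cell_population(5, "fragmented", seed = 1)
frame <- render_frame(list(cells[[1]]), op, seed = 2)$image
mask <- segment_lumen(frame, synth_roi(cells[[1]]))
compute_vmi(mask)
compute_tti(frame, synth_roi(cells[[1]]))

mo <- motion_spec(n_frames = 61, membrane_speed = 1, seed = 3)
sim <- simulate_timelapse(cells[1], op, mo)
res <- run_motility_pipeline(sim$movie, list(synth_roi(cells[[1]])),
                             run_config(register = FALSE))
res$r_end
```

## Known limitations

* The VMI and TTI definitions follow their verbal descriptions in the
  vacuole-morphometry literature; they are reimplementations, not certified
  ports of any particular plugin, and the original tools' auxiliary filter
  sets are not reproduced.
* The correlation measure uses the global-Pearson reading of the
  "average R per frame" contract; plugin-specific sliding-window semantics
  are approximated by the tiled option.
* Registration is rigid only (translation + rotation); elongating roots
  that deform non-rigidly within the 120-s window will leave residual
  motion in `R(t)`.
* Statistics pool cells across roots; no mixed-effects/nesting correction
  is attempted.
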