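# tonodyn

Quantitative analysis of central-vacuole organization and rapid tonoplast
motility in plant root rhizodermis cells, from single-plane confocal images
and time-lapse recordings of a fluorescent tonoplast marker.

Root epidermis cells mature by fusing many small vacuolar compartments into
one central vacuole, while the tonoplast (the vacuole-bounding membrane)
also moves rapidly with cytoplasmic streaming on the scale of seconds.
`tonodyn` measures both processes per cell:

* **VMI** (vacuolar morphology index, µm²) — size of the largest vacuolar
  compartment in the optical section, operationalized as
  `Feret_max × extent_⊥` of the largest-area lumen compartment, analyzed as
  `ln(VMI)`. Higher VMI = more consolidated vacuole.
* **TTI** (tonoplast topology index, µm⁻¹) — tonoplast membrane crossings
  per unit length along a diagonal cell transect:
  `TTI = crossings / (transect length × pixel size)`. Higher TTI = more
  convoluted, fragmented vacuome.
* **R(t)** — Pearson correlation of pixel intensities between the first
  movie frame and the frame at time `t`, computed after contrast
  enhancement, 8-bit conversion, rigid-body drift registration, rotation to
  vertical and per-cell ROI cropping. Fast membrane motion decorrelates the
  image, so `R(t)` decays; the endpoint `r_end = R(120 s)` summarizes
  motility per cell. Kymographs along a transect visualize the same motion.

Cells are stratified into "small"/"large" by the pooled median length
(odd counts resolved by the closest-neighbor rule), and group contrasts are
tested with Mann–Whitney (exact for small tie-free samples), Kruskal–Wallis
with Dunn's post hoc, Welch's t, or two-way type-II ANOVA, with
Benjamini–Hochberg FDR correction per metric family.

A synthetic generator (`generate_cell_population()`, `render_frame()`,
`simulate_timelapse()`) renders tonoplast-like cells — harmonic-deformed
lumen compartments with bright membrane ridges, PSF blur, Poisson/Gaussian
noise, bleaching, rigid growth drift and Gaussian-process membrane motion —
with full ground truth, so the entire chain is testable without microscope
data.

## Worked example

The numbered drivers under `analysis/` run the two workflows end to end on
synthetic data (`01_simulate.R` writes the images first; tables land in
`results/`). `analysis/02_morphology.R` compares 12 consolidated against 12
fragmented cells and prints:

```
consolidated  n=12  median VMI  27.12 um^2  median TTI 0.112 /um
fragmented    n=12  median VMI   1.65 um^2  median TTI 0.156 /um

stratified comparisons (BH-adjusted within each metric family):
     metric stratum       group1     group2       p_raw       p_adj stars
     ln_vmi   small consolidated fragmented 0.002525253 0.002525253    **
     ln_vmi   large consolidated fragmented 0.002525253 0.002525253    **
 tti_per_um   small consolidated fragmented 0.022751642 0.045503285     *
 tti_per_um   large consolidated fragmented 0.106060606 0.106060606    NS
```

Consolidated cells carry one large compartment (median VMI 27 µm² vs
1.7 µm²) and fewer membrane crossings (median TTI 0.112 µm⁻¹ vs
0.156 µm⁻¹) — the morphological signature of an advanced central vacuole.
`analysis/03_motility.R` contrasts slow (0.3 px/frame) and fast
(1.5 px/frame) membrane motion and demonstrates the registration rationale:

```
slow  mean R(120 s) = 0.753 (n = 12)
fast  mean R(120 s) = 0.234 (n = 12)

r_end with registration:    0.976
r_end without registration: -0.038
```

Faster membrane motion pulls the 120-s correlation endpoint down, and a
motionless cell drifting 1 px/frame looks maximally "motile" unless the
drift is removed by registration first. `analysis/04_stats.R` exercises the
multi-group battery (Kruskal–Wallis + Dunn, two-way ANOVA) on a synthetic
genotype × treatment design.

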