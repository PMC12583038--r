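# Shared fixtures: noiseless optics for geometric oracles, and small helpers
# to build single-cell frames and movies in code.

quiet_optics <- function(...) {
  optics_spec(poisson_gain = 0, gaussian_sigma = 0, bleach_rate = 0, ...)
}

# One synthetic cell rendered noiselessly; returns cells, frame, labels, roi.
make_cell_frame <- function(preset = "consolidated", seed = 1,
                            optics = quiet_optics(), ...) {
  cells <- generate_cell_population(1, preset, seed = seed, ...)
  fr <- render_frame(cells, optics, apply_noise = FALSE)
  list(cells = cells, image = fr$image, labels = fr$labels,
       roi = synth_roi(cells[[1]], pixel_size_um = optics$pixel_size_um))
}

# A hand-built cell_spec with circular compartments at given centers/radii.
manual_cell <- function(rect, centers, radii, amp = 0, k_harm = 3,
                        phase = 0, id = "manual", label = "manual") {
  n <- length(radii)
  tonodyn:::new_cell_spec(
    cell_id = id, rect = rect, centers = centers, radii = radii,
    amp = rep(amp, n), k_harm = rep(k_harm, n), phase = rep(phase, n),
    condition_label = label, pixel_size_um = 0.11)
}

# Rasterized disc label matrix (single compartment), 0-based center coords.
disc_labels <- function(dim, center, r) {
  h <- dim[1]; w <- dim[2]
  px <- rep(0:(w - 1), each = h); py <- rep(0:(h - 1), times = w)
  matrix(as.integer(sqrt((px - center[1])^2 + (py - center[2])^2) <= r),
         nrow = h)
}
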