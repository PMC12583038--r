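# Synthetic tonoplast image and movie generator.
#
# Cells are axis-aligned rectangles containing dark vacuole-lumen compartments
# bounded by bright thin membrane ridges, mimicking a tonoplast marker in
# root rhizodermis cells imaged by spinning-disc confocal microscopy.
# Compartments are discs deformed by a low-order radial harmonic, the minimal
# shape family that makes membrane convolutedness (and hence the transect
# crossing count) tunable.

#' Optics and noise model for synthetic rendering
#'
#' Intensities are on a 16-bit-like arbitrary-unit scale. The rendering
#' pipeline is: paint membrane/lumen/background, Gaussian blur of scale
#' `psf_sigma_px` (point-spread proxy), global multiplicative bleaching,
#' Poisson shot noise (`poisson_gain` photons per intensity unit; 0 disables),
#' then additive Gaussian read noise.
#'
#' @param pixel_size_um micrometers per pixel.
#' @param membrane_thickness_px thickness of the rendered tonoplast ridge.
#' @param membrane_intensity,lumen_intensity,background_intensity intensities
#'   (arbitrary units); must satisfy membrane > background >= lumen >= 0.
#' @param psf_sigma_px Gaussian blur sigma in pixels (>= 0).
#' @param poisson_gain photons per intensity unit; 0 disables shot noise.
#' @param gaussian_sigma read-noise standard deviation.
#' @param bleach_rate per-frame multiplicative signal decay in `[0, 1)`.
#' @return a list of class `optics_spec`.
#' @export
optics_spec <- function(pixel_size_um = 0.11, membrane_thickness_px = 3,
                        membrane_intensity = 12000, lumen_intensity = 500,
                        background_intensity = 1500, psf_sigma_px = 1,
                        poisson_gain = 0.02, gaussian_sigma = 120,
                        bleach_rate = 0.004) {
  stopifnot(membrane_intensity > background_intensity,
            background_intensity >= lumen_intensity, lumen_intensity >= 0,
            psf_sigma_px >= 0, poisson_gain >= 0, gaussian_sigma >= 0,
            bleach_rate >= 0, bleach_rate < 1)
  structure(as.list(environment()), class = "optics_spec")
}

#' Motion model for synthetic time-lapse movies
#'
#' Two motion components are superimposed: a slow rigid drift (growth proxy)
#' accumulating `drift_per_frame` every frame, and fast stochastic membrane
#' motion modeled as a smooth Gaussian-process displacement of each
#' compartment (temporal correlation length 3 frames) whose per-frame step
#' RMS equals `membrane_speed` pixels.
#'
#' @param n_frames number of frames (>= 2 for a movie).
#' @param frame_interval_s seconds between frames.
#' @param drift_per_frame numeric length-3: `(dx_px, dy_px, theta_deg)` rigid
#'   drift added each frame (applied cumulatively about the image center).
#' @param membrane_speed RMS per-frame boundary displacement, px/frame.
#' @param seed integer seed controlling all stochastic components.
#' @return a list of class `motion_spec`.
#' @export
motion_spec <- function(n_frames = 61, frame_interval_s = 2,
                        drift_per_frame = c(0, 0, 0), membrane_speed = 0,
                        seed = 1L) {
  stopifnot(n_frames >= 2, membrane_speed >= 0,
            length(drift_per_frame) == 3)
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 drift_per_frame = as.numeric(drift_per_frame),
                 membrane_speed = membrane_speed, seed = as.integer(seed)),
            class = "motion_spec")
}

# One synthetic cell: rectangle + compartment geometry. Internal constructor;
# users normally obtain these from generate_cell_population().
new_cell_spec <- function(cell_id, rect, centers, radii, amp, k_harm, phase,
                          condition_label, pixel_size_um, preset = NA_character_) {
  stopifnot(nrow(centers) == length(radii), length(radii) == length(amp))
  structure(
    list(cell_id = as.character(cell_id), rect = as.numeric(rect),
         length_um = rect[4] * pixel_size_um,
         n_compartments = length(radii), centers = centers, radii = radii,
         amp = amp, k_harm = k_harm, phase = phase,
         condition_label = as.character(condition_label), preset = preset),
    class = "cell_spec")
}

# Effective outer radius of a compartment (harmonic crest + half membrane).
comp_outer_radius <- function(cell, j, thickness) {
  cell$radii[j] * (1 + cell$amp[j]) + thickness / 2
}

#' Generate a population of synthetic cells
#'
#' Draws `n_cells` rectangular cells with randomly packed vacuole
#' compartments. Two presets emulate the biological extremes seen in root
#' atrichoblasts: `"consolidated"` (1-2 large compartments, nearly round — an
#' advanced central vacuole) and `"fragmented"` (6 or more small, wavier
#' compartments — an immature, convoluted vacuome). Cell heights (lengths)
#' are drawn uniformly from `cell_height_px_range`.
#'
#' @param n_cells number of cells (>= 1).
#' @param preset `"consolidated"` or `"fragmented"`.
#' @param seed integer seed; identical inputs give identical populations.
#' @param pixel_size_um micrometers per pixel.
#' @param cell_width_px cell rectangle width.
#' @param cell_height_px_range min/max cell rectangle height.
#' @param membrane_thickness_px membrane ridge thickness used for margins.
#' @param layout `"separate"` places every cell at the origin of its own
#'   frame; `"column"` stacks cells vertically in one shared frame with a
#'   `gap_px` spacer.
#' @param gap_px spacing between cells for `layout = "column"`.
#' @param condition_label label carried by every cell (defaults to preset).
#' @return list of `cell_spec` objects.
#' @export
generate_cell_population <- function(n_cells,
                                     preset = c("consolidated", "fragmented"),
                                     seed = 1L, pixel_size_um = 0.11,
                                     cell_width_px = 72,
                                     cell_height_px_range = c(110, 170),
                                     membrane_thickness_px = 3,
                                     layout = c("separate", "column"),
                                     gap_px = 12, condition_label = NULL) {
  preset <- match.arg(preset)
  layout <- match.arg(layout)
  stopifnot(n_cells >= 1, cell_width_px >= 24,
            diff(cell_height_px_range) >= 0, cell_height_px_range[1] >= 48)
  if (is.null(condition_label)) condition_label <- preset
  set.seed(seed)
  t <- membrane_thickness_px
  y_cursor <- 0
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    h <- round(stats::runif(1, cell_height_px_range[1],
                            cell_height_px_range[2]))
    w <- cell_width_px
    rect <- if (layout == "column") c(0, y_cursor, w, h) else c(0, 0, w, h)
    y_cursor <- y_cursor + h + gap_px
    geom <- switch(preset,
      consolidated = list(n_rng = 1:2,
                          r_fun = function(n) {
                            r1 <- stats::runif(1, 0.30, 0.40) * min(w, h)
                            if (n == 1) r1 else
                              c(r1, stats::runif(1, 0.10, 0.16) * min(w, h))
                          },
                          amp_rng = c(0.03, 0.10), k_rng = 2:4),
      fragmented   = list(n_rng = 6:8,
                          r_fun = function(n) stats::runif(n, 5.5, 8),
                          amp_rng = c(0.10, 0.20), k_rng = 3:5))
    n_comp <- if (length(geom$n_rng) == 1) geom$n_rng else
      sample(geom$n_rng, 1)
    radii <- geom$r_fun(n_comp)
    amp <- stats::runif(n_comp, geom$amp_rng[1], geom$amp_rng[2])
    k_harm <- sample(geom$k_rng, n_comp, replace = TRUE)
    phase <- stats::runif(n_comp, 0, 2 * pi)
    stopifnot(all(radii > t))  # radii must exceed membrane thickness
    centers <- pack_compartments(rect, radii, amp, t)
    if (is.null(centers)) {
      stop(sprintf("packing failure: could not place %d compartments in a %d x %d cell",
                   n_comp, w, h))
    }
    cells[[i]] <- new_cell_spec(
      cell_id = sprintf("%s_%02d", preset, i), rect = rect,
      centers = centers, radii = radii, amp = amp, k_harm = k_harm,
      phase = phase, condition_label = condition_label,
      pixel_size_um = pixel_size_um, preset = preset)
  }
  cells
}

# Rejection-sampling placement of non-overlapping compartments strictly
# inside `rect` with a 2 px margin. Returns an n x 2 matrix of centers or
# NULL after bounded retries (caller raises the packing-failure error).
pack_compartments <- function(rect, radii, amp, thickness,
                              margin = 2, max_restarts = 40,
                              tries_per_comp = 120) {
  n <- length(radii)
  r_out <- radii * (1 + amp) + thickness / 2
  for (restart in seq_len(max_restarts)) {
    centers <- matrix(NA_real_, n, 2)
    ok_all <- TRUE
    for (j in order(r_out, decreasing = TRUE)) {
      lo_x <- rect[1] + r_out[j] + margin
      hi_x <- rect[1] + rect[3] - 1 - r_out[j] - margin
      lo_y <- rect[2] + r_out[j] + margin
      hi_y <- rect[2] + rect[4] - 1 - r_out[j] - margin
      if (hi_x <= lo_x || hi_y <= lo_y) return(NULL)  # cannot ever fit
      placed <- FALSE
      for (try in seq_len(tries_per_comp)) {
        cand <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
        prev <- which(!is.na(centers[, 1]))
        if (length(prev) == 0 ||
            all(sqrt(rowSums((centers[prev, , drop = FALSE] -
                              matrix(cand, length(prev), 2, byrow = TRUE))^2)) >
                r_out[prev] + r_out[j] + 4)) {  # 4 px cytoplasm gap
          centers[j, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok_all <- FALSE; break }
    }
    if (ok_all) return(centers)
  }
  NULL
}

#' Render one synthetic frame with ground-truth labels
#'
#' Paints every cell's compartments (bright membrane ridge of the configured
#' thickness around a dark lumen) on a uniform background, blurs with the
#' optical PSF, and optionally applies shot/read noise. The returned label
#' image marks each lumen compartment (interior strictly inside the membrane)
#' with a globally unique positive label.
#'
#' @param cells list of `cell_spec` (see [generate_cell_population()]).
#' @param optics an [optics_spec()].
#' @param dim frame shape `c(height, width)`; default bounds all cell rects.
#' @param seed optional seed for the noise draw (set only when not `NULL`).
#' @param apply_noise logical; disable for noiseless ground-truth rendering.
#' @param displacement optional list (per cell) of n_compartments x 2 center
#'   offsets; used by the time-lapse simulator.
#' @param phase_offset optional list (per cell) of per-compartment phase
#'   offsets in radians (shape rotation under rigid drift).
#' @param drift length-3 `(dx, dy, theta_deg)` rigid transform applied to the
#'   whole scene about the frame center.
#' @param bleach_factor global multiplicative intensity factor.
#' @return list with `image` (numeric matrix) and `labels` (integer matrix).
#' @export
render_frame <- function(cells, optics, dim = NULL, seed = NULL,
                         apply_noise = TRUE, displacement = NULL,
                         phase_offset = NULL, drift = c(0, 0, 0),
                         bleach_factor = 1) {
  stopifnot(inherits(optics, "optics_spec"))
  if (is.null(dim)) {
    dim <- c(max(vapply(cells, function(c) c$rect[2] + c$rect[4], 0)),
             max(vapply(cells, function(c) c$rect[1] + c$rect[3], 0)))
  }
  h <- dim[1]; w <- dim[2]
  img <- matrix(optics$background_intensity, h, w)
  labels <- matrix(0L, h, w)
  centerpt <- c((w - 1) / 2, (h - 1) / 2)
  th_rad <- drift[3] * pi / 180
  t2 <- optics$membrane_thickness_px / 2
  label_id <- 0L
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    for (j in seq_len(cell$n_compartments)) {
      label_id <- label_id + 1L
      cen <- cell$centers[j, ]
      if (!is.null(displacement)) cen <- cen + displacement[[ci]][j, ]
      ph <- cell$phase[j]
      if (!is.null(phase_offset)) ph <- ph + phase_offset[[ci]][j]
      # whole-scene rigid drift: move center, rotate harmonic shape
      if (any(drift != 0)) {
        moved <- rigid_apply_points(cen[1], cen[2], drift[1], drift[2],
                                    drift[3], centerpt)
        cen <- c(moved$x, moved$y)
        ph <- ph - cell$k_harm[j] * th_rad
      }
      r_out <- cell$radii[j] * (1 + cell$amp[j]) + t2 + 1
      xs <- max(0, floor(cen[1] - r_out)):min(w - 1, ceiling(cen[1] + r_out))
      ys <- max(0, floor(cen[2] - r_out)):min(h - 1, ceiling(cen[2] + r_out))
      if (length(xs) == 0 || length(ys) == 0) next
      px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
      rho <- sqrt((px - cen[1])^2 + (py - cen[2])^2)
      phi <- atan2(py - cen[2], px - cen[1])
      Rb <- cell$radii[j] * (1 + cell$amp[j] * cos(cell$k_harm[j] * phi + ph))
      lum <- rho <= Rb - t2
      mem <- abs(rho - Rb) <= t2
      idx <- cbind(py + 1, px + 1)
      img[idx[lum, , drop = FALSE]] <- optics$lumen_intensity
      img[idx[mem, , drop = FALSE]] <- optics$membrane_intensity
      labels[idx[lum, , drop = FALSE]] <- label_id
    }
  }
  if (optics$psf_sigma_px > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = optics$psf_sigma_px))
  }
  img <- img * bleach_factor
  if (apply_noise && (optics$poisson_gain > 0 || optics$gaussian_sigma > 0)) {
    if (!is.null(seed)) set.seed(seed)
    if (optics$poisson_gain > 0) {
      img <- matrix(stats::rpois(length(img), pmax(img, 0) * optics$poisson_gain) /
                      optics$poisson_gain, nrow = h)
    }
    if (optics$gaussian_sigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, optics$gaussian_sigma),
                          nrow = h)
    }
    img <- pmax(img, 0)
  }
  list(image = img, labels = labels)
}

#' Simulate a tonoplast time-lapse movie with ground truth
#'
#' Renders `motion$n_frames` frames. Frame `k` (0-based) sees the cumulative
#' rigid drift `k * drift_per_frame` and a smooth stochastic displacement of
#' every compartment with per-frame RMS step `membrane_speed`. Compartments
#' are clamped so they never leave their cell rectangle (clamp events are
#' counted in the ground truth). Bleaching multiplies frame `k` by
#' `(1 - bleach_rate)^k`.
#'
#' @param cells list of `cell_spec`.
#' @param optics an [optics_spec()].
#' @param motion a [motion_spec()].
#' @param dim frame shape `c(height, width)`; default bounds all cell rects.
#' @param return_labels logical; also return per-frame ground-truth label
#'   images (memory-heavy, meant for tests).
#' @return list with `movie` (a [tono_movie()]) and `truth`: a list holding
#'   `transforms` (per-frame cumulative `dx, dy, theta_deg`), `boundary_disp`
#'   (per-frame mean compartment displacement from frame 0, px), `clamp_count`,
#'   and `cells` (the population table, see [population_table()]); plus
#'   `labels` when requested.
#' @export
simulate_timelapse <- function(cells, optics, motion, dim = NULL,
                               return_labels = FALSE) {
  stopifnot(inherits(motion, "motion_spec"))
  set.seed(motion$seed)
  nf <- motion$n_frames
  # smooth per-compartment displacement tracks (GP via Gaussian smoothing of
  # white noise, correlation length 3 frames), scaled to the target step RMS
  disp_tracks <- lapply(cells, function(cell) {
    lapply(seq_len(cell$n_compartments), function(j) {
      if (motion$membrane_speed == 0) return(matrix(0, nf, 2))
      raw <- matrix(stats::rnorm(2 * (nf + 12)), ncol = 2)
      kern <- stats::dnorm(-6:6, sd = 3); kern <- kern / sum(kern)
      sm <- apply(raw, 2, function(col) {
        stats::filter(col, kern, sides = 2)[7:(nf + 6)]
      })
      sm <- sweep(sm, 2, sm[1, ])  # start at zero displacement
      steps <- diff(sm)
      rms <- sqrt(mean(rowSums(steps^2)))
      if (rms == 0) return(matrix(0, nf, 2))
      sm * motion$membrane_speed / rms
    })
  })
  clamp_count <- 0L
  t2 <- optics$membrane_thickness_px / 2
  frames <- vector("list", nf)
  labels_out <- if (return_labels) vector("list", nf) else NULL
  mean_disp <- numeric(nf)
  transforms <- data.frame(frame = 0:(nf - 1),
                           dx = (0:(nf - 1)) * motion$drift_per_frame[1],
                           dy = (0:(nf - 1)) * motion$drift_per_frame[2],
                           theta_deg = (0:(nf - 1)) * motion$drift_per_frame[3])
  for (k in seq_len(nf)) {
    disp_k <- vector("list", length(cells))
    all_d <- numeric(0)
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      dmat <- matrix(0, cell$n_compartments, 2)
      for (j in seq_len(cell$n_compartments)) {
        d <- disp_tracks[[ci]][[j]][k, ]
        pos <- cell$centers[j, ] + d
        r_eff <- comp_outer_radius(cell, j, optics$membrane_thickness_px)
        lo <- c(cell$rect[1], cell$rect[2]) + r_eff + 2
        hi <- c(cell$rect[1] + cell$rect[3], cell$rect[2] + cell$rect[4]) -
          1 - r_eff - 2
        clamped <- pmin(pmax(pos, lo), hi)
        if (any(clamped != pos)) clamp_count <- clamp_count + 1L
        dmat[j, ] <- clamped - cell$centers[j, ]
      }
      disp_k[[ci]] <- dmat
      all_d <- c(all_d, sqrt(rowSums(dmat^2)))
    }
    mean_disp[k] <- mean(all_d)
    fr <- render_frame(cells, optics, dim = dim, apply_noise = TRUE,
                       displacement = disp_k,
                       drift = c(transforms$dx[k], transforms$dy[k],
                                 transforms$theta_deg[k]),
                       bleach_factor = (1 - optics$bleach_rate)^(k - 1))
    frames[[k]] <- fr$image
    if (return_labels) labels_out[[k]] <- fr$labels
  }
  movie <- tono_movie(frames, pixel_size_um = optics$pixel_size_um,
                      frame_interval_s = motion$frame_interval_s,
                      bit_depth = 16L)
  truth <- list(transforms = transforms,
                boundary_disp = data.frame(frame = 0:(nf - 1),
                                           mean_disp_px = mean_disp),
                clamp_count = clamp_count,
                cells = population_table(cells))
  out <- list(movie = movie, truth = truth)
  if (return_labels) out$labels <- labels_out
  out
}

#' Does the cell diagonal cross every membrane transversally?
#'
#' The crossing-count parity argument (a closed membrane is crossed an even
#' number of times) requires transversal intersections: a transect that
#' merely grazes a membrane ring produces a single merged intensity run, and
#' one passing within a blur length of the ring is ambiguous. This
#' ground-truth helper reports whether the cell's top-left to bottom-right
#' diagonal either clearly pierces the lumen or clearly misses the outer
#' membrane edge of every compartment, with `clearance` pixels to spare
#' (covering PSF blur and profile sampling).
#'
#' @param cell a `cell_spec`.
#' @param optics an [optics_spec()] (membrane thickness is used).
#' @param clearance safety margin in pixels.
#' @return logical.
#' @export
diagonal_transversal <- function(cell, optics, clearance = 2.5) {
  r0 <- cell$rect[1:2]
  r1 <- cell$rect[1:2] + cell$rect[3:4] - 1
  v <- r1 - r0; L2 <- sum(v^2)
  t2 <- optics$membrane_thickness_px / 2
  for (j in seq_len(cell$n_compartments)) {
    cen <- cell$centers[j, ]
    s <- max(0, min(1, sum((cen - r0) * v) / L2))
    d <- sqrt(sum((r0 + s * v - cen)^2))
    inner <- cell$radii[j] * (1 - cell$amp[j]) - t2
    outer <- cell$radii[j] * (1 + cell$amp[j]) + t2
    if (d > inner - clearance && d < outer + clearance) return(FALSE)
  }
  TRUE
}

#' Ground-truth table for a synthetic population
#'
#' @param cells list of `cell_spec`.
#' @return data frame with one row per cell: identifiers, rectangle, length,
#'   compartment count, and the largest compartment's maximal extent
#'   (`2 r (1 + amp)`, px) for downstream morphology checks.
#' @export
population_table <- function(cells) {
  do.call(rbind, lapply(cells, function(c) {
    jmax <- which.max(c$radii)
    data.frame(cell_id = c$cell_id, condition_label = c$condition_label,
               preset = c$preset, x0 = c$rect[1], y0 = c$rect[2],
               width = c$rect[3], height = c$rect[4],
               length_um = c$length_um, n_compartments = c$n_compartments,
               largest_radius_px = c$radii[jmax],
               largest_extent_px = 2 * c$radii[jmax] * (1 + c$amp[jmax]))
  }))
}

#' ROI corresponding to a synthetic cell
#'
#' @param cell a `cell_spec`.
#' @param pixel_size_um pixel size for the derived length.
#' @return a [cell_roi()] covering the cell's rectangle.
#' @export
synth_roi <- function(cell, pixel_size_um = 0.11) {
  cell_roi(cell$cell_id, cell$rect[1], cell$rect[2], cell$rect[3],
           cell$rect[4], condition_label = cell$condition_label,
           pixel_size_um = pixel_size_um)
}

#' Write simulation ground truth to disk
#'
#' Writes the per-cell geometry as CSV and the per-frame rigid transforms (plus
#' boundary displacement and clamp counter) as JSON.
#'
#' @param truth the `truth` component of [simulate_timelapse()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$cells, file.path(dir, "cells_ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(transforms = truth$transforms, boundary_disp = truth$boundary_disp,
         clamp_count = truth$clamp_count),
    file.path(dir, "motion_ground_truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
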