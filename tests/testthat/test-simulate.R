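test_that("population generation is deterministic and respects presets", {
  a <- generate_cell_population(5, "fragmented", seed = 11)
  b <- generate_cell_population(5, "fragmented", seed = 11)
  expect_identical(a, b)

  cons <- generate_cell_population(8, "consolidated", seed = 2)
  expect_true(all(vapply(cons, `[[`, 0L, "n_compartments") %in% 1:2))

  frag <- generate_cell_population(20, "fragmented", seed = 7)
  tab <- population_table(frag)
  expect_true(all(tab$n_compartments >= 6))
  expect_equal(nrow(tab), 20)
})

test_that("compartments always fit inside the cell rectangle with margin", {
  for (seed in 1:6) {
    for (preset in c("consolidated", "fragmented")) {
      cells <- generate_cell_population(3, preset, seed = seed)
      for (cell in cells) {
        for (j in seq_len(cell$n_compartments)) {
          r_out <- cell$radii[j] * (1 + cell$amp[j]) + 1.5
          expect_true(all(cell$centers[j, ] - r_out - 2 >=
                            cell$rect[1:2] - 1e-9))
          expect_true(all(cell$centers[j, ] + r_out + 2 <=
                            cell$rect[1:2] + cell$rect[3:4] - 1 + 1e-9))
        }
      }
    }
  }
})

test_that("infeasible packing raises an explicit failure", {
  expect_error(
    generate_cell_population(1, "fragmented", seed = 1, cell_width_px = 24,
                             cell_height_px_range = c(48, 48)),
    "packing failure")
})

test_that("noiseless rendering puts the maximum on the membrane ridge", {
  fx <- make_cell_frame("consolidated", seed = 4)
  op <- quiet_optics()
  cell <- fx$cells[[1]]
  expect_equal(max(fx$labels), cell$n_compartments)

  # brightest pixel lies on a membrane annulus of some compartment
  idx <- arrayInd(which.max(fx$image), dim(fx$image))
  p <- c(idx[2] - 1, idx[1] - 1)
  on_membrane <- any(vapply(seq_len(cell$n_compartments), function(j) {
    rho <- sqrt(sum((p - cell$centers[j, ])^2))
    phi <- atan2(p[2] - cell$centers[j, 2], p[1] - cell$centers[j, 1])
    Rb <- cell$radii[j] *
      (1 + cell$amp[j] * cos(cell$k_harm[j] * phi + cell$phase[j]))
    abs(rho - Rb) <= op$membrane_thickness_px / 2 + 1.5
  }, logical(1)))
  expect_true(on_membrane)

  # deep-lumen pixels stay at lumen intensity despite PSF blur
  inner <- fx$image[fx$labels > 0 & !as.logical(
    EBImage::dilate(fx$labels == 0, EBImage::makeBrush(9, "disc")))]
  expect_true(all(abs(inner - op$lumen_intensity) < 1))

  # noiseless rendering is reproducible bit for bit
  again <- render_frame(fx$cells, quiet_optics(), apply_noise = FALSE)
  expect_identical(fx$image, again$image)
})

test_that("time-lapse ground truth records drift, motion and labels", {
  cells <- generate_cell_population(1, "consolidated", seed = 9)
  op <- quiet_optics()

  # static movie: all frames identical
  st <- simulate_timelapse(cells, op, motion_spec(n_frames = 4, seed = 1))
  for (k in 2:4) expect_identical(st$movie$frames[[k]], st$movie$frames[[1]])

  # cumulative drift transform at frame 4 is 4x the per-frame drift
  dr <- simulate_timelapse(cells, op,
                           motion_spec(n_frames = 5, seed = 1,
                                       drift_per_frame = c(1, 0, 0)))
  expect_equal(dr$truth$transforms$dx, 0:4)
  expect_equal(dr$truth$transforms$theta_deg, rep(0, 5))

  # higher membrane speed -> larger recorded mean boundary displacement
  lo <- simulate_timelapse(cells, op,
                           motion_spec(n_frames = 20, membrane_speed = 0.5,
                                       seed = 3))
  hi <- simulate_timelapse(cells, op,
                           motion_spec(n_frames = 20, membrane_speed = 2,
                                       seed = 3))
  expect_gt(mean(hi$truth$boundary_disp$mean_disp_px),
            mean(lo$truth$boundary_disp$mean_disp_px))

  # conservation: every frame keeps all lumen labels (no compartment loss)
  lb <- simulate_timelapse(cells, op,
                           motion_spec(n_frames = 6, membrane_speed = 3,
                                       seed = 5),
                           return_labels = TRUE)
  n_comp <- cells[[1]]$n_compartments
  for (k in 1:6) {
    expect_equal(length(setdiff(unique(as.integer(lb$labels[[k]])), 0L)),
                 n_comp)
  }

  # determinism of the full stochastic simulation
  s1 <- simulate_timelapse(cells, optics_spec(),
                           motion_spec(n_frames = 3, membrane_speed = 1,
                                       seed = 21))
  s2 <- simulate_timelapse(cells, optics_spec(),
                           motion_spec(n_frames = 3, membrane_speed = 1,
                                       seed = 21))
  expect_identical(s1$movie$frames, s2$movie$frames)
})
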