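# Independent oracles kept apart from the implementation paths ------------

# Brute-force VMI: scan every pair of pixel coordinates for the maximal
# diameter, then the perpendicular extent, without convex hulls.
brute_vmi_um2 <- function(lab, px_um) {
  idx <- which(lab == 1, arr.ind = TRUE)
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  d2 <- as.matrix(stats::dist(pts))
  ij <- arrayInd(which.max(d2), dim(d2))
  feret <- d2[ij]
  u <- (pts[ij[2], ] - pts[ij[1], ]) / feret
  proj <- pts %*% c(-u[2], u[1])
  feret * (max(proj) - min(proj)) * px_um^2
}

# Independent crossing count: explicit state-machine scan over the profile.
scan_crossings <- function(above) {
  runs <- 0L; inside <- FALSE; start_run <- above[1]
  for (v in above) {
    if (v && !inside) { inside <- TRUE; runs <- runs + 1L }
    if (!v) { inside <- FALSE; start_run <- FALSE }
  }
  if (above[1]) runs <- runs - 1L
  if (above[length(above)] && !(all(above))) runs <- runs - 1L
  if (all(above)) runs <- 0L
  max(runs, 0L)
}

test_that("lumen segmentation recovers compartments and flags degeneracy", {
  # single compartment, noise off: K = 1, area within 5% of ground truth
  cells <- list(manual_cell(c(0, 0, 72, 72), matrix(c(35, 35), 1), 25))
  fx <- render_frame(cells, quiet_optics(psf_sigma_px = 0.8),
                     apply_noise = FALSE)
  mask <- segment_lumen(fx$image, pixel_size_um = 0.11)
  expect_equal(mask$K, 1L)
  expect_lt(abs(sum(mask$labels == 1) / sum(fx$labels == 1) - 1), 0.05)

  # constant ROI: empty mask with warning flag
  expect_warning(m0 <- segment_lumen(matrix(5, 30, 30)), "degenerate")
  expect_equal(m0$K, 0L)
  expect_true(m0$degenerate)

  # fragmented preset cell: every ground-truth compartment recovered
  for (seed in c(2, 6)) {
    fy <- make_cell_frame("fragmented", seed = seed)
    mk <- segment_lumen(fy$image, fy$roi)
    expect_equal(mk$K, fy$cells[[1]]$n_compartments)
  }
})

test_that("VMI matches analytic and brute-force oracles", {
  # rasterized disc r = 20 px at 0.1 um/px: vmi = (2r)^2 px^2 = 16 um^2
  lab <- disc_labels(c(64, 64), c(31.5, 31.5), 20)
  v <- compute_vmi(lab, pixel_size_um = 0.1)
  expect_lt(abs(v$vmi_um2 / 16 - 1), 0.05)

  # thin rectangle: rotating-calipers result equals the brute-force scan
  lab2 <- matrix(0L, 40, 120)
  lab2[16:25, 11:110] <- 1L  # 100 x 10 px block
  v2 <- compute_vmi(lab2, pixel_size_um = 0.1)
  expect_lt(abs(v2$vmi_um2 / brute_vmi_um2(lab2, 0.1) - 1), 0.05)

  # max-area selection: small second compartment is ignored
  lab3 <- disc_labels(c(64, 64), c(20, 20), 11)
  lab3[disc_labels(c(64, 64), c(50, 50), 2.5) == 1] <- 2L
  v3 <- compute_vmi(lab3, pixel_size_um = 0.1)
  expect_equal(v3$vmi_um2,
               compute_vmi(disc_labels(c(64, 64), c(20, 20), 11),
                           pixel_size_um = 0.1)$vmi_um2)

  # monotone under scaling: doubling the disc multiplies vmi by ~4
  small <- compute_vmi(disc_labels(c(96, 96), c(47.5, 47.5), 12),
                       pixel_size_um = 0.1)
  big <- compute_vmi(disc_labels(c(96, 96), c(47.5, 47.5), 24),
                     pixel_size_um = 0.1)
  expect_lt(abs(big$vmi_um2 / (4 * small$vmi_um2) - 1), 0.05)

  # ln transform strictly monotone
  expect_identical(order(c(small$vmi_um2, big$vmi_um2)),
                   order(c(small$ln_vmi, big$ln_vmi)))

  expect_error(compute_vmi(matrix(0L, 10, 10)), "no compartments")
})

test_that("TTI counts diagonal membrane crossings", {
  op <- quiet_optics(psf_sigma_px = 0.8)

  # one centered compartment: entry + exit = 2 crossings
  one <- list(manual_cell(c(0, 0, 80, 80), matrix(c(39.5, 39.5), 1), 22))
  f1 <- render_frame(one, op, apply_noise = FALSE)$image
  t1 <- compute_tti(f1, pixel_size_um = 0.11)
  expect_equal(t1$crossings, 2L)
  expect_equal(t1$tti_per_um, 2 / (sqrt(79^2 + 79^2) * 0.11))

  # uniform dark ROI: 0 crossings, tti 0, flagged degenerate
  t0 <- compute_tti(matrix(3, 40, 40), pixel_size_um = 0.11)
  expect_equal(t0$crossings, 0L)
  expect_equal(t0$tti_per_um, 0)
  expect_true(t0$degenerate)

  # 4 disjoint compartments centered on the diagonal: 8 crossings
  d <- 200
  cen <- cbind(seq(25, 175, length.out = 4), seq(25, 175, length.out = 4))
  four <- list(manual_cell(c(0, 0, d, d), cen, rep(14, 4)))
  f4 <- render_frame(four, op, apply_noise = FALSE)$image
  t4 <- compute_tti(f4, pixel_size_um = 0.11)
  expect_equal(t4$crossings, 8L)
})

test_that("TTI equals the independent run-scan oracle with even parity", {
  op <- optics_spec()
  quiet <- quiet_optics()
  n_transversal <- 0
  for (seed in 1:25) {
    preset <- if (seed %% 2) "consolidated" else "fragmented"
    # oracle equivalence holds for noisy renders too
    fx <- make_cell_frame(preset, seed = seed, optics = op)
    f <- fx$image
    h <- nrow(f); w <- ncol(f)
    n <- ceiling(sqrt((w - 1)^2 + (h - 1)^2) / 0.5) + 1
    tt <- seq(0, 1, length.out = n)
    prof <- tonodyn:::bilinear_sample(f, tt * (w - 1), tt * (h - 1))
    thr <- tonodyn:::otsu_threshold(prof)
    res <- compute_tti(f, pixel_size_um = 0.11)
    if (res$degenerate) {
      expect_equal(res$crossings, 0L)  # contrast-free profile, no threshold
    } else {
      expect_equal(res$crossings, scan_crossings(prof >= thr))
    }

    # parity: even crossings whenever the diagonal is transversal to every
    # membrane (a closed curve is pierced an even number of times)
    fq <- render_frame(fx$cells, quiet, apply_noise = FALSE)$image
    if (diagonal_transversal(fx$cells[[1]], quiet)) {
      n_transversal <- n_transversal + 1
      resq <- compute_tti(fq, pixel_size_um = 0.11)
      expect_equal(resq$crossings %% 2, 0)
    }
  }
  expect_gt(n_transversal, 5)  # the parity branch is actually exercised
})

test_that("TTI per um is stable under 2x resolution re-rendering", {
  base <- quiet_optics(psf_sigma_px = 0.8)
  fine <- quiet_optics(psf_sigma_px = 1.6, pixel_size_um = 0.055,
                       membrane_thickness_px = 6)
  for (seed in c(3, 9, 14)) {
    cells <- generate_cell_population(1, "fragmented", seed = seed)
    c1 <- cells[[1]]
    c2 <- manual_cell(c1$rect * 2, c1$centers * 2, c1$radii * 2)
    c2$amp <- c1$amp; c2$k_harm <- c1$k_harm; c2$phase <- c1$phase
    c2$n_compartments <- c1$n_compartments
    f1 <- render_frame(list(c1), base, apply_noise = FALSE)$image
    f2 <- render_frame(list(c2), fine, apply_noise = FALSE)$image
    t1 <- compute_tti(f1, pixel_size_um = 0.11)
    t2 <- compute_tti(f2, pixel_size_um = 0.055)
    expect_lt(abs(t2$tti_per_um / t1$tti_per_um - 1), 0.10)
  }
})

test_that("morphology_table collects per-cell records and failure codes", {
  fx1 <- make_cell_frame("consolidated", seed = 21)
  fx2 <- make_cell_frame("fragmented", seed = 22)
  tab <- morphology_table(list(fx1$image, fx2$image),
                          list(fx1$roi, fx2$roi))
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$vmi_um2)))
  expect_true(all(tab$tti_per_um > 0))
  expect_gt(tab$vmi_um2[1], tab$vmi_um2[2])  # consolidated bigger compartment

  # blank cell: record kept, metrics missing, failure flagged
  blank_roi <- cell_roi("blank", 0, 0, 40, 40, "none")
  tab2 <- morphology_table(matrix(5, 40, 40), list(blank_roi))
  expect_equal(nrow(tab2), 1)
  expect_true(is.na(tab2$vmi_um2))
  expect_match(tab2$flags, "no_compartment|degenerate")

  # diagonal averaging: "both" equals the mean of the two single diagonals
  f <- fx2$image
  both <- compute_tti(f, pixel_size_um = 0.11, diagonal = "both")
  tlbr <- compute_tti(f, pixel_size_um = 0.11)
  flip <- compute_tti(f[, ncol(f):1], pixel_size_um = 0.11)
  expect_equal(both$crossings, (tlbr$crossings + flip$crossings) / 2)
})
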