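# Preprocessing chain applied before any measurement, mirroring the standard
# confocal workflow: contrast enhancement with percentile saturation, 8-bit
# conversion, rigid-body drift registration against the first frame, rotation
# to orient the root vertically, and per-cell ROI cropping.

#' Percentile contrast enhancement with 8-bit conversion
#'
#' Per frame, clips the lowest and highest `saturated_fraction / 2` of pixel
#' values and rescales linearly to 0..255 (rounded). This reproduces the
#' common "enhance contrast with N% saturated pixels" operation; the default
#' saturates 0.35% of pixels in total. A constant frame maps to all zeros
#' rather than erroring, so blank ROIs degrade gracefully.
#'
#' @param movie a [tono_movie()] (or a single matrix).
#' @param saturated_fraction total fraction of pixels saturated, in
#'   `[0, 0.5)`.
#' @return an 8-bit [tono_movie()] (or matrix when a matrix was given).
#' @export
enhance_contrast <- function(movie, saturated_fraction = 0.0035) {
  stopifnot(saturated_fraction >= 0, saturated_fraction < 0.5)
  if (is.matrix(movie)) return(enhance_frame(movie, saturated_fraction))
  out <- lapply(movie$frames, enhance_frame, sf = saturated_fraction)
  tono_movie(out, pixel_size_um = movie$pixel_size_um,
             frame_interval_s = movie$frame_interval_s, bit_depth = 8L)
}

enhance_frame <- function(f, sf) {
  qs <- stats::quantile(f, c(sf / 2, 1 - sf / 2), names = FALSE)
  if (qs[2] <= qs[1]) return(matrix(0, nrow(f), ncol(f)))
  v <- (f - qs[1]) / (qs[2] - qs[1])
  matrix(round(pmin(pmax(v, 0), 1) * 255), nrow(f), ncol(f))
}

#' Estimate the rigid transform between two frames
#'
#' Returns the scene displacement `D = (dx, dy, theta_deg)` of `target`
#' relative to `reference`: features of the reference appear in the target at
#' `D(p) = R(theta)(p - c) + c + (dx, dy)` with `c` the image center.
#' Registration undoes `D` by resampling the target at `D(q)`.
#'
#' The estimator maximizes the valid-pixel Pearson correlation between the
#' reference and the back-warped target over a 3-level image pyramid: a
#' coarse rotation grid combined with FFT cross-correlation for translation
#' provides the initialization, followed by Nelder-Mead subpixel refinement
#' at the two finer levels. On noiseless synthetic warps with shifts up to
#' 10 px and rotations up to 10 degrees the recovery error stays below
#' 0.5 px / 0.5 degrees (asserted by the test suite).
#'
#' @param reference,target numeric matrices of equal shape, non-constant.
#' @param init optional length-3 starting transform (skips the global coarse
#'   search; used for warm-starting along a stack).
#' @param theta_range half-width of the coarse rotation search, degrees.
#' @return list with `dx`, `dy`, `theta_deg` and the achieved correlation
#'   `similarity`.
#' @export
estimate_rigid_transform <- function(reference, target, init = NULL,
                                     theta_range = 12) {
  stopifnot(identical(dim(reference), dim(target)))
  if (stats::sd(reference) == 0 || stats::sd(target) == 0)
    stop("no signal: constant frame cannot be registered")
  ref1 <- downsample2(reference); tgt1 <- downsample2(target)
  ref2 <- downsample2(ref1);      tgt2 <- downsample2(tgt1)

  score <- function(ref, tgt, par) {
    reg <- warp_sample_forward(tgt, par[1], par[2], par[3], pad = NA_real_)
    s <- masked_pearson(ref, reg)
    if (is.na(s)) -1 else s
  }
  refine <- function(ref, tgt, par, scale_px) {
    opt <- stats::optim(par, function(p) -score(ref, tgt, p),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 400,
                                       parscale = c(scale_px, scale_px, 1)))
    opt$par
  }

  if (is.null(init)) {
    thetas <- seq(-theta_range, theta_range, by = 2)
    cand <- lapply(thetas, function(th) {
      # de-rotate target; the residual is a pure shift e with d = R(th) e
      tgt_rot <- warp_sample_forward(tgt2, 0, 0, th, pad = mean(tgt2))
      sh <- xcorr_shift(ref2, tgt_rot, max_shift = ceiling(10 / 4) + 3)
      e <- c(sh[["dx"]], sh[["dy"]])
      thr <- th * pi / 180
      d <- c(cos(thr) * e[1] - sin(thr) * e[2],
             sin(thr) * e[1] + cos(thr) * e[2])
      par <- c(d, th)
      list(par = par, s = score(ref2, tgt2, par))
    })
    scores <- vapply(cand, `[[`, numeric(1), "s")
    # refine the two best coarse candidates, keep the winner
    top <- order(scores, decreasing = TRUE)[1:2]
    ref2_fits <- lapply(top, function(i)
      refine(ref2, tgt2, cand[[i]]$par, scale_px = 1))
    fit_scores <- vapply(ref2_fits, function(p) score(ref2, tgt2, p),
                         numeric(1))
    par2 <- ref2_fits[[which.max(fit_scores)]]
    par1 <- refine(ref1, tgt1, c(par2[1:2] * 2, par2[3]), scale_px = 0.5)
  } else {
    par1 <- refine(ref1, tgt1, c(init[1:2] / 2, init[3]), scale_px = 0.5)
  }
  par0 <- refine(reference, target, c(par1[1:2] * 2, par1[3]), scale_px = 0.25)
  list(dx = par0[1], dy = par0[2], theta_deg = par0[3],
       similarity = score(reference, target, par0))
}

#' Register a stack to its first frame (rigid body)
#'
#' Estimates the rigid drift of every frame relative to frame 1 and resamples
#' each frame into the first frame's coordinates. Frame 1 is returned
#' untouched. Estimation is warm-started from the previous frame's transform,
#' which makes slow cumulative growth drift cheap to track.
#'
#' @param movie a [tono_movie()] with at least 2 frames.
#' @param theta_range coarse rotation search half-width for frame 2 (later
#'   frames are warm-started).
#' @param pad fill value for pixels leaving the field of view; default is the
#'   frame's median intensity.
#' @return list with `movie` (registered) and `transforms`, a data frame of
#'   per-frame `frame` (0-based), `dx`, `dy`, `theta_deg`.
#' @export
register_stack <- function(movie, theta_range = 12, pad = NULL) {
  nf <- n_frames(movie)
  if (nf < 2) stop("register_stack needs at least 2 frames")
  ref <- movie$frames[[1]]
  out <- movie$frames
  tr <- data.frame(frame = 0:(nf - 1), dx = 0, dy = 0, theta_deg = 0)
  prev <- NULL
  for (k in 2:nf) {
    est <- tryCatch(
      estimate_rigid_transform(ref, movie$frames[[k]], init = prev,
                               theta_range = theta_range),
      error = function(e) stop(sprintf("registration failed at frame %d: %s",
                                       k - 1, conditionMessage(e))))
    prev <- c(est$dx, est$dy, est$theta_deg)
    tr$dx[k] <- est$dx; tr$dy[k] <- est$dy; tr$theta_deg[k] <- est$theta_deg
    fill <- if (is.null(pad)) stats::median(movie$frames[[k]]) else pad
    out[[k]] <- warp_sample_forward(movie$frames[[k]], est$dx, est$dy,
                                    est$theta_deg, pad = fill)
  }
  list(movie = tono_movie(out, pixel_size_um = movie$pixel_size_um,
                          frame_interval_s = movie$frame_interval_s,
                          bit_depth = movie$bit_depth),
       transforms = tr)
}

#' Rotate a movie about the image center
#'
#' Rotates every frame by a user-supplied angle (the root orientation step is
#' manual: no auto-detection). Padding is a constant value; 0 degrees is the
#' identity.
#'
#' @param movie a [tono_movie()].
#' @param angle_deg rotation in degrees (counter-clockwise in image
#'   convention with y pointing down).
#' @param pad fill value outside the original support.
#' @return the rotated [tono_movie()].
#' @export
rotate_to_vertical <- function(movie, angle_deg, pad = 0) {
  if (angle_deg == 0) return(movie)
  out <- lapply(movie$frames, function(f)
    warp_rigid(f, 0, 0, angle_deg, pad = pad))
  tono_movie(out, pixel_size_um = movie$pixel_size_um,
             frame_interval_s = movie$frame_interval_s,
             bit_depth = movie$bit_depth)
}

#' Crop a movie to a cell ROI
#'
#' Extracts the exact half-open rectangle of the ROI from every frame. A
#' rectangle reaching outside the frame raises an error; nothing is silently
#' clipped.
#'
#' @param movie a [tono_movie()].
#' @param roi a [cell_roi()].
#' @return a [tono_movie()] of shape `height x width`, metadata preserved.
#' @export
crop_roi <- function(movie, roi) {
  d <- dim(movie$frames[[1]])
  if (roi$x0 < 0 || roi$y0 < 0 || roi$x0 + roi$width > d[2] ||
      roi$y0 + roi$height > d[1]) {
    stop(sprintf("ROI %s (%d,%d,%dx%d) exceeds frame bounds %dx%d",
                 roi$cell_id, roi$x0, roi$y0, roi$width, roi$height,
                 d[2], d[1]))
  }
  rows <- (roi$y0 + 1):(roi$y0 + roi$height)
  cols <- (roi$x0 + 1):(roi$x0 + roi$width)
  out <- lapply(movie$frames, function(f) f[rows, cols, drop = FALSE])
  tono_movie(out, pixel_size_um = movie$pixel_size_um,
             frame_interval_s = movie$frame_interval_s,
             bit_depth = movie$bit_depth)
}
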