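# Internal image primitives shared across modules.
#
# Image convention: plain numeric matrix, rows = y (downward), cols = x.
# Pixel coordinates are 0-based: pixel (x, y) lives at matrix[y + 1, x + 1].

#' Otsu threshold of a numeric vector or matrix
#'
#' Computes the between-class-variance-maximizing threshold of the intensity
#' values. Works on any shape (image ROI or 1-D transect profile) by rescaling
#' to \[0, 1\] and delegating to [EBImage::otsu()].
#'
#' @param x numeric vector or matrix of intensities.
#' @param levels number of histogram levels.
#' @return threshold on the original intensity scale, or `NA_real_` when the
#'   input is constant (degenerate: no two classes exist).
#' @keywords internal
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(NA_real_)
  u <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1L)),
                       range = c(0, 1), levels = levels)
  rng[1] + as.numeric(thr) * diff(rng)
}

#' Bilinear sampling of an image at arbitrary (x, y) positions
#'
#' @param img numeric matrix (rows = y).
#' @param x,y 0-based sample coordinates (vectors of equal length).
#' @param pad value returned for samples outside the image support.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y, pad = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  eps <- 1e-7  # snap coordinates at the support boundary (fp round-off)
  x <- ifelse(x > -eps & x < 0, 0, ifelse(x > w - 1 & x < w - 1 + eps, w - 1, x))
  y <- ifelse(y > -eps & y < 0, 0, ifelse(y > h - 1 & y < h - 1 + eps, h - 1, y))
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  out <- rep(pad, length(x))
  ok <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1 &
        x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  x1k <- pmin(x0k + 1, w - 1); y1k <- pmin(y0k + 1, h - 1)
  x0k <- pmax(x0k, 0); y0k <- pmax(y0k, 0)
  i00 <- img[cbind(y0k + 1, x0k + 1)]
  i01 <- img[cbind(y0k + 1, x1k + 1)]
  i10 <- img[cbind(y1k + 1, x0k + 1)]
  i11 <- img[cbind(y1k + 1, x1k + 1)]
  out[ok] <- (1 - fyk) * ((1 - fxk) * i00 + fxk * i01) +
             fyk       * ((1 - fxk) * i10 + fxk * i11)
  out
}

# Rigid transform helper: T(p) = R_theta (p - c) + c + (dx, dy), angles in
# degrees, positive = counter-clockwise in (x, y-down) image convention.
rigid_apply_points <- function(x, y, dx, dy, theta_deg, center) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  xr <- x - center[1]; yr <- y - center[2]
  list(x = ct * xr - st * yr + center[1] + dx,
       y = st * xr + ct * yr + center[2] + dy)
}

#' Apply a rigid transform to image content
#'
#' Moves the image content by the transform `T(p) = R(theta)(p - c) + c + d`:
#' output pixel `q` takes the value of the input at `T^{-1}(q)`, so a feature
#' at position `p` appears at `T(p)` in the output.
#'
#' @param img numeric matrix.
#' @param dx,dy translation in pixels.
#' @param theta_deg rotation in degrees about `center`.
#' @param center rotation center, 0-based `(x, y)`; default image center.
#' @param pad fill value outside the input support.
#' @return numeric matrix of the same shape.
#' @keywords internal
warp_rigid <- function(img, dx = 0, dy = 0, theta_deg = 0, center = NULL,
                       pad = 0) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  # inverse transform: rotate by -theta about c, then undo translation
  inv <- rigid_apply_points(gx - dx, gy - dy, 0, 0, -theta_deg, center)
  vals <- bilinear_sample(img, inv$x, inv$y, pad = pad)
  matrix(vals, nrow = h, ncol = w)
}

# Resample image at positions T(q) for the rigid transform T; used to undo a
# scene displacement D: registered(q) = target(D(q)).
warp_sample_forward <- function(img, dx, dy, theta_deg, center = NULL,
                                pad = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  fwd <- rigid_apply_points(gx, gy, dx, dy, theta_deg, center)
  matrix(bilinear_sample(img, fwd$x, fwd$y, pad = pad), nrow = h, ncol = w)
}

# 2x2 block-mean downsampling (odd trailing row/col dropped).
downsample2 <- function(img) {
  h <- 2L * (nrow(img) %/% 2L); w <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (img[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
          img[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
          img[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
          img[seq(2, h, 2), seq(2, w, 2), drop = FALSE])
}

# Integer-shift estimate by FFT cross-correlation of mean-removed images.
# Returns c(dx, dy): b's scene displacement relative to a's (b = a's content
# moved by +(dx, dy)). Sign convention is pinned down by tests.
xcorr_shift <- function(a, b, max_shift = Inf) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)), inverse = TRUE))
  h <- nrow(a); w <- ncol(a)
  sy <- c(0:(h - 1)); sy[sy > h / 2] <- sy[sy > h / 2] - h
  sx <- c(0:(w - 1)); sx[sx > w / 2] <- sx[sx > w / 2] - w
  ok <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift)
  cc[!ok] <- -Inf
  idx <- arrayInd(which.max(cc), dim(cc))
  c(dx = -sx[idx[2]], dy = -sy[idx[1]])
}

# Pearson correlation between img a and b over finite pixels of both;
# returns NA if fewer than min_frac of pixels are valid or variance vanishes.
masked_pearson <- function(a, b, min_frac = 0.5) {
  ok <- is.finite(a) & is.finite(b)
  n <- sum(ok)
  if (n < min_frac * length(a) || n < 8) return(NA_real_)
  av <- a[ok]; bv <- b[ok]
  sa <- stats::sd(av); sb <- stats::sd(bv)
  if (sa == 0 || sb == 0) return(NA_real_)
  stats::cor(av, bv)
}
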