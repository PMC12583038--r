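# Tonoplast motility as frame-to-first-frame pixel-intensity correlation.
#
# For each cell (cropped, registered, contrast-enhanced movie), the first
# frame is the fixed source and every frame is correlated against it; the
# resulting R(t) curve decays faster the more the membrane moves. The
# single-number endpoint r_end is R at the frame nearest the 120-s horizon.

#' Pearson correlation between two frames
#'
#' With `window = "full"`, computes the Pearson correlation coefficient of
#' the two flattened pixel-intensity vectors (explicit sum formula). With an
#' integer window `w`, tiles the common shape into non-overlapping `w x w`
#' blocks (partial edge blocks discarded), computes Pearson per block, and
#' returns the unweighted mean over blocks where both images have nonzero
#' variance (spatially resolved variant of the same statistic).
#'
#' @param frame_a,frame_b numeric matrices of identical shape.
#' @param window `"full"` or a positive integer block size not exceeding the
#'   smaller image dimension.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
frame_correlation <- function(frame_a, frame_b, window = "full") {
  stopifnot(identical(dim(frame_a), dim(frame_b)))
  if (identical(window, "full")) {
    r <- pearson_sum(as.numeric(frame_a), as.numeric(frame_b))
    if (is.na(r)) stop("undefined correlation: zero variance frame")
    return(r)
  }
  w <- as.integer(window)
  stopifnot(w >= 2, w <= min(dim(frame_a)))
  nby <- nrow(frame_a) %/% w; nbx <- ncol(frame_a) %/% w
  rs <- c()
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      rows <- ((by - 1) * w + 1):(by * w)
      cols <- ((bx - 1) * w + 1):(bx * w)
      r <- pearson_sum(as.numeric(frame_a[rows, cols]),
                       as.numeric(frame_b[rows, cols]))
      if (!is.na(r)) rs <- c(rs, r)
    }
  }
  if (length(rs) == 0) stop("undefined correlation: zero variance in all blocks")
  mean(rs)
}

# Explicit Pearson sum formula; NA when either variance is zero.
pearson_sum <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  vx <- sum(x * x) - sx * sx / n
  vy <- sum(y * y) - sy * sy / n
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cxy <- sum(x * y) - sx * sy / n
  min(1, max(-1, cxy / sqrt(vx * vy)))
}

#' Frame-to-first-frame correlation curve of a cell movie
#'
#' @param movie a preprocessed (cropped, registered, enhanced) per-cell
#'   [tono_movie()].
#' @param window passed to [frame_correlation()].
#' @param horizon_s endpoint horizon in seconds; `r_end` is R at the frame
#'   nearest this time. When the movie ends more than half a frame interval
#'   before the horizon, `r_end` is flagged truncated.
#' @param cell_id,condition_label metadata carried into the curve.
#' @param length_um cell length (defaults to ROI height times pixel size).
#' @return object of class `motility_curve`: list with `times_s`, `r_values`,
#'   `r_end`, `r_end_time_s`, `truncated`, and the metadata fields.
#' @export
motility_curve <- function(movie, window = "full", horizon_s = 120,
                           cell_id = "cell", condition_label = "unlabeled",
                           length_um = NULL) {
  nf <- n_frames(movie)
  times <- frame_times(movie)
  f0 <- movie$frames[[1]]
  r <- vapply(seq_len(nf), function(k)
    frame_correlation(f0, movie$frames[[k]], window = window), numeric(1))
  k_end <- which.min(abs(times - horizon_s))
  truncated <- max(times) < horizon_s - movie$frame_interval_s / 2
  if (is.null(length_um))
    length_um <- nrow(f0) * movie$pixel_size_um
  structure(list(cell_id = cell_id, condition_label = condition_label,
                 length_um = length_um, times_s = times, r_values = r,
                 r_end = r[k_end], r_end_time_s = times[k_end],
                 truncated = truncated),
            class = "motility_curve")
}

#' Group-averaged correlation curves with SEM
#'
#' @param curves list of `motility_curve` sharing one time grid.
#' @param group_by field used for grouping (default `condition_label`).
#' @return data frame with columns group, t_s, mean_r, sem, n. SEM is the
#'   sample standard deviation divided by `sqrt(n)`; `NA` for n = 1.
#' @export
average_curves <- function(curves, group_by = "condition_label") {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$times_s
  same <- vapply(curves, function(c) isTRUE(all.equal(c$times_s, grid)),
                 logical(1))
  if (!all(same)) stop("curves do not share one time grid")
  groups <- vapply(curves, function(c) as.character(c[[group_by]]),
                   character(1))
  out <- lapply(unique(groups), function(g) {
    rs <- do.call(rbind, lapply(curves[groups == g],
                                function(c) c$r_values))
    n <- nrow(rs)
    data.frame(group = g, t_s = grid, mean_r = colMeans(rs),
               sem = if (n > 1) apply(rs, 2, stats::sd) / sqrt(n)
                     else NA_real_,
               n = n)
  })
  do.call(rbind, out)
}

#' Kymograph along a line segment
#'
#' Builds the position-by-time image whose row `t` is the interpolated
#' intensity profile along the segment in frame `t`. Sample positions are
#' `0, step_px, 2 step_px, ...` covering `[0, L)`, so the width is
#' `ceiling(L / step_px)`.
#'
#' @param movie a [tono_movie()].
#' @param p0,p1 segment endpoints, 0-based `(x, y)` pixels, inside the frame.
#' @param step_px sampling step along the segment.
#' @return numeric matrix of shape `n_frames x ceiling(L / step_px)`.
#' @export
kymograph <- function(movie, p0, p1, step_px = 0.5) {
  d <- dim(movie$frames[[1]])
  pts <- rbind(p0, p1)
  if (any(pts[, 1] < 0 | pts[, 1] > d[2] - 1 |
          pts[, 2] < 0 | pts[, 2] > d[1] - 1))
    stop("kymograph segment outside frame bounds")
  L <- sqrt(sum((p1 - p0)^2))
  n <- ceiling(L / step_px)
  s <- (seq_len(n) - 1) * step_px / L
  xs <- p0[1] + s * (p1[1] - p0[1])
  ys <- p0[2] + s * (p1[2] - p0[2])
  t(vapply(movie$frames, function(f) bilinear_sample(f, xs, ys),
           numeric(n)))
}

#' Long-format table of motility curves
#'
#' @param curves list of `motility_curve`.
#' @return data frame with columns cell_id, condition_label, length_um, t_s,
#'   r.
#' @export
curves_table <- function(curves) {
  do.call(rbind, lapply(curves, function(c) {
    data.frame(cell_id = c$cell_id, condition_label = c$condition_label,
               length_um = c$length_um, t_s = c$times_s, r = c$r_values)
  }))
}

#' Endpoint table of motility curves
#'
#' One row per cell with the 120-s-horizon endpoint, the quantity compared
#' between genotypes/treatments.
#'
#' @param curves list of `motility_curve`.
#' @return data frame with cell_id, condition_label, length_um, r_end,
#'   r_end_time_s, truncated.
#' @export
r_end_table <- function(curves) {
  do.call(rbind, lapply(curves, function(c) {
    data.frame(cell_id = c$cell_id, condition_label = c$condition_label,
               length_um = c$length_um, r_end = c$r_end,
               r_end_time_s = c$r_end_time_s, truncated = c$truncated)
  }))
}
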