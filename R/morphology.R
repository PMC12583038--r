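# Vacuole morphology metrics from a single frame + cell ROI.
#
# Two complementary indices of central-vacuole organization:
#  * VMI (vacuolar morphology index): size of the largest vacuolar
#    compartment in the optical section, operationalized as maximal Feret
#    diameter times the maximal extent perpendicular to it (um^2), natural-log
#    transformed for statistics. Higher VMI = more consolidated vacuole.
#  * TTI (tonoplast topology index): number of tonoplast membrane crossings
#    per micrometer along a diagonal cell transect. Higher TTI = more
#    convoluted / fragmented vacuome.

#' Segment vacuole-lumen compartments within a cell ROI
#'
#' The membrane signal is thresholded (Otsu over the ROI), closed
#' morphologically to seal small gaps, and the complement is labeled
#' (4-connectivity). The component touching all four ROI edges is the
#' extracellular background and is removed; components touching some edge are
#' kept but flagged as border-touching (central vacuoles abut the cell edge
#' in elongated cells). Components smaller than `min_area_px` are dropped as
#' noise specks. Labels are renumbered 1..K by decreasing area.
#'
#' @param frame numeric matrix (8-bit enhanced or raw float).
#' @param roi optional [cell_roi()]; when given the frame is cropped first.
#' @param min_area_px minimum compartment area in pixels.
#' @param close_radius radius of the disc used to close the membrane mask.
#' @param pixel_size_um pixel size attached to the mask.
#' @return object of class `lumen_mask`: list with `labels` (integer matrix,
#'   0 = non-lumen), `K` (number of compartments), `border_labels` (labels
#'   touching an ROI edge), `degenerate` (TRUE when the ROI was constant and
#'   no threshold exists) and `pixel_size_um`.
#' @export
segment_lumen <- function(frame, roi = NULL, min_area_px = 9,
                          close_radius = 2, pixel_size_um = 0.11) {
  if (!is.null(roi)) {
    frame <- crop_roi(tono_movie(frame, pixel_size_um = pixel_size_um),
                      roi)$frames[[1]]
  }
  empty <- function(degenerate) {
    structure(list(labels = matrix(0L, nrow(frame), ncol(frame)), K = 0L,
                   border_labels = integer(0), degenerate = degenerate,
                   pixel_size_um = pixel_size_um), class = "lumen_mask")
  }
  thr <- otsu_threshold(frame)
  if (is.na(thr)) {
    m <- empty(TRUE)
    warning("degenerate membrane threshold: constant ROI, empty mask")
    return(m)
  }
  membrane <- frame >= thr
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    membrane <- EBImage::closing(membrane, brush) > 0
  }
  lab <- EBImage::bwlabel(!membrane)  # 4-connected complement components
  lab <- matrix(as.integer(lab), nrow(frame))
  if (max(lab) == 0L) return(empty(FALSE))
  h <- nrow(lab); w <- ncol(lab)
  edge <- list(top = lab[1, ], bottom = lab[h, ], left = lab[, 1],
               right = lab[, w])
  touches <- vapply(seq_len(max(lab)), function(l) {
    vapply(edge, function(e) any(e == l), logical(1))
  }, logical(4))
  exterior <- which(colSums(touches) == 4L)
  border <- which(colSums(touches) > 0L & colSums(touches) < 4L)
  areas <- tabulate(lab, nbins = max(lab))
  keep <- setdiff(which(areas >= min_area_px), exterior)
  if (length(keep) == 0) return(empty(FALSE))
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, h, w)
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  structure(list(labels = out, K = length(keep),
                 border_labels = which(keep %in% border),
                 degenerate = FALSE, pixel_size_um = pixel_size_um),
            class = "lumen_mask")
}

#' Vacuolar morphology index of the largest compartment
#'
#' Selects the compartment of maximal area and returns
#' `vmi_um2 = Feret_max x extent_perpendicular` (both in micrometers, from
#' the convex hull of the compartment's pixel centers) together with its
#' natural logarithm. The alternative strategy `"area"` uses the
#' compartment's pixel area in um^2 instead.
#'
#' @param mask a `lumen_mask` from [segment_lumen()], or an integer label
#'   matrix (pixel size then taken from `pixel_size_um`).
#' @param strategy `"feret"` (default) or `"area"`.
#' @param pixel_size_um used when `mask` is a bare matrix.
#' @return list with `vmi_um2` and `ln_vmi`.
#' @export
compute_vmi <- function(mask, strategy = c("feret", "area"),
                        pixel_size_um = 0.11) {
  strategy <- match.arg(strategy)
  if (inherits(mask, "lumen_mask")) {
    lab <- mask$labels; px <- mask$pixel_size_um
  } else { lab <- mask; px <- pixel_size_um }
  if (max(lab) == 0L) stop("no compartments: VMI undefined for K = 0")
  areas <- tabulate(lab, nbins = max(lab))
  biggest <- which.max(areas)
  idx <- which(lab == biggest, arr.ind = TRUE)
  if (strategy == "area") {
    vmi <- areas[biggest] * px^2
    return(list(vmi_um2 = vmi, ln_vmi = log(vmi)))
  }
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  # maximal Feret diameter over hull vertices
  dmat <- as.matrix(stats::dist(hull))
  ij <- arrayInd(which.max(dmat), dim(dmat))
  feret_px <- dmat[ij]
  u <- hull[ij[2], ] - hull[ij[1], ]
  u <- u / sqrt(sum(u^2))
  perp <- c(-u[2], u[1])
  proj <- hull %*% perp
  perp_px <- max(proj) - min(proj)
  vmi <- (feret_px * px) * (perp_px * px)
  list(vmi_um2 = vmi, ln_vmi = log(vmi))
}

#' Tonoplast topology index along a diagonal transect
#'
#' Samples the intensity profile along the cell diagonal from the top-left
#' to the bottom-right ROI corner (pixel centers, steps of at most
#' `step_px`), binarizes it at a membrane threshold (Otsu over the profile by
#' default), and counts maximal above-threshold runs. Runs containing either
#' transect endpoint are excluded: those are plasma-membrane contacts, not
#' tonoplast. `diagonal = "both"` averages the two diagonals.
#'
#' @param frame numeric matrix.
#' @param roi optional [cell_roi()] to crop first.
#' @param pixel_size_um micrometers per pixel.
#' @param step_px transect sampling step (<= 0.5 px recommended).
#' @param diagonal `"tl-br"` (default) or `"both"`.
#' @param threshold membrane threshold; default Otsu on the profile.
#' @param min_contrast minimum relative contrast `(max - min) / max` of the
#'   profile for a membrane threshold to be meaningful; profiles below it
#'   (e.g. a transect that misses every membrane and sees only blur ripple
#'   on the background) are flagged degenerate with 0 crossings.
#' @return list with `crossings` (may be half-integer for `"both"`),
#'   `transect_length_um`, `tti_per_um`, and `degenerate` flag (constant or
#'   contrast-free profile, crossings reported as 0).
#' @export
compute_tti <- function(frame, roi = NULL, pixel_size_um = 0.11,
                        step_px = 0.5, diagonal = c("tl-br", "both"),
                        threshold = NULL, min_contrast = 0.05) {
  diagonal <- match.arg(diagonal)
  if (!is.null(roi)) {
    frame <- crop_roi(tono_movie(frame, pixel_size_um = pixel_size_um),
                      roi)$frames[[1]]
  }
  h <- nrow(frame); w <- ncol(frame)
  one <- function(p0, p1) {
    L <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, ceiling(L / step_px) + 1L)
    tt <- seq(0, 1, length.out = n)
    prof <- bilinear_sample(frame, p0[1] + tt * (p1[1] - p0[1]),
                            p0[2] + tt * (p1[2] - p0[2]))
    rng <- range(prof)
    flat <- diff(rng) <= min_contrast * max(abs(rng), .Machine$double.eps)
    thr <- if (is.null(threshold)) otsu_threshold(prof) else threshold
    if (is.na(thr) || (is.null(threshold) && flat)) {
      return(list(crossings = 0L, length_px = L, degenerate = TRUE))
    }
    list(crossings = count_interior_runs(prof >= thr), length_px = L,
         degenerate = FALSE)
  }
  d1 <- one(c(0, 0), c(w - 1, h - 1))
  if (diagonal == "both") {
    d2 <- one(c(w - 1, 0), c(0, h - 1))
    crossings <- (d1$crossings + d2$crossings) / 2
    L <- (d1$length_px + d2$length_px) / 2
    degenerate <- d1$degenerate && d2$degenerate
  } else {
    crossings <- d1$crossings; L <- d1$length_px; degenerate <- d1$degenerate
  }
  len_um <- L * pixel_size_um
  list(crossings = crossings, transect_length_um = len_um,
       tti_per_um = crossings / len_um, degenerate = degenerate)
}

# Count maximal TRUE runs of a logical profile, excluding any run containing
# the first or last sample (plasma-membrane contacts at the cell corners).
count_interior_runs <- function(above) {
  r <- rle(above)
  if (length(r$values) == 0) return(0L)
  runs <- which(r$values)
  if (length(runs) == 0) return(0L)
  drop_first <- r$values[1]
  drop_last <- r$values[length(r$values)]
  n <- length(runs) - as.integer(drop_first) - as.integer(drop_last)
  # a single run spanning the whole profile would be subtracted twice
  max(n, 0L)
}

#' Morphology table for a set of cells
#'
#' Runs [segment_lumen()], [compute_vmi()] and [compute_tti()] for every ROI
#' and collects one record per cell. Per-cell failures (e.g. no compartment
#' found) are recorded as a failure code with `NA` metrics, never fatal.
#'
#' @param frames a single matrix shared by all ROIs, or a list of matrices
#'   parallel to `rois` (one frame per cell, e.g. synthetic single-cell
#'   renders).
#' @param rois list of [cell_roi()].
#' @param pixel_size_um micrometers per pixel.
#' @param diagonal transect mode passed to [compute_tti()].
#' @param vmi_strategy passed to [compute_vmi()].
#' @param min_area_px passed to [segment_lumen()].
#' @param root_surface optional logical vector (metadata filter flag carried
#'   through to the output).
#' @return data frame with columns cell_id, condition_label, length_um,
#'   vmi_um2, ln_vmi, crossings, transect_length_um, tti_per_um, flags.
#' @export
morphology_table <- function(frames, rois, pixel_size_um = 0.11,
                             diagonal = "tl-br", vmi_strategy = "feret",
                             min_area_px = 9, root_surface = NULL) {
  if (is.matrix(frames)) frames <- rep(list(frames), length(rois))
  stopifnot(length(frames) == length(rois))
  rows <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    rec <- data.frame(cell_id = roi$cell_id,
                      condition_label = roi$condition_label,
                      length_um = roi$length_um, vmi_um2 = NA_real_,
                      ln_vmi = NA_real_, crossings = NA_real_,
                      transect_length_um = NA_real_, tti_per_um = NA_real_,
                      flags = "")
    flags <- character(0)
    res <- tryCatch({
      mask <- suppressWarnings(
        segment_lumen(frames[[i]], roi, min_area_px = min_area_px,
                      pixel_size_um = pixel_size_um))
      if (mask$degenerate) flags <- c(flags, "degenerate_roi")
      if (length(mask$border_labels) > 0) flags <- c(flags, "border_touching")
      if (mask$K >= 1) {
        vmi <- compute_vmi(mask, strategy = vmi_strategy)
        rec$vmi_um2 <- vmi$vmi_um2; rec$ln_vmi <- vmi$ln_vmi
      } else flags <- c(flags, "no_compartment")
      tti <- compute_tti(frames[[i]], roi, pixel_size_um = pixel_size_um,
                         diagonal = diagonal)
      if (tti$degenerate) flags <- c(flags, "degenerate_transect")
      rec$crossings <- tti$crossings
      rec$transect_length_um <- tti$transect_length_um
      rec$tti_per_um <- tti$tti_per_um
      rec
    }, error = function(e) {
      flags <<- c(flags, paste0("error:", conditionMessage(e)))
      rec
    })
    res$flags <- paste(flags, collapse = ";")
    if (!is.null(root_surface)) res$root_surface <- root_surface[i]
    res
  })
  do.call(rbind, rows)
}
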