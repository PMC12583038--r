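#' Time-lapse movie container
#'
#' A `tono_movie` is an ordered list of single-plane grayscale frames sharing
#' one shape, plus the physical metadata needed downstream: the pixel size in
#' micrometers and the frame interval in seconds. Frame `k` (1-based list
#' index) is taken at time `t = (k - 1) * frame_interval_s`. Intensities are
#' stored as floats; `bit_depth` records the nominal acquisition depth (8 or
#' 16) used when writing TIFF.
#'
#' @param frames list of numeric matrices (rows = y, cols = x), all the same
#'   shape, or a single matrix for a one-frame "movie".
#' @param pixel_size_um micrometers per pixel (isotropic).
#' @param frame_interval_s seconds between consecutive frames.
#' @param bit_depth nominal bit depth, 8 or 16.
#' @return an object of class `tono_movie`.
#' @export
tono_movie <- function(frames, pixel_size_um = 0.11, frame_interval_s = 2,
                       bit_depth = 16L) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, all(vapply(frames, is.matrix, logical(1))))
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop("all frames must share one shape")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, bit_depth = as.integer(bit_depth)),
    class = "tono_movie")
}

#' @export
print.tono_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "tono_movie: %d frame(s) of %d x %d px, %.3g um/px, dt = %g s, %d-bit\n",
    length(x$frames), d[1], d[2], x$pixel_size_um, x$frame_interval_s,
    x$bit_depth))
  invisible(x)
}

#' Number of frames and time axis of a movie
#' @param movie a [tono_movie()].
#' @return `n_frames`: integer count. `frame_times`: numeric vector of
#'   acquisition times in seconds, starting at 0.
#' @export
n_frames <- function(movie) length(movie$frames)

#' @rdname n_frames
#' @export
frame_times <- function(movie) {
  (seq_len(n_frames(movie)) - 1) * movie$frame_interval_s
}

#' Read / write a movie as multi-page grayscale TIFF
#'
#' Intensities are stored as unsigned integers; on read they are returned on
#' the integer scale (0..255 or 0..65535), on write floats are clamped and
#' quantized to the movie's `bit_depth`.
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_interval_s metadata to attach on read (TIFF
#'   tags are not relied upon).
#' @param bit_depth depth assumed on read when pages are not flagged.
#' @return `read_movie_tiff`: a [tono_movie()]. `write_movie_tiff`: the path,
#'   invisibly.
#' @export
read_movie_tiff <- function(path, pixel_size_um = 0.11, frame_interval_s = 2,
                            bit_depth = 16L) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel if multichannel
    matrix(as.numeric(p), nrow = nrow(p))
  })
  tono_movie(frames, pixel_size_um = pixel_size_um,
             frame_interval_s = frame_interval_s, bit_depth = bit_depth)
}

#' @rdname read_movie_tiff
#' @param movie a [tono_movie()] to write.
#' @export
write_movie_tiff <- function(movie, path) {
  maxv <- 2^movie$bit_depth - 1
  pages <- lapply(movie$frames, function(f) {
    pmin(pmax(round(f), 0), maxv) / maxv
  })
  tiff::writeTIFF(pages, path, bits.per.sample = movie$bit_depth)
  invisible(path)
}

#' Rectangular cell region of interest
#'
#' Axis-aligned rectangle in frame coordinates identifying one cell.
#' Coordinates are 0-based and half-open: the rectangle covers pixels
#' `x0 .. x0 + width - 1`, `y0 .. y0 + height - 1`, with y increasing
#' downward. The cell length is the ROI's y-extent in micrometers
#' (`height * pixel_size_um`), matching the convention that roots are rotated
#' to vertical before ROIs are drawn.
#'
#' @param cell_id identifier (string or number; stored as character).
#' @param x0,y0 top-left corner, 0-based pixels.
#' @param width,height extent in pixels; both must be at least 8.
#' @param condition_label genotype/treatment label, e.g. `"WT"` or `"SMIFH2"`.
#' @param pixel_size_um micrometers per pixel, used to derive `length_um`.
#' @return an object of class `cell_roi`.
#' @export
cell_roi <- function(cell_id, x0, y0, width, height,
                     condition_label = "unlabeled", pixel_size_um = 0.11) {
  stopifnot(width >= 8, height >= 8, x0 >= 0, y0 >= 0)
  structure(
    list(cell_id = as.character(cell_id), x0 = as.integer(x0),
         y0 = as.integer(y0), width = as.integer(width),
         height = as.integer(height),
         condition_label = as.character(condition_label),
         length_um = height * pixel_size_um),
    class = "cell_roi")
}

#' Read / write cell ROIs as JSON or CSV
#'
#' The on-disk record is a flat table/array of
#' `{cell_id, x0, y0, width, height, condition_label}`; format is chosen by
#' file extension (`.json` or `.csv`).
#'
#' @param path file path ending in `.json` or `.csv`.
#' @param pixel_size_um pixel size used to derive each ROI's `length_um`.
#' @return `read_rois`: a list of [cell_roi()]. `write_rois`: the path,
#'   invisibly.
#' @export
read_rois <- function(path, pixel_size_um = 0.11) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    json = jsonlite::fromJSON(path),
    csv  = utils::read.csv(path, stringsAsFactors = FALSE),
    stop("unsupported ROI format: .", ext))
  lapply(seq_len(nrow(df)), function(i) {
    cell_roi(df$cell_id[i], df$x0[i], df$y0[i], df$width[i], df$height[i],
             condition_label = df$condition_label[i],
             pixel_size_um = pixel_size_um)
  })
}

#' @rdname read_rois
#' @param rois list of [cell_roi()] to write.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r) {
    data.frame(cell_id = r$cell_id, x0 = r$x0, y0 = r$y0, width = r$width,
               height = r$height, condition_label = r$condition_label)
  }))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else stop("unsupported ROI format: .", ext)
  invisible(path)
}
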