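#' Movie rendering parameters
#'
#' Geometry and photometry for rasterizing a trace into a synthetic
#' grayscale stack. The glia limitans is drawn as a fixed dark horizontal
#' landmark at `boundary_row`; rows above it (smaller indices) are inside the
#' spinal cord. Intensities are stored as `AU / au_max` in [0, 1] and written
#' as 16-bit TIFF.
#'
#' @param width,height Frame size in pixels.
#' @param pixel_size_um Pixel pitch (um/px).
#' @param boundary_row Image row of the glia limitans.
#' @param background_au Background level in AU.
#' @param noise_sd Per-pixel Gaussian noise SD in AU (default 0).
#' @param au_max AU value mapped to full scale.
#' @return List of class `movie_params`.
#' @export
movie_params <- function(width = 64, height = 160, pixel_size_um = 0.5,
                         boundary_row = 50, background_au = 10,
                         noise_sd = 0, au_max = 200) {
  stopifnot(width >= 8, height >= 8, pixel_size_um > 0,
            boundary_row >= 1, boundary_row <= height)
  structure(list(width = width, height = height,
                 pixel_size_um = pixel_size_um, boundary_row = boundary_row,
                 background_au = background_au, noise_sd = noise_sd,
                 au_max = au_max),
            class = "movie_params")
}

## Offsets (dr, dc) of the npx pixels nearest the blob center, in a
## deterministic order (distance, then row, then column).
.blob_offsets <- function(npx) {
  r <- ceiling(sqrt(npx / pi)) + 2L
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[order(g$dr^2 + g$dc^2, g$dr, g$dc), ]
  g[seq_len(npx), ]
}

#' Render a trace table as a synthetic grayscale movie
#'
#' One frame per trace row. The growth cone is drawn as a compact blob whose
#' pixel count times the pixel area matches `area_um2` to within half a pixel
#' area and whose pixel value equals `intensity_au`; the blob's dorsal-most
#' pixel row encodes `position_um` relative to the boundary row. Frames where
#' the growth cone is absent contain only background (and the boundary
#' landmark).
#'
#' @param trace A trace table.
#' @param params A [movie_params()] list.
#' @param seed Seed for the pixel noise (unused at `noise_sd = 0`).
#' @return Numeric array `height x width x n_frames` with values in [0, 1].
#' @export
render_movie <- function(trace, params = movie_params(), seed = 0) {
  .check_trace(trace)
  stopifnot(inherits(params, "movie_params"))
  withr::local_seed(as.integer(seed))
  px <- params$pixel_size_um
  n <- nrow(trace)
  arr <- array(params$background_au / params$au_max,
               dim = c(params$height, params$width, n))
  if (params$noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, params$noise_sd) / params$au_max
  ## boundary landmark: a dark line (kept below background so it can never be
  ## segmented as signal)
  arr[params$boundary_row, , ] <- (params$background_au - 5) / params$au_max
  ccol <- round(params$width / 2)
  for (i in seq_len(n)) {
    if (!trace$present[i]) next
    npx <- max(1L, as.integer(round(trace$area_um2[i] / px^2)))
    off <- .blob_offsets(npx)
    top <- params$boundary_row - as.integer(round(trace$position_um[i] / px))
    rows <- off$dr - min(off$dr) + top
    cols <- off$dc + ccol
    if (min(rows) < 1 || max(rows) > params$height ||
        min(cols) < 1 || max(cols) > params$width)
      stop("frame too small to contain the growth-cone blob (frame ",
           trace$frame[i], ")", call. = FALSE)
    arr[cbind(rows, cols, i)] <- trace$intensity_au[i] / params$au_max
  }
  arr[] <- pmax(0, pmin(1, arr))
  arr
}

#' Write / read a movie as multi-page 16-bit grayscale TIFF
#'
#' @param movie Array `height x width x n_frames` in [0, 1].
#' @param path Output path.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   returns the array.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- lapply(seq_len(dim(movie)[3]), function(i) movie[, , i])
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame dimensions in ", path, call. = FALSE)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}
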