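#' Segment the growth cone in one frame
#'
#' Thresholds the frame at the larger of the Otsu threshold and a robust
#' floor (median + 3 MAD of the frame), labels connected components, and
#' returns the component nearest the prior terminus position (the largest
#' component when no prior is given). Components smaller than `min_size`
#' pixels are ignored.
#'
#' @param frame Numeric matrix (any consistent intensity scale).
#' @param prior Optional prior terminus as `c(row, col)`.
#' @param min_size Minimum component size in pixels (default 5).
#' @return Logical mask matrix; all-`FALSE` (with attribute `empty = TRUE`)
#'   when no component qualifies, including for an all-constant frame.
#' @export
segment_growth_cone <- function(frame, prior = NULL, min_size = 5) {
  stopifnot(is.matrix(frame))
  empty <- function() {
    m <- matrix(FALSE, nrow(frame), ncol(frame))
    attr(m, "empty") <- TRUE
    m
  }
  rng <- range(frame)
  if (diff(rng) == 0) return(empty())
  thr_otsu <- EBImage::otsu(EBImage::Image(frame), range = rng)
  floor_thr <- stats::median(frame) + 3 * stats::mad(frame)
  thr <- max(thr_otsu, floor_thr)
  bw <- frame > thr
  if (!any(bw)) return(empty())
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0) return(empty())
  if (is.null(prior) || length(keep) == 1) {
    best <- keep[which.max(sizes[keep])]
  } else {
    d <- vapply(keep, function(k) {
      w <- which(lab == k, arr.ind = TRUE)
      sqrt((mean(w[, 1]) - prior[1])^2 + (mean(w[, 2]) - prior[2])^2)
    }, numeric(1))
    best <- keep[which.min(d)]
  }
  mask <- lab == best
  attr(mask, "empty") <- FALSE
  mask
}

#' Extract a trace table from an image stack
#'
#' Per frame: growth-cone area = mask pixels x pixel area; intensity = mean
#' pixel value inside the mask (converted back to AU); position = signed
#' distance of the mask's dorsal-most (boundary-most) pixel row from the
#' boundary row, positive inside the spinal cord. Frames with an empty mask
#' are marked absent. Tracking is seeded by the largest component of the
#' first non-empty frame and follows the mask centroid thereafter.
#'
#' @param movie Array `height x width x n_frames` (values in [0, 1] as
#'   produced by [render_movie()] / [read_movie_tiff()]), or a path to a
#'   multi-page TIFF.
#' @param params The [movie_params()] used to render (supplies pixel size,
#'   boundary row and the AU scale).
#' @param dt_min Frame interval in minutes (default 5).
#' @return A trace table (tibble) with the same schema as
#'   [simulate_axon()]'s, interchangeable downstream.
#' @export
track <- function(movie, params = movie_params(), dt_min = AX_DT_MIN) {
  if (is.character(movie)) movie <- read_movie_tiff(movie)
  stopifnot(is.array(movie), length(dim(movie)) == 3)
  if (dim(movie)[3] < 2) stop("need at least 2 frames", call. = FALSE)
  px <- params$pixel_size_um
  n <- dim(movie)[3]
  prior <- NULL
  res <- vector("list", n)
  soma_um <- -40
  for (i in seq_len(n)) {
    mask <- segment_growth_cone(movie[, , i] * params$au_max, prior = prior)
    if (isTRUE(attr(mask, "empty"))) {
      res[[i]] <- c(NA_real_, NA_real_, NA_real_)
      next
    }
    w <- which(mask, arr.ind = TRUE)
    prior <- c(mean(w[, 1]), mean(w[, 2]))
    area <- nrow(w) * px^2
    intensity <- mean(movie[, , i][mask] * params$au_max)
    position <- (params$boundary_row - min(w[, 1])) * px
    res[[i]] <- c(area, intensity, position)
  }
  m <- do.call(rbind, res)
  present <- !is.na(m[, 1])
  trace <- tibble::tibble(
    frame = 0:(n - 1L),
    time_min = (0:(n - 1L)) * dt_min,
    area_um2 = m[, 1],
    intensity_au = m[, 2],
    position_um = m[, 3],
    length_um = ifelse(present, m[, 3] - soma_um, 0),
    present = present
  )
  class(trace) <- c("trace_table", class(trace))
  trace
}
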