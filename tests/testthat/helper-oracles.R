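# Independent brute-force scanner used as the oracle for detect_peaks:
# explicit frame-by-frame scan over the thresholded trace, written without
# rle() so it shares no code path with the implementation.
brute_force_peaks <- function(trace, k = 3, merge_gap = 1) {
  x <- trace$intensity_au
  pres <- trace$present
  xp <- x[pres]
  base <- median(xp)
  sc <- mad(xp)
  if (sc == 0) sc <- sd(xp)
  if (is.na(sc) || sc == 0) {
    return(data.frame(start_frame = integer(), end_frame = integer()))
  }
  thr <- base + k * sc
  above <- !is.na(x) & pres & x >= thr
  n <- length(above)
  starts <- ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    s <- i; e <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (above[j]) { e <- j; gap <- 0L } else {
        gap <- gap + 1L
        if (gap > merge_gap) break
      }
      j <- j + 1L
    }
    starts <- c(starts, s); ends <- c(ends, e)
    i <- j + 1L
  }
  data.frame(start_frame = trace$frame[starts], end_frame = trace$frame[ends])
}

# Minimal hand-built trace table for worked examples.
make_manual_trace <- function(intensity, position = NULL, length_um = NULL,
                              area = NULL, present = NULL) {
  n <- length(intensity)
  if (is.null(present)) present <- !is.na(intensity)
  if (is.null(position)) position <- rep(-1, n)
  if (is.null(length_um)) length_um <- position + 40
  if (is.null(area)) area <- rep(12, n)
  tibble::tibble(
    frame = 0:(n - 1L),
    time_min = (0:(n - 1L)) * 5,
    area_um2 = ifelse(present, area, NA_real_),
    intensity_au = ifelse(present, intensity, NA_real_),
    position_um = ifelse(present, position, NA_real_),
    length_um = ifelse(present, length_um, 0),
    present = present
  )
}

# Baseline with a small +/-1 alternation so the MAD scale is informative.
make_step_trace <- function(n = 100, elevated = integer(0), high = 120) {
  intensity <- 100 + rep(c(-1, 1), length.out = n)
  intensity[elevated + 1L] <- high
  make_manual_trace(intensity)
}
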