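#' Detect retraction events in an axon-length series
#'
#' A retraction is a maximal interval in which the axon length falls from at
#' least `l_grow` down to at most `theta` times the running maximum attained
#' since the previous retraction. Both the initial post-injury retraction and
#' any later collapse back to the soma qualify.
#'
#' @param length_um Numeric vector of axon lengths (um from the soma), one
#'   per frame; `NA` is treated as zero length (no dorsal axon).
#' @param l_grow Minimum length that arms a retraction (default 10 um).
#' @param theta Fraction of the running maximum that ends one (default 0.1).
#' @return Tibble of retraction events with `start_frame` (frame of the peak
#'   length), `trough_frame`, `start_min`, `trough_min` and `drop_um`,
#'   ordered in time.
#' @export
detect_retractions <- function(length_um, l_grow = 10, theta = 0.1) {
  stopifnot(length(length_um) >= 3)
  length_um[is.na(length_um)] <- 0
  if (any(length_um < 0)) stop("negative axon lengths", call. = FALSE)
  out <- list()
  run_max <- -Inf
  peak_i <- 1L
  armed <- FALSE
  for (i in seq_along(length_um)) {
    if (length_um[i] > run_max) { run_max <- length_um[i]; peak_i <- i }
    if (!armed && length_um[i] >= l_grow) armed <- TRUE
    if (armed && run_max >= l_grow && length_um[i] <= theta * run_max) {
      out[[length(out) + 1L]] <- c(peak_i, i, run_max - length_um[i])
      run_max <- length_um[i]
      peak_i <- i
      armed <- FALSE
    }
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(numeric(0), ncol = 3)
  tibble::tibble(
    start_frame = as.integer(m[, 1] - 1L),
    trough_frame = as.integer(m[, 2] - 1L),
    start_min = (m[, 1] - 1) * AX_DT_MIN,
    trough_min = (m[, 2] - 1) * AX_DT_MIN,
    drop_um = m[, 3]
  )
}

#' Growth-cone velocity during actin concentrates
#'
#' For each event with at least two frames, the velocity is the mean of the
#' per-frame position increments divided by the frame interval (positive =
#' toward/into the spinal cord). The axon-level value is the event-duration-
#' weighted mean.
#'
#' @param trace A trace table with `position_um`.
#' @param events Events from [detect_peaks()] on the same trace.
#' @return Axon-level velocity in um/min, or `NA` (with attribute
#'   `undefined = TRUE`) when no event has two or more frames.
#' @examples
#' # positions 0, 0.5, 1.0 um across one 3-frame event -> 0.1 um/min
#' @export
velocity_during <- function(trace, events) {
  .check_trace(trace)
  if (!"position_um" %in% names(trace))
    stop("trace lacks position_um", call. = FALSE)
  off <- trace$frame[1]
  vs <- numeric(0); wt <- numeric(0)
  for (i in seq_len(nrow(events))) {
    s <- events$start_frame[i] - off + 1L
    e <- events$end_frame[i] - off + 1L
    if (e - s + 1L < 2L) next
    p <- trace$position_um[s:e]
    if (anyNA(p)) next
    vs <- c(vs, mean(diff(p)) / AX_DT_MIN)
    wt <- c(wt, events$duration_min[i])
  }
  if (length(vs) == 0)
    return(structure(NA_real_, undefined = TRUE))
  sum(vs * wt) / sum(wt)
}

#' Cohort mean and SEM of axon-level velocities
#'
#' @param v Numeric vector of per-axon velocities; `NA` values (axons without
#'   usable events) are dropped.
#' @return List with `mean`, `sem`, `n`.
#' @export
velocity_summary <- function(v) {
  v <- v[!is.na(v)]
  list(mean = mean(v),
       sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
       n = length(v))
}

#' Call spinal re-entry from a position trace
#'
#' An axon is called `reentered` when its terminus position exceeds
#' `epsilon_um` inside the glia limitans for at least `m_frames` consecutive
#' frames within the 24-h movie; the crossing time is the first frame of the
#' first qualifying run. Otherwise the call is `failed_retracted` if the axon
#' regrew (reached at least `l_grow` after first dropping below it) and
#' `no_regrowth` if it never did (or the trace is entirely absent).
#'
#' @param trace A trace table.
#' @param epsilon_um Entry depth threshold in um (default 1).
#' @param m_frames Persistence requirement in frames (default 3, i.e. 15 min,
#'   guarding against single-frame noise crossings).
#' @param l_grow Regrowth threshold in um (default 10).
#' @return A list of class `reentry_call`: `outcome`, `crossing_time_min`
#'   (`NA` unless reentered), `n_retractions`.
#' @export
call_reentry <- function(trace, epsilon_um = 1, m_frames = 3, l_grow = 10) {
  .check_trace(trace)
  stopifnot(epsilon_um > 0, m_frames >= 1)
  len <- trace$length_um
  len[is.na(len)] <- 0
  retr <- detect_retractions(len, l_grow = l_grow)
  if (!any(trace$present)) {
    return(structure(list(outcome = "no_regrowth",
                          crossing_time_min = NA_real_,
                          n_retractions = nrow(retr)),
                     class = "reentry_call"))
  }
  inside <- !is.na(trace$position_um) & trace$position_um > epsilon_um
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= m_frames)
  if (length(qual)) {
    return(structure(list(outcome = "reentered",
                          crossing_time_min = trace$time_min[starts[qual[1]]],
                          n_retractions = nrow(retr)),
                     class = "reentry_call"))
  }
  ## regrowth: reached l_grow after first falling below it
  below <- which(len < l_grow)
  regrew <- length(below) > 0 && any(len[below[1]:length(len)] >= l_grow)
  structure(list(outcome = if (regrew) "failed_retracted" else "no_regrowth",
                 crossing_time_min = NA_real_,
                 n_retractions = nrow(retr)),
            class = "reentry_call")
}

#' @export
print.reentry_call <- function(x, ...) {
  cat("<reentry_call> ", x$outcome, sep = "")
  if (!is.na(x$crossing_time_min))
    cat(" at ", x$crossing_time_min, " min", sep = "")
  cat("; retractions: ", x$n_retractions, "\n", sep = "")
  invisible(x)
}

#' Per-condition outcome fractions
#'
#' @param calls Tibble with columns `condition` and `outcome` (one row per
#'   axon), e.g. assembled from [call_reentry()] results.
#' @return Tibble with one row per condition x outcome (all three outcomes
#'   always present) and columns `n` and `fraction`; fractions sum to 1
#'   within each condition.
#' @export
outcome_summary <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("condition", "outcome") %in% names(calls)),
            nrow(calls) >= 1)
  lv <- c("reentered", "failed_retracted", "no_regrowth")
  tab <- table(condition = calls$condition,
               outcome = factor(calls$outcome, levels = lv))
  out <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  totals <- rowSums(tab)
  out$fraction <- out$n / totals[out$condition]
  tibble::as_tibble(out[order(out$condition), ])
}
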