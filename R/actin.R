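#' Detect actin-concentrate peaks in an intensity trace
#'
#' A concentrate is a maximal run of present frames whose Lifeact intensity
#' is at least `baseline + k * scale`, where the baseline is the median of
#' present-frame intensities and the scale their MAD (falling back to the SD
#' when the MAD is zero on a non-constant trace). Runs separated by at most
#' `merge_gap` sub-threshold frames are merged, so a single noisy dip does
#' not split one concentrate into two.
#'
#' @param trace A trace table (see [simulate_axon()] or [track()]).
#' @param k Threshold multiplier (default 3).
#' @param merge_gap Maximum number of sub-threshold frames bridged when
#'   merging adjacent runs (default 1).
#' @return Tibble of peak events with `start_frame`, `end_frame` (inclusive),
#'   `duration_min` = (end - start + 1) x 5, and `initiation_min` (time
#'   post-injury of the first event frame). Zero rows if no frame exceeds the
#'   threshold.
#' @examples
#' sim <- simulate_axon(make_preset("untreated"), seed = 2)
#' detect_peaks(sim$trace)
#' @export
detect_peaks <- function(trace, k = 3, merge_gap = 1) {
  .check_trace(trace)
  stopifnot(k > 0, merge_gap >= 0)
  present <- trace$present
  if (sum(present) < 3)
    stop("need at least 3 present frames to detect peaks", call. = FALSE)
  x <- trace$intensity_au[present]
  baseline <- stats::median(x)
  scale <- stats::mad(x)
  if (scale == 0) scale <- stats::sd(x)
  above <- !is.na(trace$intensity_au) & present &
    (trace$intensity_au >= baseline + k * scale)
  if (is.na(scale) || scale == 0 || !any(above)) {
    return(tibble::tibble(start_frame = integer(), end_frame = integer(),
                          duration_min = numeric(), initiation_min = numeric()))
  }
  r <- rle(above)
  ## merge sub-threshold gaps of length <= merge_gap between two runs
  if (length(r$values) > 2 && merge_gap > 0) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    bridge <- interior[!r$values[interior] & r$lengths[interior] <= merge_gap]
    if (length(bridge)) {
      r$values[bridge] <- TRUE
      above <- inverse.rle(r)
      r <- rle(above)
    }
  }
  ends_all <- cumsum(r$lengths)
  starts_all <- ends_all - r$lengths + 1L
  sel <- which(r$values)
  s <- trace$frame[starts_all[sel]]
  e <- trace$frame[ends_all[sel]]
  tibble::tibble(
    start_frame = s,
    end_frame = e,
    duration_min = (e - s + 1L) * AX_DT_MIN,
    initiation_min = s * AX_DT_MIN
  )
}

#' Summarize peak events over a cohort of axons
#'
#' Duration is pooled across all events of all axons (matching per-
#' concentrate sample sizes); count and initiation time are summarized per
#' axon, with axons contributing zero events counted in the mean count.
#'
#' @param events Tibble of events carrying an `axon_id` column in addition to
#'   the [detect_peaks()] columns (bind the per-axon results together), or a
#'   list of per-axon event tibbles.
#' @param axon_ids Vector of all axon ids in the cohort, including axons with
#'   no events. Defaults to the ids present in `events`.
#' @return A list: `n_axons`, `n_events`, `count_mean`/`count_sem` (peaks per
#'   axon), `duration_mean`/`duration_sem` (min, pooled over events; `NA` and
#'   `duration_defined = FALSE` when there are no events anywhere), and
#'   `initiation_mean`/`initiation_sem` (min, per-axon first event).
#' @export
peak_stats <- function(events, axon_ids = NULL) {
  if (is.list(events) && !is.data.frame(events)) {
    nm <- names(events) %||% as.character(seq_along(events))
    events <- dplyr::bind_rows(
      lapply(seq_along(events), function(i)
        dplyr::mutate(events[[i]], axon_id = nm[i])))
    if (is.null(axon_ids)) axon_ids <- nm
  }
  stopifnot(is.data.frame(events))
  if (nrow(events) > 0 && !"axon_id" %in% names(events))
    stop("events must carry an axon_id column", call. = FALSE)
  if (is.null(axon_ids)) axon_ids <- unique(events$axon_id)
  if (length(axon_ids) < 1) stop("need at least one axon", call. = FALSE)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  counts <- vapply(axon_ids, function(a)
    sum(events$axon_id == a), integer(1))
  has_events <- nrow(events) > 0
  first_init <- if (has_events)
    vapply(split(events$initiation_min, events$axon_id), min, numeric(1))
  else numeric(0)
  list(
    n_axons = length(axon_ids),
    n_events = nrow(events),
    count_mean = mean(counts),
    count_sem = sem(counts),
    duration_defined = has_events,
    duration_mean = if (has_events) mean(events$duration_min) else NA_real_,
    duration_sem = if (has_events) sem(events$duration_min) else NA_real_,
    initiation_mean = if (has_events) mean(first_init) else NA_real_,
    initiation_sem = if (has_events) sem(first_init) else NA_real_
  )
}

#' Classify the actin organization of every frame
#'
#' Frames inside a detected concentrate are labelled `concentrate`; present
#' frames within `w` frames of an event boundary are `transition` (the time
#' points temporally adjacent to concentrates); remaining present frames are
#' `dispersed`; non-present frames are `absent`.
#'
#' @param trace A trace table.
#' @param events Events from [detect_peaks()] on the same trace.
#' @param w Adjacency window in frames (default 1).
#' @return A list with `states` (tibble `frame`, `time_min`, `state`) and
#'   `fractions` (named fractions of present frames in each of the three
#'   non-absent states; they sum to 1 when present frames exist).
#' @export
classify_frames <- function(trace, events, w = 1) {
  .check_trace(trace)
  stopifnot(w >= 1)
  n <- nrow(trace)
  if (nrow(events) > 0 &&
      (min(events$start_frame) < min(trace$frame) ||
       max(events$end_frame) > max(trace$frame)))
    stop("events lie outside the trace frame range", call. = FALSE)
  state <- ifelse(trace$present, "dispersed", "absent")
  off <- trace$frame[1]
  for (i in seq_len(nrow(events))) {
    s <- events$start_frame[i] - off + 1L
    e <- events$end_frame[i] - off + 1L
    lo <- max(1L, s - w); hi <- min(n, e + w)
    adj <- setdiff(lo:hi, s:e)
    adj <- adj[state[adj] != "absent" & state[adj] != "concentrate"]
    state[adj] <- "transition"
    state[s:e] <- "concentrate"
  }
  pres <- state != "absent"
  fr <- c(concentrate = mean(state[pres] == "concentrate"),
          transition = mean(state[pres] == "transition"),
          dispersed = mean(state[pres] == "dispersed"))
  list(states = tibble::tibble(frame = trace$frame,
                               time_min = trace$time_min,
                               state = state),
       fractions = fr)
}

#' Area-intensity scatter table
#'
#' One row per present frame with its growth-cone area, mean Lifeact
#' intensity and (optionally) actin-state label, for plotting or export.
#'
#' @param trace A trace table.
#' @param states Optional `states` tibble from [classify_frames()].
#' @return Tibble with `time_min`, `area_um2`, `intensity_au` and `state`
#'   (`NA` when `states` is not supplied); absent frames are excluded.
#' @export
scatter_table <- function(trace, states = NULL) {
  .check_trace(trace)
  if (!any(trace$present)) stop("no present frames", call. = FALSE)
  out <- tibble::tibble(
    time_min = trace$time_min,
    area_um2 = trace$area_um2,
    intensity_au = trace$intensity_au,
    state = if (is.null(states)) NA_character_ else states$state
  )
  out[trace$present, ]
}

.check_trace <- function(trace) {
  need <- c("frame", "time_min", "intensity_au", "present")
  if (!is.data.frame(trace) || !all(need %in% names(trace)))
    stop("not a trace table; required columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
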