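#' Simulate one regenerating DRG axon
#'
#' Generates a 24-h, 5-min-sampled growth-cone trace together with its ground
#' truth. The trajectory follows the stereotyped phases seen in live imaging:
#' an initial retraction to the soma completed within 1 h of injury, dorsal
#' re-extension to the dorsal root entry zone, a series of actin-concentrate
#' events while the terminus dwells at the glia limitans, and finally either
#' spinal cord entry (if the crossing gate is satisfied) or a second
#' retraction to the soma.
#'
#' During concentrate events the Lifeact intensity is elevated (+12 AU over a
#' slowly wobbling ~100 AU baseline) and the growth-cone area reduced; frames
#' temporally adjacent to events carry intermediate values. The terminus moves
#' with a per-event velocity drawn from the preset's velocity distribution
#' (positive = toward the spinal cord). An axon crosses the boundary if and
#' only if some concentrate with terminus within `gate_boundary_um` of the
#' glia limitans persists at least `gate_min_duration` minutes; truncation of
#' the duration distribution makes this impossible for control-like presets
#' and certain for `ca_src_taxol`.
#'
#' @param preset A `condition_preset` from [make_preset()], or a preset name.
#' @param seed Integer seed; identical `(preset, seed)` give bit-identical
#'   output.
#' @param noise_sd Per-frame intensity noise SD in AU (area noise is 0.3x).
#'   Use 0 for noise-free traces.
#' @param gate_min_duration Crossing gate: minimum concentrate persistence in
#'   minutes (default 60, between the DMSO ~40-min and Taxol ~110-min means).
#' @param gate_boundary_um Crossing gate: maximum distance of the terminus
#'   from the glia limitans during the event (default 2).
#' @return A list with elements `truth` (class `axon_truth`: `events` tibble
#'   with per-event frames, minutes and velocity; `outcome` in
#'   {reentered, failed_retracted, no_regrowth}; `crossing_time_min`;
#'   `retraction_times_min`) and `trace` (tibble with `frame`, `time_min`,
#'   `area_um2`, `intensity_au`, `position_um`, `length_um`, `present`).
#'   Position is the dorsoventral coordinate of the terminus, 0 at the glia
#'   limitans, positive inside the spinal cord; length is measured from the
#'   soma (40 um ventral to the boundary).
#' @examples
#' sim <- simulate_axon(make_preset("dmso"), seed = 1)
#' sim$truth$outcome
#' @export
simulate_axon <- function(preset, seed, noise_sd = 1.5,
                          gate_min_duration = 60, gate_boundary_um = 2) {
  if (is.character(preset)) preset <- make_preset(preset)
  stopifnot(inherits(preset, "condition_preset"),
            is.numeric(seed), length(seed) == 1, seed >= 0)
  dt <- AX_DT_MIN
  n_total <- AX_N_FRAMES
  withr::local_seed(as.integer(seed))

  ## ground-truth draws
  K <- sample_peak_count(preset, 1)
  dur_min <- sample_durations(preset, K)
  nfr <- pmax(1L, as.integer(round(dur_min / dt)))
  vel <- stats::rnorm(K, preset$velocity_mean_um_per_min, preset$velocity_sd)
  phase_i <- stats::runif(1, 0, 2 * pi)
  phase_a <- stats::runif(1, 0, 2 * pi)
  ## inter-event spacing ~1 h: concentrates are sprinkled over the hours the
  ## terminus dwells at the boundary
  gaps <- 2L + stats::rpois(K, 10)

  ## schedule events after re-extension; drop events that do not fit,
  ## always keeping at least 8 frames after the last event
  arrival <- 29L
  soma_um <- -40
  dwell_um <- -1
  starts <- ends <- integer(0)
  t <- arrival
  for (j in seq_len(K)) {
    s <- t + gaps[j]
    e <- s + nfr[j] - 1L
    if (e > n_total - 1L - 8L) break
    starts <- c(starts, s); ends <- c(ends, e)
    t <- e
  }
  if (length(starts) == 0L) { # extreme scheduling overflow; keep first event
    starts <- arrival + 2L
    ends <- min(starts + nfr[1] - 1L, n_total - 9L)
  }
  n_ev <- length(starts)
  nfr <- nfr[seq_len(n_ev)]
  vel <- vel[seq_len(n_ev)]

  ## event position paths: the concentrate drives an approach that ends at
  ## the dwell position for advancing events, or a retreat that starts there;
  ## paths are clamped to stay between the boundary and the re-extended shaft
  ev_path <- lapply(seq_len(n_ev), function(j) {
    p0 <- max(dwell_um - max(0, vel[j]) * dt * (nfr[j] - 1L), -35)
    pmin(pmax(p0 + vel[j] * dt * (0:(nfr[j] - 1L)), -35), dwell_um)
  })
  ## crossing gate: persistence and proximity to the boundary
  ev_pmax <- vapply(ev_path, max, numeric(1))
  gate_ok <- preset$crossing_gated &
    (nfr * dt >= gate_min_duration) & (ev_pmax >= -gate_boundary_um)
  cross_idx <- if (any(gate_ok)) which(gate_ok)[1] else NA_integer_
  if (!is.na(cross_idx) && cross_idx < n_ev) {
    keep <- seq_len(cross_idx)
    starts <- starts[keep]; ends <- ends[keep]
    nfr <- nfr[keep]; vel <- vel[keep]; ev_path <- ev_path[keep]
    n_ev <- cross_idx
  }
  reentered <- !is.na(cross_idx)

  ## paint per-frame position and phase labels (frames are 0-based)
  idx <- function(f) f + 1L
  pos <- rep(NA_real_, n_total)
  present <- rep(FALSE, n_total)
  is_event <- rep(FALSE, n_total)
  rf <- 0:11 # initial retraction, complete within 1 h
  pos[idx(rf)] <- seq(-2, -39, length.out = length(rf))
  present[idx(rf)] <- TRUE
  gf <- 14:arrival # dorsal re-extension back to the boundary
  pos[idx(gf)] <- seq(-39, dwell_um, length.out = length(gf))
  present[idx(gf)] <- TRUE

  prev_end <- arrival
  for (j in seq_len(n_ev)) {
    s <- starts[j]; e <- ends[j]
    gap_f <- if (s - prev_end > 1L) (prev_end + 1L):(s - 1L) else integer(0)
    if (length(gap_f)) {
      interp <- seq(pos[idx(prev_end)], ev_path[[j]][1],
                    length.out = length(gap_f) + 2)
      pos[idx(gap_f)] <- interp[-c(1, length(interp))]
      present[idx(gap_f)] <- TRUE
    }
    fr <- s:e
    pos[idx(fr)] <- ev_path[[j]]
    present[idx(fr)] <- TRUE
    is_event[idx(fr)] <- TRUE
    prev_end <- e
  }

  e_last <- ends[n_ev]
  pos_end <- pos[idx(e_last)]
  crossing_frame <- NA_integer_
  retraction2_frame <- NA_integer_
  if (reentered) {
    after <- (e_last + 1L):(n_total - 1L)
    k <- seq_along(after)
    pos[idx(after)] <- pos_end + (20 - pos_end) * pmin(1, k / 5)
    present[idx(after)] <- TRUE
    crossing_frame <- after[which(pos[idx(after)] > 1)[1]]
  } else {
    ## failed axons keep dwelling at the boundary and only collapse back to
    ## the soma late (~20 h post-injury), as in the treatment-window data
    retraction2_frame <- max(241L, e_last + 1L)
    if (retraction2_frame > e_last + 1L) {
      dwf <- (e_last + 1L):(retraction2_frame - 1L)
      k1 <- min(length(dwf), 6L)
      pos[idx(dwf)] <- c(seq(pos_end, dwell_um, length.out = k1 + 1)[-1],
                         rep(dwell_um, length(dwf) - k1))
      present[idx(dwf)] <- TRUE
    }
    r2 <- retraction2_frame:min(retraction2_frame + 11L, n_total - 1L)
    p_from <- pos[idx(retraction2_frame - 1L)]
    pos[idx(r2)] <- seq(p_from, -39, length.out = length(r2) + 1)[-1]
    present[idx(r2)] <- TRUE
    ## remaining frames: no dorsal axon (absent)
  }

  ## intensity / area with slow baseline wobble; concentrates elevated and
  ## compact, adjacent frames intermediate
  time_min <- (0:(n_total - 1L)) * dt
  base_i <- 100 + 1.0 * sin(2 * pi * time_min / 480 + phase_i)
  base_a <- 12 + 0.5 * sin(2 * pi * time_min / 480 + phase_a)
  intensity <- base_i
  area <- base_a
  adj <- rep(FALSE, n_total)
  for (j in seq_len(n_ev)) {
    for (f in c(starts[j] - 1L, ends[j] + 1L)) {
      i <- idx(f)
      if (f >= 0 && f < n_total && present[i] && !is_event[i]) adj[i] <- TRUE
    }
  }
  ## concentrates saturate to a stereotyped bright, compact state; the slow
  ## wobble only modulates the dispersed baseline
  intensity[is_event] <- 112
  area[is_event] <- base_a[is_event] - 7
  intensity[adj] <- base_i[adj] + 1.5
  area[adj] <- base_a[adj] - 3
  if (noise_sd > 0) {
    ## bounded imaging noise (clamped at +/- 2.5 SD)
    clamp <- function(z, s) pmin(pmax(z, -2.5 * s), 2.5 * s)
    intensity <- intensity + clamp(stats::rnorm(n_total, 0, noise_sd), noise_sd)
    area <- pmax(0.5, area + clamp(stats::rnorm(n_total, 0, 0.3 * noise_sd),
                                   0.3 * noise_sd))
  }
  intensity[!present] <- NA_real_
  area[!present] <- NA_real_
  pos[!present] <- NA_real_
  length_um <- ifelse(present, pos - soma_um, 0)

  trace <- tibble::tibble(
    frame = 0:(n_total - 1L),
    time_min = time_min,
    area_um2 = area,
    intensity_au = intensity,
    position_um = pos,
    length_um = length_um,
    present = present
  )
  class(trace) <- c("trace_table", class(trace))

  events <- tibble::tibble(
    start_frame = starts,
    end_frame = ends,
    start_min = starts * dt,
    end_min = ends * dt,
    duration_min = nfr * dt,
    velocity_um_per_min = vel
  )
  truth <- structure(list(
    condition = preset$name,
    events = events,
    outcome = if (reentered) "reentered" else "failed_retracted",
    crossing_time_min = if (reentered) crossing_frame * dt else NA_real_,
    retraction_times_min = if (reentered) 0 else c(0, retraction2_frame * dt)
  ), class = "axon_truth")

  list(truth = truth, trace = trace)
}

#' @export
print.axon_truth <- function(x, ...) {
  cat("<axon_truth> ", x$condition, ": ", x$outcome, sep = "")
  if (!is.na(x$crossing_time_min))
    cat(" (crossed at ", x$crossing_time_min, " min)", sep = "")
  cat("\n", nrow(x$events), " concentrate event(s)\n", sep = "")
  invisible(x)
}

#' Simulate a cohort of axons from one preset
#'
#' Convenience wrapper returning per-axon truths and traces for `n_axons`
#' independent axons, seeded deterministically from `seed`.
#'
#' @inheritParams simulate_axon
#' @param n_axons Number of axons.
#' @return List with elements `truths` and `traces` (lists of length
#'   `n_axons`).
#' @export
simulate_axon_cohort <- function(preset, n_axons, seed, noise_sd = 1.5,
                                 gate_min_duration = 60,
                                 gate_boundary_um = 2) {
  if (is.character(preset)) preset <- make_preset(preset)
  sims <- lapply(seq_len(n_axons), function(i)
    simulate_axon(preset, seed + i - 1L, noise_sd = noise_sd,
                  gate_min_duration = gate_min_duration,
                  gate_boundary_um = gate_boundary_um))
  list(truths = lapply(sims, `[[`, "truth"),
       traces = lapply(sims, `[[`, "trace"))
}
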