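#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulation, peak detection, actin-state classification,
#' velocity, re-entry calling, cohort records, behavior scoring and the
#' cohort statistics, writing tidy CSV tables, JSON summaries and a run log
#' to the output directory. Identical config and seed give bit-identical
#' outputs.
#'
#' Required config keys: `presets` (character vector of preset names),
#' `n_axons`, `seed`, `outdir`. Optional: `noise_sd` (default 1.5),
#' `n_animals` (default 8; 0 skips the cohort step), `behavior_n` (default 5
#' recordings per category; 0 skips behavior), `render` (default `FALSE`;
#' when `TRUE`, the first axon of each condition is rendered to a TIFF stack
#' and re-quantified with [track()]).
#'
#' @param config Named list, or path to a YAML/JSON config file.
#' @param outdir Overrides `config$outdir` when given.
#' @return Invisibly, a list with the per-condition summaries and the paths
#'   written.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    cfg_path <- config
    config <- if (grepl("\\.json$", cfg_path, ignore.case = TRUE))
      jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    else yaml::read_yaml(cfg_path)
  }
  stopifnot(is.list(config))
  required <- c("presets", "n_axons", "seed", "outdir")
  missing_keys <- required[vapply(required, function(k)
    is.null(config[[k]]), logical(1))]
  if (!is.null(outdir)) missing_keys <- setdiff(missing_keys, "outdir")
  if (length(missing_keys))
    stop("config missing required key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  outdir <- outdir %||% config$outdir
  noise_sd <- config$noise_sd %||% 1.5
  n_animals <- config$n_animals %||% 8
  behavior_n <- config$behavior_n %||% 5
  do_render <- isTRUE(config$render)
  seed <- as.integer(config$seed)
  n_axons <- as.integer(config$n_axons)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- c("axentry pipeline run",
                 "config:",
                 paste0("  ", strsplit(yaml::as.yaml(config), "\n")[[1]]))
  all_events <- list()
  summaries <- list()
  calls_tbl <- list()
  paths <- character(0)

  for (pi in seq_along(config$presets)) {
    cond <- config$presets[[pi]]
    preset <- make_preset(cond)
    base_seed <- seed + (pi - 1L) * n_axons
    log_lines <- c(log_lines, sprintf("condition %s: axon seeds %d..%d",
                                      cond, base_seed,
                                      base_seed + n_axons - 1L))
    sims <- simulate_axon_cohort(preset, n_axons, base_seed,
                                 noise_sd = noise_sd)
    events <- lapply(sims$traces, detect_peaks)
    ids <- sprintf("%s_%03d", cond, seq_len(n_axons))
    ev_tbl <- dplyr::bind_rows(lapply(seq_len(n_axons), function(i)
      dplyr::mutate(events[[i]], axon_id = ids[i], condition = cond)))
    all_events[[cond]] <- ev_tbl
    vel <- vapply(seq_len(n_axons), function(i)
      as.numeric(velocity_during(sims$traces[[i]], events[[i]])), numeric(1))
    calls <- lapply(sims$traces, call_reentry)
    calls_tbl[[cond]] <- tibble::tibble(
      axon_id = ids, condition = cond,
      outcome = vapply(calls, `[[`, character(1), "outcome"),
      crossing_time_min = vapply(calls, `[[`, numeric(1),
                                 "crossing_time_min"),
      n_retractions = vapply(calls, `[[`, integer(1), "n_retractions"),
      velocity_um_per_min = vel
    )
    states <- lapply(seq_len(n_axons), function(i)
      classify_frames(sims$traces[[i]], events[[i]]))
    frac <- colMeans(do.call(rbind, lapply(states, `[[`, "fractions")))
    st <- peak_stats(ev_tbl, axon_ids = ids)
    vsum <- velocity_summary(vel)
    summaries[[cond]] <- list(
      condition = cond, n_axons = n_axons,
      peaks_per_axon_mean = st$count_mean, peaks_per_axon_sem = st$count_sem,
      duration_mean_min = st$duration_mean, duration_sem_min = st$duration_sem,
      initiation_mean_min = st$initiation_mean,
      velocity_mean_um_per_min = vsum$mean, velocity_sem = vsum$sem,
      state_fractions = as.list(frac),
      reentered_fraction = mean(calls_tbl[[cond]]$outcome == "reentered")
    )
    traces_tbl <- dplyr::bind_rows(lapply(seq_len(n_axons), function(i)
      dplyr::mutate(sims$traces[[i]], axon_id = ids[i], condition = cond)))
    p1 <- file.path(outdir, paste0("traces_", cond, ".csv"))
    p2 <- file.path(outdir, paste0("events_", cond, ".csv"))
    write_trace_csv(traces_tbl, p1)
    readr::write_csv(ev_tbl, p2)
    paths <- c(paths, p1, p2)

    if (do_render) {
      mp <- movie_params()
      movie <- render_movie(sims$traces[[1]], mp)
      p3 <- file.path(outdir, paste0("movie_", cond, ".tiff"))
      write_movie_tiff(movie, p3)
      requant <- track(movie, mp)
      p4 <- file.path(outdir, paste0("requantified_", cond, ".csv"))
      write_trace_csv(requant, p4)
      paths <- c(paths, p3, p4)
    }

    if (n_animals > 0) {
      coh <- simulate_cohort(preset, n_animals, seed + 90000L + pi)
      p5 <- file.path(outdir, paste0("cohort_", cond, ".csv"))
      readr::write_csv(coh$records, p5)
      paths <- c(paths, p5)
      if (stats::var(coh$records$n_regenerated) > 0) {
        rg <- regress(coh$records$n_regenerated, coh$records$perk_ipsi_au)
        summaries[[cond]]$perk_regression <-
          list(slope = rg$slope, intercept = rg$intercept,
               r_squared = rg$r_squared, p_value = rg$p_value, n = rg$n)
      } else {
        log_lines <- c(log_lines, sprintf(
          "condition %s: n_regenerated constant; pErk regression skipped",
          cond))
      }
    }
  }

  calls_all <- dplyr::bind_rows(calls_tbl)
  p6 <- file.path(outdir, "reentry_calls.csv")
  readr::write_csv(calls_all, p6)
  p7 <- file.path(outdir, "outcome_summary.csv")
  readr::write_csv(outcome_summary(calls_all), p7)
  paths <- c(paths, p6, p7)

  ev_all <- dplyr::bind_rows(all_events)
  if (length(unique(ev_all$condition)) >= 2 &&
      all(table(ev_all$condition) >= 2)) {
    cmp <- compare_groups(ev_all, "duration_min", "condition")
    p8 <- file.path(outdir, "duration_anova.csv")
    readr::write_csv(cmp$tukey, p8)
    paths <- c(paths, p8)
    summaries$duration_anova <- list(
      statistic = cmp$anova$statistic[1], p_value = cmp$anova$p_value[1])
  }

  if (behavior_n > 0) {
    cats <- c("typical", "stunted", "moderate", "absent")
    rows <- list()
    for (ci in seq_along(cats)) {
      for (i in seq_len(behavior_n)) {
        sim <- simulate_behavior(cats[ci], seed + 80000L + ci * 100L + i)
        sc <- score_behavior(sim$truth$tail_angle_deg,
                             sim$truth$displacement)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          true_category = cats[ci], rep = i,
          n_shivers = sc$n_shivers, pct_time = sc$pct_time,
          category = sc$category)
      }
    }
    p9 <- file.path(outdir, "behavior_scores.csv")
    readr::write_csv(dplyr::bind_rows(rows), p9)
    paths <- c(paths, p9)
  }

  p10 <- file.path(outdir, "summary.json")
  jsonlite::write_json(summaries, p10, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  p11 <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, p11)
  paths <- c(paths, p10, p11)
  invisible(list(summaries = summaries, paths = paths))
}
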