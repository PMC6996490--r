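## Condition presets: the per-condition quantities the generator emulates.
## Duration means and the dmso/taxol/co-treatment velocities are the printed
## study values; the remaining velocities are generator choices (see the
## methods vignette). Truncation bounds are chosen so that the duration-gated
## crossing (>= 60 min at the boundary) is impossible for control-like
## conditions and certain for ca_src_taxol.

.preset_registry <- function() {
  list(
    untreated    = list(n_peaks_mean = 3.2, duration_mean_min = 26.31,
                        duration_shape = 4, duration_bounds_min = c(5, 55),
                        velocity_mean_um_per_min = -0.0758, velocity_sd = 0.15,
                        crossing_gated = TRUE),
    dmso         = list(n_peaks_mean = 3.2, duration_mean_min = 40.59,
                        duration_shape = 4, duration_bounds_min = c(5, 55),
                        velocity_mean_um_per_min = -0.0758, velocity_sd = 0.15,
                        crossing_gated = TRUE),
    taxol        = list(n_peaks_mean = 3.2, duration_mean_min = 110.7,
                        duration_shape = 4, duration_bounds_min = c(5, 400),
                        velocity_mean_um_per_min = 0.142, velocity_sd = 0.15,
                        crossing_gated = TRUE),
    taxol_gm6001 = list(n_peaks_mean = 3.2, duration_mean_min = 40.59,
                        duration_shape = 4, duration_bounds_min = c(5, 55),
                        velocity_mean_um_per_min = 0.0226, velocity_sd = 0.15,
                        crossing_gated = TRUE),
    taxol_su6656 = list(n_peaks_mean = 3.2, duration_mean_min = 40.59,
                        duration_shape = 4, duration_bounds_min = c(5, 55),
                        velocity_mean_um_per_min = 0.066, velocity_sd = 0.15,
                        crossing_gated = TRUE),
    src          = list(n_peaks_mean = 3.2, duration_mean_min = 33.94,
                        duration_shape = 4, duration_bounds_min = c(5, 55),
                        velocity_mean_um_per_min = -0.0758, velocity_sd = 0.15,
                        crossing_gated = TRUE),
    ca_src       = list(n_peaks_mean = 3.2, duration_mean_min = 78.95,
                        duration_shape = 4, duration_bounds_min = c(5, 400),
                        velocity_mean_um_per_min = 0.10, velocity_sd = 0.15,
                        crossing_gated = TRUE),
    ca_src_taxol = list(n_peaks_mean = 3.2, duration_mean_min = 78.95,
                        duration_shape = 4, duration_bounds_min = c(65, 400),
                        velocity_mean_um_per_min = 0.142, velocity_sd = 0.15,
                        crossing_gated = TRUE),
    development  = list(n_peaks_mean = 3.2, duration_mean_min = 40,
                        duration_shape = 4, duration_bounds_min = c(5, 400),
                        velocity_mean_um_per_min = 0.10, velocity_sd = 0.15,
                        crossing_gated = TRUE)
  )
}

#' Names of the registered condition presets
#'
#' @return Character vector of valid preset names.
#' @export
preset_names <- function() names(.preset_registry())

## Mean of a gamma(shape, rate = shape/m) truncated to (lo, hi), as a
## function of the untruncated mean m.
.trunc_gamma_mean <- function(m, shape, lo, hi) {
  rate <- shape / m
  num <- stats::pgamma(hi, shape + 1, rate) - stats::pgamma(lo, shape + 1, rate)
  den <- stats::pgamma(hi, shape, rate) - stats::pgamma(lo, shape, rate)
  (shape / rate) * num / den
}

## Find the untruncated mean whose truncated mean equals `target`.
.calibrate_trunc_gamma <- function(target, shape, lo, hi) {
  f <- function(m) .trunc_gamma_mean(m, shape, lo, hi) - target
  m_lo <- target
  while (is.finite(f(m_lo)) && f(m_lo) > 0) m_lo <- m_lo / 2
  m_hi <- target
  while (is.finite(f(m_hi)) && f(m_hi) < 0) m_hi <- m_hi * 2
  if (!is.finite(f(m_lo)) || !is.finite(f(m_hi)))
    stop("cannot calibrate truncated gamma: target mean ", target,
         " unreachable within bounds (", lo, ", ", hi, ")", call. = FALSE)
  stats::uniroot(f, lower = m_lo, upper = m_hi, tol = 1e-10)$root
}

#' Build a condition preset
#'
#' A preset bundles the statistical structure of one experimental condition:
#' expected number of actin concentrates per axon, the concentrate-duration
#' distribution (truncated gamma, calibrated so its mean equals the condition
#' mean), growth-cone velocity during concentrates, and whether duration-gated
#' boundary crossing is permitted. Registered conditions and their duration
#' means (minutes): untreated 26.31, dmso 40.59, taxol 110.7,
#' taxol_gm6001 40.59, taxol_su6656 40.59, src 33.94, ca_src 78.95,
#' ca_src_taxol 78.95, development 40.
#'
#' @param name Condition label; one of [preset_names()].
#' @param config Optional overrides: a named list, or the path to a YAML/JSON
#'   file, whose entries replace preset fields (e.g. `duration_mean_min`,
#'   `velocity_mean_um_per_min`, `duration_bounds_min`).
#' @return An object of class `condition_preset`: a list with fields `name`,
#'   `n_peaks_mean`, `duration_mean_min`, `duration_shape`,
#'   `duration_bounds_min`, `velocity_mean_um_per_min`, `velocity_sd`,
#'   `crossing_gated`, plus the calibrated internal sampler mean
#'   `duration_gamma_mean`.
#' @examples
#' make_preset("taxol")$duration_mean_min
#' make_preset("untreated")$n_peaks_mean
#' @export
make_preset <- function(name, config = NULL) {
  reg <- .preset_registry()
  if (length(name) != 1 || !is.character(name) || !name %in% names(reg))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(reg), collapse = ", "),
         call. = FALSE)
  p <- reg[[name]]
  p$name <- name
  if (!is.null(config)) {
    if (is.character(config)) config <- read_preset_config(config, name)
    stopifnot(is.list(config))
    for (k in names(config)) p[[k]] <- config[[k]]
  }
  .validate_preset(p)
  p$duration_gamma_mean <- .calibrate_trunc_gamma(
    p$duration_mean_min, p$duration_shape,
    p$duration_bounds_min[1], p$duration_bounds_min[2])
  structure(p, class = "condition_preset")
}

.validate_preset <- function(p) {
  b <- p$duration_bounds_min
  if (!(p$duration_mean_min > 0)) stop("duration_mean_min must be > 0",
                                       call. = FALSE)
  if (!(length(b) == 2 && b[1] >= AX_DT_MIN && b[2] >= b[1]))
    stop("duration_bounds_min must be (lower >= ", AX_DT_MIN,
         ", upper >= lower)", call. = FALSE)
  if (!(p$n_peaks_mean > 0)) stop("n_peaks_mean must be > 0", call. = FALSE)
  invisible(p)
}

#' Read preset overrides from a key-value config file
#'
#' The file (YAML or JSON by extension) either holds preset fields at the top
#' level, or a map from preset names to field lists, in which case the entry
#' for `name` is returned.
#'
#' @param path Path to the config file.
#' @param name Preset name used to select a per-preset section, if present.
#' @return Named list of overrides (possibly empty).
#' @export
read_preset_config <- function(path, name = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(name) && !is.null(cfg[[name]]) && is.list(cfg[[name]]))
    cfg <- cfg[[name]]
  lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
}

#' @export
print.condition_preset <- function(x, ...) {
  cat("<condition_preset> ", x$name, "\n", sep = "")
  cat(sprintf("  concentrates/axon (mean): %.2f\n", x$n_peaks_mean))
  cat(sprintf("  duration: mean %.2f min, gamma shape %g, bounds (%g, %g)\n",
              x$duration_mean_min, x$duration_shape,
              x$duration_bounds_min[1], x$duration_bounds_min[2]))
  cat(sprintf("  velocity during concentrates: %.4f +/- %.2f um/min\n",
              x$velocity_mean_um_per_min, x$velocity_sd))
  cat(sprintf("  crossing gated: %s\n", x$crossing_gated))
  invisible(x)
}

#' Draw concentrate durations for a preset
#'
#' Durations are truncated-gamma distributed; the sampler is calibrated so the
#' mean of the truncated distribution equals the preset's
#' `duration_mean_min`. Sampling uses the inverse CDF, so draws are exact.
#'
#' @param preset A `condition_preset`.
#' @param n Number of draws.
#' @return Numeric vector of durations in minutes, inside the preset bounds.
#' @export
sample_durations <- function(preset, n) {
  stopifnot(inherits(preset, "condition_preset"), n >= 0)
  shape <- preset$duration_shape
  rate <- shape / preset$duration_gamma_mean
  lo <- preset$duration_bounds_min[1]
  hi <- preset$duration_bounds_min[2]
  u <- stats::runif(n, stats::pgamma(lo, shape, rate),
                    stats::pgamma(hi, shape, rate))
  stats::qgamma(u, shape, rate)
}

## Shifted Poisson (minimum 1) concentrate count; the same count process is
## used for every preset because no between-treatment difference in peak
## number was observed.
sample_peak_count <- function(preset, n) {
  1L + stats::rpois(n, preset$n_peaks_mean - 1)
}
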