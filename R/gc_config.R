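#' Germinal-centre simulation configuration
#'
#' Parameters of the stochastic two-compartment (dark zone / light zone) GC
#' model. All times are in hours post GC onset; all rates are per hour. Event
#' probabilities per time step are derived from rates as
#' `p = 1 - exp(-rate * dt)`.
#'
#' The default dynamics were calibrated once so that a simulated GC reaction
#' reproduces the canonical kinetics — founder influx of 2 cells/h over the
#' first 4 days, expansion to a population of order 1000 cells within the
#' first week, subsequent decline over the 21-day reaction, and affinity
#' maturation completing during the second week — and are frozen at those
#' values.
#'
#' @param duration Length of the simulated reaction (hours).
#' @param dt Time step (hours).
#' @param founder_rate Founder-cell influx rate (cells/hour).
#' @param influx_window Influx is restricted to `t < influx_window` (hours).
#' @param initial_divisions Division budget granted to each founder on entry.
#' @param dz_division_rate Division rate of dark-zone cells with remaining
#'   budget (per hour).
#' @param mutation_prob Probability that a daughter cell mutates (one lattice
#'   step) at division.
#' @param sel_rate Base rate at which light-zone cells are positively selected
#'   (per hour); the per-cell probability is scaled by the cell's affinity
#'   relative to the current light-zone mean affinity (soft competition),
#'   by the Tfh crowding factor `1 / (1 + N_LZ / tfh_capacity)`, and by the
#'   antigen availability `exp(-t / antigen_tau)`, capped at 1.
#' @param tfh_capacity Number of light-zone cells at which T-follicular-helper
#'   help is half-saturated; limits GC size through competition for help.
#' @param antigen_tau Time constant (hours) of the exponential decay of
#'   antigen availability, which terminates the reaction; `Inf` disables it.
#' @param antigen_rise Optional time constant (hours) of an initial rise of
#'   antigen presentation (immune-complex deposition on follicular dendritic
#'   cells), delaying the onset of selection tests and of light-zone death by
#'   neglect; 0 (the default) disables it.
#' @param lz_max_dwell Light-zone dwell time (hours) after which unselected
#'   cells become apoptosis-prone.
#' @param lz_death_rate Death rate of unselected light-zone cells past
#'   `lz_max_dwell` (per hour).
#' @param p_recycle Probability that a selected cell recycles to the dark
#'   zone; otherwise it leaves the GC as an output cell.
#' @param d_min,d_max Bounds of the dynamic number of divisions granted on
#'   selection: `round(d_min + (d_max - d_min) * s)` where `s` in `[0,1]` is
#'   the normalised relative affinity (the Tfh help signal proxy).
#' @param affinity_dependent If `FALSE`, selection probability and division
#'   numbers are independent of affinity (control mimicking abolished
#'   selection).
#' @param shape_dim,gamma Shape-space dimension and affinity width; see
#'   [affinity_model()].
#' @param founder_dist Length-2 band of founder distances to the shape-space
#'   optimum.
#' @return An object of class `gc_config`.
#' @export
gc_config <- function(duration = 504, dt = 0.1,
                      founder_rate = 2, influx_window = 96,
                      initial_divisions = 6L,
                      dz_division_rate = 0.125, mutation_prob = 0.5,
                      sel_rate = 0.03, tfh_capacity = 300,
                      antigen_tau = 700, antigen_rise = 0,
                      lz_max_dwell = 6,
                      lz_death_rate = 0.5, p_recycle = 0.8,
                      d_min = 1, d_max = 6,
                      affinity_dependent = TRUE,
                      shape_dim = 4L, gamma = 2.8,
                      founder_dist = c(5, 7)) {
  cfg <- list(duration = duration, dt = dt, founder_rate = founder_rate,
              influx_window = influx_window,
              initial_divisions = as.integer(initial_divisions),
              dz_division_rate = dz_division_rate,
              mutation_prob = mutation_prob, sel_rate = sel_rate,
              tfh_capacity = tfh_capacity, antigen_tau = antigen_tau,
              antigen_rise = antigen_rise, lz_max_dwell = lz_max_dwell, lz_death_rate = lz_death_rate,
              p_recycle = p_recycle, d_min = d_min, d_max = d_max,
              affinity_dependent = isTRUE(affinity_dependent),
              shape_dim = as.integer(shape_dim), gamma = gamma,
              founder_dist = as.numeric(founder_dist))
  validate_gc_config(cfg)
  structure(cfg, class = "gc_config")
}

validate_gc_config <- function(cfg) {
  num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  rates <- c("founder_rate", "dz_division_rate", "sel_rate", "lz_death_rate")
  for (f in rates) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0) {
      stop("`", f, "` must be a non-negative rate", call. = FALSE)
    }
  }
  probs <- c("mutation_prob", "p_recycle")
  for (f in probs) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("`", f, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (!num1(cfg$dt) || cfg$dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (!num1(cfg$duration) || cfg$duration <= 0) {
    stop("`duration` must be > 0", call. = FALSE)
  }
  if (!num1(cfg$influx_window) || cfg$influx_window < 0) {
    stop("`influx_window` must be >= 0", call. = FALSE)
  }
  if (!num1(cfg$lz_max_dwell) || cfg$lz_max_dwell < 0) {
    stop("`lz_max_dwell` must be >= 0", call. = FALSE)
  }
  if (!num1(cfg$tfh_capacity) || cfg$tfh_capacity <= 0) {
    stop("`tfh_capacity` must be > 0", call. = FALSE)
  }
  if (length(cfg$antigen_tau) != 1L || is.na(cfg$antigen_tau) ||
      cfg$antigen_tau <= 0) {
    stop("`antigen_tau` must be > 0 (Inf allowed)", call. = FALSE)
  }
  if (!num1(cfg$antigen_rise) || cfg$antigen_rise < 0) {
    stop("`antigen_rise` must be >= 0", call. = FALSE)
  }
  if (cfg$initial_divisions < 0) {
    stop("`initial_divisions` must be >= 0", call. = FALSE)
  }
  if (!num1(cfg$d_min) || !num1(cfg$d_max) || cfg$d_min < 0 ||
      cfg$d_max < cfg$d_min) {
    stop("`d_min`/`d_max` must satisfy 0 <= d_min <= d_max", call. = FALSE)
  }
  if (!num1(cfg$gamma) || cfg$gamma <= 0) {
    stop("`gamma` must be > 0", call. = FALSE)
  }
  if (cfg$shape_dim < 1) stop("`shape_dim` must be >= 1", call. = FALSE)
  if (length(cfg$founder_dist) != 2L || cfg$founder_dist[1] < 0 ||
      cfg$founder_dist[2] < cfg$founder_dist[1]) {
    stop("`founder_dist` must be an increasing length-2 band", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.gc_config <- function(x, ...) {
  cat("<gc_config>\n")
  cat("  duration:", x$duration, "h, dt:", x$dt, "h\n")
  cat("  influx:", x$founder_rate, "cells/h for", x$influx_window,
      "h, founder burst:", x$initial_divisions, "divisions\n")
  cat("  DZ division rate:", x$dz_division_rate, "/h, mutation prob:",
      x$mutation_prob, "\n")
  cat("  LZ selection rate:", x$sel_rate, "/h, dwell:", x$lz_max_dwell,
      "h, death rate:", x$lz_death_rate, "/h\n")
  cat("  Tfh capacity:", x$tfh_capacity, "cells, antigen rise/decay:",
      x$antigen_rise, "/", x$antigen_tau, "h\n")
  cat("  recycle:", x$p_recycle, ", divisions on selection:", x$d_min, "-",
      x$d_max, "\n")
  cat("  shape space: d =", x$shape_dim, ", gamma =", x$gamma,
      ", founder distance:", paste(x$founder_dist, collapse = "-"), "\n")
  invisible(x)
}

# Affinity model implied by a config.
config_affinity_model <- function(config) {
  affinity_model(dim = config$shape_dim, gamma = config$gamma)
}
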