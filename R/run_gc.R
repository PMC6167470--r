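snapshot_to_cells <- function(snap) {
  tibble::tibble(
    cell_id = snap$cell_id, clone_id = snap$clone_id,
    lineage_id = snap$lineage_id, lineage_late = snap$lineage_late,
    color = snap$color, zone = snap$zone,
    divisions_left = snap$divisions_left, birth_time = snap$birth_time,
    stain_tried = snap$stain_tried, stain_count = snap$stain_count,
    affinity = snap$affinity
  )
}

protocol_to_list <- function(protocol) {
  list(mode = protocol$mode,
       probabilities = protocol$scheme$probabilities,
       t_start = protocol$t_start, f_stained = protocol$f_stained,
       tau_tamoxifen = protocol$tau_tamoxifen,
       tau_stainstop = protocol$tau_stainstop,
       dt_stain = protocol$dt_stain,
       allow_restain = protocol$allow_restain,
       lineage_t0 = protocol$lineage_t0)
}

state_cells_with_affinity <- function(state, config) {
  cells <- state$cells
  cells$affinity <- affinity(config_affinity_model(config), state$pos)
  cells
}

#' Simulate one germinal-centre reaction
#'
#' Runs the full stochastic GC reaction under a configuration and staining
#' protocol: founder influx, scheduled staining calls, lineage definition at
#' the protocol's `lineage_t0`, and the per-step division/selection dynamics.
#' A [dominance_record()] is emitted at every requested record time.
#'
#' Two engines implement identical event logic: `"cpp"` (compiled, used for
#' cohorts) and `"r"` (the reference implementation built from
#' [influx_founders()], [apply_staining()], [define_lineages()] and
#' [gc_step()]).
#'
#' @param config A [gc_config()].
#' @param protocol A [staining_protocol()].
#' @param seed Integer seed; the trajectory is reproducible from
#'   `(config, protocol, seed)`.
#' @param record_times Times (hours, multiples of `config$dt`) at which to
#'   record dominance statistics; must lie within `[0, duration]`.
#' @param engine `"cpp"` or `"r"`.
#' @param genealogy Track parent pointers (memory-hungry; small runs only).
#' @param kinetics_every If positive, record population size and mean
#'   affinity every that many hours (`"cpp"` engine).
#' @return A list of class `gc_run` with elements `records` (tibble, one row
#'   per record time), `cells` (final cell table including affinities),
#'   `state` (final engine state), `founder_log`, `counts`, `n_output`, and
#'   optionally `kinetics` and `genealogy`.
#' @export
run_gc <- function(config, protocol = staining_protocol("none"),
                   seed = 1L, record_times = config$duration,
                   engine = c("cpp", "r"), genealogy = FALSE,
                   kinetics_every = -1) {
  stopifnot(inherits(config, "gc_config"),
            inherits(protocol, "staining_protocol"))
  engine <- match.arg(engine)
  record_times <- sort(as.numeric(record_times))
  if (length(record_times) &&
      (min(record_times) < 0 || max(record_times) > config$duration + 1e-9)) {
    stop("record times must lie within [0, duration]", call. = FALSE)
  }
  snapped <- round(record_times / config$dt) * config$dt
  if (any(abs(snapped - record_times) > 1e-6)) {
    stop("record times must be multiples of dt", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (engine == "cpp") {
    res <- .cpp_run_gc(unclass(config), protocol_to_list(protocol),
                       snapped, kinetics_every, genealogy)
    records <- do.call(rbind, lapply(res$snapshots, function(s) {
      dominance_record(snapshot_to_cells(s), gc_id = seed, t = s$t,
                       scheme = protocol$scheme)
    }))
    st <- res$state
    out <- list(
      records = records,
      cells = snapshot_to_cells(st$snapshot),
      state = st,
      founder_log = tibble::as_tibble(res$founder_log),
      counts = st$counts,
      n_output = st$n_output,
      kinetics = tibble::as_tibble(res$kinetics)
    )
    if (genealogy) out$genealogy <- as.data.frame(res$genealogy)
  } else {
    out <- run_gc_r(config, protocol, snapped, genealogy)
  }
  out$seed <- as.integer(seed)
  class(out) <- "gc_run"
  out
}

# Reference-engine run loop; mirrors the compiled engine's event schedule.
run_gc_r <- function(config, protocol, record_times, genealogy = FALSE) {
  state <- init_gc(config)
  if (genealogy) {
    state$genealogy <- data.frame(cell_id = integer(), parent_id = integer(),
                                  birth_time = numeric(), clone_id = integer())
  }
  stain_times <- staining_call_times(protocol)
  nsteps <- round(config$duration / config$dt)
  records <- list()
  ri <- 1L
  shot_done <- FALSE
  for (step in 0:nsteps) {
    t <- step * config$dt
    state$time <- t
    while (ri <= length(record_times) &&
           abs(record_times[ri] - t) < config$dt / 2) {
      cells <- state_cells_with_affinity(state, config)
      records[[ri]] <- dominance_record(cells, gc_id = NA_integer_, t = t,
                                        scheme = protocol$scheme)
      ri <- ri + 1L
    }
    if (step == nsteps) break
    state <- influx_founders(state, config, config$dt, protocol)
    if (!state$lineages_defined && is.finite(protocol$lineage_t0) &&
        t >= protocol$lineage_t0 - 1e-9) {
      state <- define_lineages(state, t)
    }
    if (protocol$mode == "decay") {
      if (any(abs(stain_times - t) < config$dt / 2)) {
        state <- apply_staining(state, protocol, t)
      }
    } else if (protocol$mode == "one_shot" && !shot_done &&
               t >= protocol$t_start - 1e-9) {
      state <- apply_staining(state, protocol, t)
      shot_done <- TRUE
    }
    state <- gc_step(state, config)
  }
  list(
    records = if (length(records)) do.call(rbind, records) else NULL,
    cells = state_cells_with_affinity(state, config),
    state = state,
    founder_log = tibble::as_tibble(state$founder_log),
    counts = state$counts,
    n_output = state$n_output,
    genealogy = state$genealogy
  )
}

#' @export
print.gc_run <- function(x, ...) {
  cat("<gc_run> seed =", x$seed, "\n")
  print(x$records)
  invisible(x)
}

#' Simulate a cohort of germinal centres
#'
#' Runs `n_gc` independent GC reactions with per-GC seeds
#' `base_seed + gc index`, so cohorts are reproducible and individual GCs can
#' be re-simulated in isolation.
#'
#' @inheritParams run_gc
#' @param n_gc Number of GCs in the cohort.
#' @param base_seed Integer; GC `i` uses seed `base_seed + i`.
#' @return A `cohort_table`: a tibble with one [dominance_record()] row per
#'   `(gc_id, t)`, carrying the config, protocol and seed as attributes.
#' @export
run_cohort <- function(config, protocol, n_gc, record_times,
                       base_seed = 1L, engine = "cpp") {
  rows <- vector("list", n_gc)
  for (i in seq_len(n_gc)) {
    run <- run_gc(config, protocol, seed = base_seed + i,
                  record_times = record_times, engine = engine)
    rec <- run$records
    rec$gc_id <- i
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "protocol") <- protocol
  attr(out, "base_seed") <- as.integer(base_seed)
  class(out) <- c("cohort_table", class(out))
  out
}
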