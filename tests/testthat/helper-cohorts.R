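# Shared simulated cohorts, built once per test run. The heavier acceptance
# checks reuse these instead of re-simulating. All seeds are fixed.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, builder(), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# Standard tamoxifen-decay cohort: injection day 2, records at the end of
# staining (day 4) and at day 11 post injection (day 13).
std_decay_cohort <- function() {
  cached("std_decay", function() {
    cfg <- gc_config(duration = 312)
    pr <- staining_protocol("decay", t_start = 48)
    run_cohort(cfg, pr, n_gc = 500, record_times = c(96, 312),
               base_seed = 101L)
  })
}

# Decay staining at a given day post GC onset, record at day 11 post
# injection.
decay_day_cohort <- function(day, n_gc, base_seed) {
  t0 <- day * 24
  ta <- t0 + 264
  cfg <- gc_config(duration = ta)
  pr <- staining_protocol("decay", t_start = t0)
  run_cohort(cfg, pr, n_gc = n_gc, record_times = ta, base_seed = base_seed)
}

day1_cohort <- function() {
  cached("day1", function() decay_day_cohort(1, 300, 7101L))
}

day4_cohort <- function() {
  cached("day4", function() decay_day_cohort(4, 1000, 7104L))
}

founder_cohort <- function() {
  cached("founder", function() {
    cfg <- gc_config(duration = 312)
    pr <- staining_protocol("founder", scheme = builtin_schemes()$founder10,
                            lineage_t0 = NA)
    run_cohort(cfg, pr, n_gc = 120, record_times = c(48, 312),
               base_seed = 2101L)
  })
}

# Cohort-mean kinetics of the default 21-day reaction.
kinetics_cohort <- function() {
  cached("kinetics", function() {
    cfg <- gc_config()
    runs <- lapply(1:25, function(i) {
      run_gc(cfg, staining_protocol("none", lineage_t0 = NA), seed = 3100 + i,
             kinetics_every = 24, record_times = numeric(0))$kinetics
    })
    t <- runs[[1]]$t
    n <- rowMeans(sapply(runs, function(k) k$n))
    aff <- rowMeans(sapply(runs, function(k) {
      ifelse(is.na(k$mean_affinity), 0, k$mean_affinity)
    }))
    tibble::tibble(t = t, n = n, mean_affinity = aff)
  })
}

# Small reduced configuration for reference-engine tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(duration = 48, dt = 0.2, founder_rate = 0.5,
         initial_divisions = 3L),
    list(...)
  )
  do.call(gc_config, args)
}

# Hand-built single-cell state for contract tests on the reference engine.
single_cell_state <- function(config, zone = 0L, divisions_left = 2L,
                              color = 0L, pos = NULL) {
  state <- init_gc(config)
  state$cells <- data.frame(
    cell_id = 1L, clone_id = 1L, lineage_id = NA_integer_,
    lineage_late = FALSE, color = as.integer(color), zone = as.integer(zone),
    divisions_left = as.integer(divisions_left), birth_time = 0,
    lz_time = 0, help = 0, stain_tried = color > 0L,
    stain_count = as.integer(color > 0L)
  )
  if (is.null(pos)) pos <- rep(0L, config$shape_dim)
  state$pos <- matrix(as.integer(pos), nrow = 1)
  state$next_cell_id <- 2L
  state$next_clone_id <- 2L
  state$counts["influx"] <- 1L
  state$founder_log <- data.frame(clone_id = 1L, entry_time = 0, late = FALSE)
  state
}
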