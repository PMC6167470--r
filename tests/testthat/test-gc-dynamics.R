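test_that("a GC starts empty and trajectories are reproducible from the seed", {
  cfg <- tiny_config()
  expect_identical(nrow(init_gc(cfg, seed = 1)$cells), 0L)

  pr <- staining_protocol("decay", t_start = 12, tau_stainstop = 24,
                          lineage_t0 = 12)
  r1 <- run_gc(cfg, pr, seed = 5, record_times = c(24, 48))
  r2 <- run_gc(cfg, pr, seed = 5, record_times = c(24, 48))
  expect_identical(r1$records, r2$records)
  expect_identical(r1$cells, r2$cells)
  r3 <- run_gc(cfg, pr, seed = 6, record_times = c(24, 48))
  expect_false(identical(r1$cells, r3$cells))
})

test_that("founder influx is Poisson over the influx window and then stops", {
  cfg <- gc_config()
  # no influx after the 4-day window
  state <- init_gc(cfg, seed = 2)
  state$time <- 5 * 24
  expect_identical(nrow(influx_founders(state, cfg, dt = 1)$cells), 0L)
  # dt = 0 adds nothing
  s0 <- init_gc(cfg, seed = 2)
  expect_identical(nrow(influx_founders(s0, cfg, dt = 0)$cells), 0L)

  # mean total founders ~ rate * window = 192
  set.seed(31)
  totals <- replicate(20, {
    s <- init_gc(cfg)
    for (t in seq(0, 95, by = 1)) {
      s$time <- t
      s <- influx_founders(s, cfg, dt = 1)
    }
    nrow(s$cells)
  })
  expect_lt(abs(mean(totals) - 192), 3 * sqrt(192 / 20))
  expect_gt(length(unique(totals)), 1L)
})

test_that("division decrements the budget and daughters inherit identity", {
  cfg <- tiny_config(dz_division_rate = 1e6, mutation_prob = 0)
  state <- single_cell_state(cfg, zone = 0L, divisions_left = 2L, color = 3L)
  state <- gc_step(state, cfg)
  expect_identical(nrow(state$cells), 2L)
  expect_identical(state$cells$divisions_left, c(1L, 1L))
  expect_identical(state$cells$clone_id, c(1L, 1L))
  expect_identical(state$cells$color, c(3L, 3L))
  # without mutation the whole clone shares one shape-space position
  for (i in 1:10) state <- gc_step(state, cfg)
  expect_identical(nrow(unique(as.data.frame(state$pos))), 1L)
})

test_that("a dark-zone cell with exhausted budget transitions to the light zone", {
  cfg <- tiny_config(dz_division_rate = 0)
  state <- single_cell_state(cfg, zone = 0L, divisions_left = 0L)
  state <- gc_step(state, cfg)
  expect_identical(state$cells$zone, 1L)
})

test_that("selection favours high-affinity light-zone cells", {
  cfg <- tiny_config(sel_rate = 2, lz_death_rate = 0, antigen_tau = Inf)
  set.seed(55)
  picks <- replicate(300, {
    state <- single_cell_state(cfg, zone = 1L, divisions_left = 0L)
    # two LZ cells: one at the optimum, one far away
    state$cells <- rbind(state$cells, state$cells)
    state$cells$cell_id <- 1:2
    state$cells$clone_id <- 1:2
    state$pos <- rbind(c(0L, 0L, 0L, 0L), c(5L, 0L, 0L, 0L))
    state <- gc_step(state, cfg)
    cl <- state$cells
    # selected cells recycle to the DZ (zone 0) or leave as output
    c(near = !any(cl$cell_id == 1L & cl$zone == 1L),
      far = !any(cl$cell_id == 2L & cl$zone == 1L))
  })
  expect_gt(sum(picks["near", ]), 2 * sum(picks["far", ]))
})

test_that("cell bookkeeping is conserved exactly", {
  cfg <- tiny_config()
  for (eng in c("cpp", "r")) {
    run <- run_gc(cfg, staining_protocol("none", lineage_t0 = NA),
                  seed = 17, record_times = 48, engine = eng)
    cnt <- run$counts
    expect_equal(
      nrow(run$cells) + 0,
      unname(cnt["influx"] + cnt["divisions"] - cnt["deaths"] - cnt["output"]) + 0
    )
    # every live cell's clone appears in the founder log
    expect_true(all(run$cells$clone_id %in% run$founder_log$clone_id))
  }
})

test_that("with a single founder the GC stays clonally pure", {
  cfg <- tiny_config(founder_rate = 0)
  state <- single_cell_state(cfg, zone = 0L, divisions_left = 3L)
  set.seed(8)
  for (i in 1:100) {
    state <- gc_step(state, cfg)
    if (nrow(state$cells) > 0) {
      expect_equal(clonal_dominance(state$cells)$dominance, 1)
    }
  }
})

test_that("run_gc validates record times", {
  cfg <- tiny_config()
  pr <- staining_protocol("none", lineage_t0 = NA)
  expect_error(run_gc(cfg, pr, seed = 1, record_times = 1000), "duration")
  expect_error(run_gc(cfg, pr, seed = 1, record_times = 0.05),
               "multiples of dt")
})

test_that("compiled and reference engines agree statistically", {
  cfg <- tiny_config()
  pr <- staining_protocol("decay", t_start = 24, tau_stainstop = 24,
                          lineage_t0 = 24)
  stats <- lapply(c("cpp", "r"), function(eng) {
    out <- sapply(1:10, function(s) {
      r <- run_gc(cfg, pr, seed = 400 + s, record_times = 48, engine = eng)
      c(n = r$records$n, d = r$records$d, influx = unname(r$counts["influx"]))
    })
    rowMeans(out)
  })
  expect_lt(abs(stats[[1]]["n"] - stats[[2]]["n"]) /
              max(stats[[1]]["n"], 1), 0.35)
  expect_lt(abs(stats[[1]]["d"] - stats[[2]]["d"]), 0.08)
  expect_lt(abs(stats[[1]]["influx"] - stats[[2]]["influx"]), 8)
})
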