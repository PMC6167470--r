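test_that("every cell alive at t0 founds its own lineage", {
  set.seed(61)
  cfg <- tiny_config(founder_rate = 2)
  state <- init_gc(cfg)
  for (t in seq(0, 23, by = 1)) {
    state$time <- t
    state <- influx_founders(state, cfg, dt = 1)
  }
  state$time <- 24
  n <- nrow(state$cells)
  expect_gt(n, 5)
  state <- define_lineages(state, 24)
  expect_identical(anyDuplicated(state$cells$lineage_id), 0L)
  expect_true(all(!state$cells$lineage_late))
  expect_equal(lineage_dominance(state$cells)$dominance, 1 / n)
  expect_error(define_lineages(state, 24), "already")
  expect_error(define_lineages(init_gc(cfg), 5), "t0")
})

test_that("sibling cells alive at t0 found different lineages", {
  cfg <- tiny_config(dz_division_rate = 1e6, mutation_prob = 0)
  state <- single_cell_state(cfg, divisions_left = 1L)
  state <- gc_step(state, cfg)          # one division -> two siblings
  expect_identical(state$cells$clone_id, c(1L, 1L))
  state <- define_lineages(state, state$time)
  expect_identical(anyDuplicated(state$cells$lineage_id), 0L)
})

test_that("founders arriving after t0 carry late lineages", {
  set.seed(62)
  cfg <- gc_config(founder_rate = 50)
  state <- init_gc(cfg)
  state <- influx_founders(state, cfg, dt = 1)
  state$time <- 1
  state <- define_lineages(state, 1)
  n0 <- nrow(state$cells)
  state <- influx_founders(state, cfg, dt = 1)
  late <- state$cells$lineage_late
  expect_identical(sum(!late), n0)
  expect_gt(sum(late), 0)
  expect_true(all(!is.na(state$cells$lineage_id)))
  # lineage-bearing cell count: equality with N iff late founders included
  expect_lt(lineage_dominance(state$cells)$dominance * nrow(state$cells),
            nrow(state$cells) + 1)
})

test_that("lineages are genealogical subtrees rooted at t0 cells", {
  cfg <- tiny_config(founder_rate = 1)
  pr <- staining_protocol("one_shot", t_start = 24, f_stained = 0.5,
                          lineage_t0 = 24)
  run <- run_gc(cfg, pr, seed = 63, record_times = 48, genealogy = TRUE)
  gen <- run$genealogy
  cells <- run$cells
  parent_of <- setNames(gen$parent_id, gen$cell_id)
  birth_of <- setNames(gen$birth_time, gen$cell_id)
  clone_of <- setNames(gen$clone_id, gen$cell_id)
  # ancestor alive at t0 (last ancestor born at or before t0)
  t0_ancestor <- function(id) {
    while (!is.na(parent_of[[as.character(id)]]) &&
           birth_of[[as.character(id)]] > 24 + 1e-9) {
      id <- parent_of[[as.character(id)]]
    }
    if (birth_of[[as.character(id)]] > 24 + 1e-9) NA_integer_ else id
  }
  live <- cells[!is.na(cells$lineage_id) & !cells$lineage_late, ]
  expect_gt(nrow(live), 0)
  anc <- vapply(live$cell_id, t0_ancestor, integer(1))
  expect_true(all(!is.na(anc)))
  # same lineage <=> same t0 ancestor
  expect_identical(anyDuplicated(unique(data.frame(l = live$lineage_id,
                                                   a = anc))$l), 0L)
  split_anc <- split(anc, live$lineage_id)
  expect_true(all(vapply(split_anc, function(a) length(unique(a)) == 1L,
                         logical(1))))
  # clone heritability: every cell's clone equals its root founder's clone
  root_of <- function(id) {
    while (!is.na(parent_of[[as.character(id)]])) {
      id <- parent_of[[as.character(id)]]
    }
    id
  }
  idx <- sample(nrow(cells), min(40, nrow(cells)))
  for (i in idx) {
    expect_identical(cells$clone_id[i],
                     unname(clone_of[[as.character(root_of(cells$cell_id[i]))]]))
  }
})

test_that("genealogies export as parseable Newick trees", {
  cfg <- tiny_config(founder_rate = 0.3, duration = 24)
  run <- run_gc(cfg, staining_protocol("none", lineage_t0 = NA), seed = 64,
                record_times = 24, genealogy = TRUE)
  path <- withr::local_tempfile(fileext = ".nwk")
  nwk <- write_genealogy_newick(run$genealogy, path, cells = run$cells)
  expect_true(file.exists(path))
  expect_identical(length(nwk), sum(is.na(run$genealogy$parent_id)))
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  # total tips = total leaf cells (one leaf per cell timeline)
  n_tips <- sum(vapply(trees, function(tr) length(tr$tip.label), integer(1)))
  expect_identical(n_tips, nrow(run$genealogy))
})
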