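test_that("initial staining probability matches the decay-window calibration", {
  f <- 0.48
  p0 <- initial_staining_probability(f, 24, 48, 1)
  expect_equal(p0 * 1, f / (24 * (1 - exp(-2))), tolerance = 1e-12)

  # numerical-integration oracle: integrating the decaying hazard over the
  # active window recovers the target stained fraction
  integ <- stats::integrate(function(t) p0 * exp(-t / 24), 0, 48,
                            rel.tol = 1e-10)$value
  expect_equal(integ, f, tolerance = 1e-6)

  # trapezoidal cross-check of the closed form
  tt <- seq(0, 48, by = 0.001)
  trap <- sum(diff(tt) * (head(p0 * exp(-tt / 24), -1) +
                            tail(p0 * exp(-tt / 24), -1)) / 2)
  expect_equal(trap, f, tolerance = 1e-6)

  # infinite stop limit reduces to f / tau
  expect_equal(initial_staining_probability(f, 24, 1e9, 1), f / 24,
               tolerance = 1e-9)
  # linear in the target fraction
  expect_equal(initial_staining_probability(0.2, 24, 48, 1) * 2,
               initial_staining_probability(0.4, 24, 48, 1), tolerance = 1e-12)
  expect_error(initial_staining_probability(0.48, -1, 48, 1), "tau")
  expect_error(initial_staining_probability(1.2, 24, 48, 1), "f_stained")
})

test_that("per-call probability decays exponentially inside the window", {
  pr <- staining_protocol("decay", t_start = 48, f_stained = 0.48)
  p0dt <- pr$p_stain_0 * pr$dt_stain
  expect_equal(staining_probability_at(pr, 48), p0dt)
  expect_equal(staining_probability_at(pr, 48 + 24), p0dt * exp(-1))
  expect_identical(staining_probability_at(pr, 48 + 48), 0)
  expect_identical(staining_probability_at(pr, 10), 0)
  expect_error(staining_probability_at(staining_protocol("one_shot"), 50),
               "decay")
})

test_that("founder staining attributes the full-column probabilities", {
  set.seed(21)
  cfg <- gc_config(founder_rate = 1e4, shape_dim = 4)
  pr <- staining_protocol("founder", scheme = builtin_schemes()$founder10,
                          lineage_t0 = NA)
  state <- influx_founders(init_gc(cfg), cfg, dt = 1, protocol = pr)
  n <- nrow(state$cells)
  expect_gt(n, 9000)
  frac <- mean(state$cells$color > 0L)
  # stained founder fraction = 1 - P(black) = 0.89
  expect_equal(frac, 0.89, tolerance = 3 * sqrt(0.89 * 0.11 / n) + 0.005)
  # conditional colour frequencies approach the renormalised visible mass
  sc <- pr$scheme
  cond <- tabulate(state$cells$color[state$cells$color > 0L], 10) /
    sum(state$cells$color > 0L)
  expect_lt(max(abs(cond - sc$probabilities[-1] / sum(sc$probabilities[-1]))),
            0.02)
  expect_true(all(state$cells$stain_tried))
})

test_that("one-shot staining hits the target fraction once", {
  set.seed(22)
  cfg <- gc_config(founder_rate = 5e3)
  state <- influx_founders(init_gc(cfg), cfg, dt = 1)
  pr <- staining_protocol("one_shot", t_start = 0, f_stained = 0.3)
  state <- apply_staining(state, pr, t = 0)
  n <- nrow(state$cells)
  expect_equal(mean(state$cells$color > 0L), 0.3,
               tolerance = 3 * sqrt(0.3 * 0.7 / n))
})

test_that("decay staining accumulates to the calibrated fraction on a static population", {
  set.seed(23)
  cfg <- gc_config(founder_rate = 5e3)
  state <- influx_founders(init_gc(cfg), cfg, dt = 1)
  pr <- staining_protocol("decay", t_start = 0, f_stained = 0.48)
  for (t in 0:47) {
    state <- apply_staining(state, pr, t = t)
  }
  n <- nrow(state$cells)
  # left-endpoint discretisation of the calibrated hazard
  expected <- sum(pr$p_stain_0 * exp(-(0:47) / 24))
  expect_equal(expected, 0.49, tolerance = 0.001)
  expect_equal(mean(state$cells$color > 0L), expected, tolerance = 0.02)
  # with restaining disabled no cell is stained twice
  expect_true(all(state$cells$stain_count <= 1L))
})

test_that("colours are immutable without restaining, mutable with it", {
  set.seed(24)
  cfg <- gc_config(founder_rate = 2e3)
  state <- influx_founders(init_gc(cfg), cfg, dt = 1)
  pr <- staining_protocol("one_shot", t_start = 0, f_stained = 0.9)
  state <- apply_staining(state, pr, t = 0)
  col1 <- state$cells$color
  state2 <- apply_staining(state, pr, t = 0)
  expect_identical(state2$cells$color[col1 > 0L], col1[col1 > 0L])
  expect_true(all(state2$cells$stain_count <= 1L))

  # restaining redraws visible colours (never back to black)
  prr <- staining_protocol("decay", t_start = 0, f_stained = 0.48,
                           allow_restain = TRUE)
  s3 <- state
  for (t in 0:10) s3 <- apply_staining(s3, prr, t = t)
  expect_true(any(s3$cells$stain_count > 1L))
  expect_true(all(s3$cells$color[col1 > 0L] > 0L))
})
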