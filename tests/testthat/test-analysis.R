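test_that("Pearson correlation and Fisher interval behave as expected", {
  x <- 1:20
  r <- pearson_fisher_ci(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_identical(r$n, 20L)

  # exact zero correlation: interval is +- tanh(z_{0.975} / sqrt(n - 3))
  set.seed(71)
  x <- 1:103
  y <- residuals(lm(rnorm(103) ~ x))
  rc <- pearson_fisher_ci(x, y)
  expect_equal(rc$r, 0, tolerance = 1e-12)
  expect_equal(rc$ci_high, tanh(qnorm(0.975) / sqrt(100)), tolerance = 1e-9)
  expect_equal(rc$ci_low, -rc$ci_high, tolerance = 1e-9)
  expect_equal(rc$ci_high, 0.194, tolerance = 0.005)

  # independent samples: small correlation at n = 1e4
  set.seed(72)
  ri <- pearson_fisher_ci(runif(1e4), runif(1e4))
  expect_lt(abs(ri$r), 0.05)

  expect_error(pearson_fisher_ci(rep(1, 10), 1:10), "zero variance")
  r3 <- pearson_fisher_ci(c(1, 2, 4), c(1, 3, 2))
  expect_true(is.na(r3$ci_low))
})

test_that("the Fisher interval matches a bootstrap interval", {
  set.seed(73)
  n <- 500
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  fi <- pearson_fisher_ci(x, y)
  boots <- replicate(1500, {
    i <- sample.int(n, replace = TRUE)
    cor(x[i], y[i])
  })
  bci <- quantile(boots, c(0.025, 0.975))
  expect_lt(abs(fi$ci_low - bci[1]), 0.03)
  expect_lt(abs(fi$ci_high - bci[2]), 0.03)
})

# A synthetic cohort table: lineage dominance correlated with PDD through a
# latent takeover variable, colour density increasing with it.
synthetic_cohort <- function(n_gc = 120, t_rec = 312, seed = 74) {
  set.seed(seed)
  z <- runif(n_gc)
  d <- pmin(1, pmax(0, 0.35 + 0.3 * z + rnorm(n_gc, 0, 0.08)))
  cmax <- pmin(1, pmax(0.05, z + rnorm(n_gc, 0, 0.1))) * d
  l <- pmin(1, pmax(0.02, z + rnorm(n_gc, 0, 0.15)))
  col <- sample(c("YFP", "RFP"), n_gc, replace = TRUE)
  ids <- seq_len(n_gc)
  tibble::tibble(
    gc_id = ids, t = rep(t_rec, n_gc), n = rep(500L, n_gc),
    f = pmin(1, l + 0.1), dominant_clone = rep(1L, n_gc),
    l = l, dominant_lineage = ids, l_late = l,
    c = cmax, dominant_color = col,
    d = d, pdd = cmax * d, mean_affinity = rep(0.5, n_gc)
  )
}

test_that("cohort correlations respect the threshold filter", {
  coh <- synthetic_cohort()
  r_all <- correlate_dominance(coh, "L", "PDD", threshold = 0, t = 312)
  expect_identical(r_all$n, 120L)
  expect_gt(r_all$r, 0.5)
  # a metric against itself is perfectly correlated
  expect_equal(correlate_dominance(coh, "L", "L", t = 312)$r, 1)
  # the number of surviving GCs is non-increasing in the threshold
  ns <- vapply(seq(0, 0.9, by = 0.1), function(T) {
    correlate_dominance(coh, "L", "PDD", threshold = T, t = 312)$n
  }, integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(correlate_dominance(coh, "X", "PDD", t = 312), "unknown metric")
  expect_error(correlate_dominance(coh, "L", "PDD", t = 999), "no records")
})

test_that("kept-vs-deleted histograms and distances behave at the edges", {
  coh <- synthetic_cohort()
  # identical L values on both sides of the split -> zero distance
  coh2 <- coh
  coh2$l <- rep(c(0.2, 0.4, 0.6), length.out = nrow(coh2))
  coh2$d <- rep(c(0.3, 0.3, 0.3, 0.6, 0.6, 0.6), length.out = nrow(coh2))
  kv0 <- kept_vs_deleted(coh2, 0.45, t = 312, n_perm = 0)
  expect_equal(kv0$distance, 0)
  # empty deleted side -> distance unset
  coh3 <- coh
  coh3$d <- 0.9
  kv1 <- kept_vs_deleted(coh3, 0.1, t = 312, n_perm = 0)
  expect_identical(kv1$n_deleted, 0L)
  expect_true(is.na(kv1$distance))
  # distances lie in [0, 1] and bins sum to 1
  kv <- kept_vs_deleted(coh, 0.5, t = 312, n_perm = 50)
  expect_true(kv$distance >= 0 && kv$distance <= 1)
  expect_equal(sum(kv$kept), 1)
  expect_equal(sum(kv$deleted), 1)
  expect_lt(kv$distance_adj, kv$distance)
})

test_that("switch fractions compare dominant colours across snapshots", {
  coh <- synthetic_cohort()
  early <- coh
  early$t <- 48
  both <- rbind(early, coh)
  expect_equal(switch_fraction(both, 48, 48), 0)
  sf <- switch_fraction(both, 48, 312)
  expect_true(sf >= 0 && sf <= 1)
  # GCs without a dominant colour are excluded
  both2 <- both
  both2$dominant_color[both2$t == 48] <- NA
  expect_true(is.na(switch_fraction(both2, 48, 312)))
})

test_that("maximum lineage dominance reduces to the single-GC value", {
  coh <- synthetic_cohort(n_gc = 1)
  expect_identical(max_lineage_dominance(coh, 312), coh$l[1])
})
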