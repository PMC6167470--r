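#' Pearson correlation with a Fisher-transform confidence interval
#'
#' Computes the sample Pearson product-moment correlation and an approximate
#' `(1 - alpha)` confidence interval via the Fisher z-transformation:
#' `tanh(atanh(r) +/- z_{1-alpha/2} / sqrt(n - 3))`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return A list of class `correlation_result` with `r`, `ci_low`, `ci_high`
#'   and `n`. For `n < 4` the interval is `NA` (it needs `n - 3 > 0`).
#' @export
pearson_fisher_ci <- function(x, y, alpha = 0.05) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- cor(x, y)
  if (n >= 4L && abs(r) < 1) {
    z <- atanh(r)
    hw <- qnorm(1 - alpha / 2) / sqrt(n - 3)
    ci <- tanh(z + c(-hw, hw))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f [%.3f, %.3f], n = %d\n",
              x$r, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

# Map user-facing metric names onto cohort-table columns.
metric_column <- function(metric) {
  key <- tolower(as.character(metric))
  map <- c(f = "f", l = "l", l_late = "l_late", c = "c", d = "d",
           pdd = "pdd", n = "n")
  if (!key %in% names(map)) {
    stop("unknown metric `", metric,
         "`; use one of F, L, L_late, C, D, PDD, N", call. = FALSE)
  }
  map[[key]]
}

cohort_at_time <- function(cohort, t) {
  sub <- cohort[abs(cohort$t - t) < 1e-6, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("cohort has no records at t = ", t, " h", call. = FALSE)
  }
  sub
}

#' Correlate two dominance metrics across a cohort
#'
#' Restricts the cohort to one analysis time, applies the staining threshold
#' (keeping GCs with colour density strictly above `threshold`), and
#' correlates the chosen metrics across the surviving GCs.
#'
#' @param cohort A [run_cohort()] table.
#' @param x_metric,y_metric Metric names: `"F"` (clonal dominance), `"L"`
#'   (lineage dominance, late founders excluded), `"L_late"` (late founders
#'   included), `"C"` (colour dominance), `"D"` (colour density), `"PDD"`.
#' @param threshold Staining threshold in `[0, 1]`.
#' @param t Analysis time (hours); defaults to the latest recorded time.
#' @return A `correlation_result` (see [pearson_fisher_ci()]); if fewer than
#'   4 GCs survive the threshold the interval is `NA`.
#' @export
correlate_dominance <- function(cohort, x_metric, y_metric, threshold = 0,
                                t = max(cohort$t)) {
  sub <- cohort_at_time(cohort, t)
  sub <- sub[!is.na(sub$d) & sub$d > threshold, , drop = FALSE]
  xc <- metric_column(x_metric)
  yc <- metric_column(y_metric)
  if (nrow(sub) < 2L) {
    return(structure(list(r = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n = nrow(sub)),
                     class = "correlation_result"))
  }
  pearson_fisher_ci(sub[[xc]], sub[[yc]])
}

#' Maximum lineage dominance across a cohort
#'
#' @param cohort A [run_cohort()] table.
#' @param t Analysis time (hours); defaults to the latest recorded time.
#' @param include_late_founders Use the late-founder-inclusive lineage
#'   dominance column.
#' @return The maximum lineage dominance across GCs at `t`.
#' @export
max_lineage_dominance <- function(cohort, t = max(cohort$t),
                                  include_late_founders = FALSE) {
  sub <- cohort_at_time(cohort, t)
  col <- if (include_late_founders) "l_late" else "l"
  max(sub[[col]], na.rm = TRUE)
}

#' Lineage-dominance distributions of kept versus deleted GCs
#'
#' Splits a cohort at the staining threshold (colour density above versus at
#' or below `threshold`) and compares the binned lineage-dominance
#' distributions of the two subsets by total-variation distance.
#'
#' The empirical total-variation distance between two finite samples is biased
#' upwards, and the bias grows as either sample shrinks. Because the split
#' sizes depend on the threshold, raw distances are not comparable across
#' thresholds; `distance_adj` subtracts the permutation null (the mean
#' distance obtained when GCs are reassigned to the two sides at random,
#' preserving the group sizes) and is the statistic to minimise when searching
#' for the threshold at which both subsets are drawn from the same
#' lineage-dominance distribution.
#'
#' @param cohort A [run_cohort()] table.
#' @param threshold Staining threshold in `[0, 1]`.
#' @param t Analysis time (hours).
#' @param bin_width Histogram bin width on `[0, 1]`.
#' @param n_perm Number of permutations for the null distance (0 disables).
#' @return List with `kept` and `deleted` (bin proportions), `breaks`,
#'   `n_kept`, `n_deleted`, `distance` (raw total variation, `NA` if either
#'   side is empty), `distance_null` (mean permuted distance) and
#'   `distance_adj` (`distance - distance_null`).
#' @export
kept_vs_deleted <- function(cohort, threshold, t = max(cohort$t),
                            bin_width = 0.05, n_perm = 200) {
  sub <- cohort_at_time(cohort, t)
  sub <- sub[!is.na(sub$l), , drop = FALSE]
  breaks <- seq(0, 1, by = bin_width)
  keep <- sub$d > threshold
  binprop <- function(x) {
    if (length(x) == 0L) return(rep(NA_real_, length(breaks) - 1L))
    h <- graphics::hist(pmin(x, 1 - 1e-12), breaks = breaks, plot = FALSE)
    h$counts / length(x)
  }
  tv <- function(a, b) 0.5 * sum(abs(binprop(a) - binprop(b)))
  pk <- binprop(sub$l[keep])
  pd <- binprop(sub$l[!keep])
  both <- any(keep) && any(!keep)
  dist <- if (both) 0.5 * sum(abs(pk - pd)) else NA_real_
  null <- NA_real_
  if (both && n_perm > 0) {
    nk <- sum(keep)
    null <- mean(replicate(n_perm, {
      i <- sample.int(nrow(sub), nk)
      tv(sub$l[i], sub$l[-i])
    }))
  }
  list(kept = pk, deleted = pd, breaks = breaks,
       n_kept = sum(keep), n_deleted = sum(!keep), distance = dist,
       distance_null = null, distance_adj = dist - null)
}

#' Fraction of GCs whose dominant colour switched
#'
#' Among the GCs whose colour density at the analysis time is above
#' `threshold` and that have a dominant colour at both times, the fraction
#' whose dominant colour differs between the staining-time and analysis-time
#' snapshots.
#'
#' @param cohort A [run_cohort()] table holding records at both times.
#' @param t_stain,t_analysis Record times (hours).
#' @param threshold Staining threshold applied at `t_analysis`.
#' @return Fraction in `[0, 1]`, or `NA` if no GC qualifies.
#' @export
switch_fraction <- function(cohort, t_stain, t_analysis, threshold = 0) {
  s1 <- cohort_at_time(cohort, t_stain)
  s2 <- cohort_at_time(cohort, t_analysis)
  m <- merge(s1[, c("gc_id", "dominant_color")],
             s2[, c("gc_id", "dominant_color", "d")],
             by = "gc_id", suffixes = c("_stain", "_analysis"))
  m <- m[m$d > threshold & !is.na(m$dominant_color_stain) &
           !is.na(m$dominant_color_analysis), , drop = FALSE]
  if (nrow(m) == 0L) return(NA_real_)
  mean(m$dominant_color_stain != m$dominant_color_analysis)
}

sweep_correlations <- function(cohort, thresholds, t) {
  do.call(rbind, lapply(thresholds, function(T) {
    r1 <- correlate_dominance(cohort, "L", "PDD", threshold = T, t = t)
    r2 <- correlate_dominance(cohort, "L_late", "PDD", threshold = T, t = t)
    tibble::tibble(threshold = T,
                   r = r1$r, ci_low = r1$ci_low, ci_high = r1$ci_high,
                   n = r1$n, r_late = r2$r)
  }))
}

#' Sweep the staining-initiation day
#'
#' For each staining day, runs a cohort with the protocol template re-timed to
#' that day (lineages defined at injection) and correlates lineage dominance
#' against PDD at a fixed day post staining, for each staining threshold.
#' `r_late` is the same correlation with late-founder lineages included.
#'
#' @param config A [gc_config()]; the run is truncated at the analysis time.
#' @param protocol_template A [staining_protocol()] whose timing is
#'   overridden per staining day.
#' @param days Staining-initiation days post GC onset.
#' @param n_gc Cohort size per day.
#' @param thresholds Staining thresholds to evaluate.
#' @param analysis_day Analysis day post staining (default 11).
#' @param base_seed Seed; day `k` uses `base_seed + k * 100000`.
#' @return Tibble with one row per (day, threshold).
#' @export
staining_time_sweep <- function(config, protocol_template, days = 1:4,
                                n_gc = 200, thresholds = c(0, 0.2, 0.4),
                                analysis_day = 11, base_seed = 1L) {
  out <- lapply(days, function(day) {
    t0 <- day * 24
    t_an <- t0 + analysis_day * 24
    proto <- unclass(protocol_template)
    proto$t_start <- t0
    proto$lineage_t0 <- t0
    class(proto) <- "staining_protocol"
    cfg <- config
    cfg$duration <- t_an
    cohort <- run_cohort(cfg, proto, n_gc, record_times = t_an,
                         base_seed = base_seed + day * 100000L)
    cbind(tibble::tibble(staining_day = day),
          sweep_correlations(cohort, thresholds, t_an))
  })
  do.call(rbind, out)
}

#' Sweep the target stained fraction
#'
#' For each stained fraction, runs a cohort with the protocol template's
#' `f_stained` replaced and correlates lineage dominance against PDD at a
#' fixed day post staining, per staining threshold.
#'
#' @inheritParams staining_time_sweep
#' @param fractions Target stained fractions in (0, 1].
#' @return Tibble with one row per (fraction, threshold).
#' @export
stained_fraction_sweep <- function(config, protocol_template,
                                   fractions = seq(0.1, 0.9, by = 0.2),
                                   n_gc = 200, thresholds = c(0, 0.4),
                                   analysis_day = 11, base_seed = 1L) {
  t_an <- protocol_template$t_start + analysis_day * 24
  cfg <- config
  cfg$duration <- t_an
  out <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    proto <- unclass(protocol_template)
    proto$f_stained <- f
    if (proto$mode == "decay") {
      proto$p_stain_0 <- initial_staining_probability(
        f, proto$tau_tamoxifen, proto$tau_stainstop, proto$dt_stain)
    }
    class(proto) <- "staining_protocol"
    cohort <- run_cohort(cfg, proto, n_gc, record_times = t_an,
                         base_seed = base_seed + i * 100000L)
    cbind(tibble::tibble(f_stained = f),
          sweep_correlations(cohort, thresholds, t_an))
  })
  do.call(rbind, out)
}

#' Compare colour schemes
#'
#' Runs one cohort per scheme under a shared protocol template and reports
#' the lineage-dominance/PDD correlation per staining threshold.
#'
#' @inheritParams staining_time_sweep
#' @param schemes Named list of [color_scheme()] objects.
#' @return Tibble with one row per (scheme, threshold).
#' @export
compare_schemes <- function(config, protocol_template,
                            schemes = builtin_schemes()[c("confetti4",
                                                          "tamoxifen10",
                                                          "equal10")],
                            n_gc = 200, thresholds = c(0, 0.4),
                            analysis_day = 11, base_seed = 1L) {
  t_an <- protocol_template$t_start + analysis_day * 24
  cfg <- config
  cfg$duration <- t_an
  out <- lapply(seq_along(schemes), function(i) {
    proto <- unclass(protocol_template)
    proto$scheme <- schemes[[i]]
    class(proto) <- "staining_protocol"
    cohort <- run_cohort(cfg, proto, n_gc, record_times = t_an,
                         base_seed = base_seed + i * 100000L)
    cbind(tibble::tibble(scheme = names(schemes)[i]),
          sweep_correlations(cohort, thresholds, t_an))
  })
  do.call(rbind, out)
}
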