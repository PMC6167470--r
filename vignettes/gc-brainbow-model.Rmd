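---
title: "Simulating multi-colour brainbow staining of germinal-centre B cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-colour brainbow staining of germinal-centre B cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcbrainbow)
```

## The question the package addresses

Brainbow/Confetti staining heritably tags B cells with one of 4 (one
recombined allele) or 10 (two alleles) colours. In a germinal centre (GC),
colours are inherited through division, so the spread of one colour traces
the expansion of the cells that carried it. Experimentalists read the
*colour dominance* of a GC — the largest fraction of its B cells in a single
visible colour — as a proxy for *clonal* or *lineage dominance*, which cannot
be observed directly without sequencing. Whether that proxy is faithful
depends on when staining happens, how long tamoxifen stays active, how many
cells are stained, and which colour scheme is used.

`gcbrainbow` simulates the whole measurement chain — GC reaction, staining
protocol, lineage bookkeeping, dominance statistics, cohort-level
correlation analyses — so those design choices can be evaluated in silico.

## The GC model

The simulator is a stochastic, individual-cell, well-mixed two-compartment
(dark zone / light zone) model. It deliberately drops the spatial detail of
full lattice GC models: every analysed output depends only on the
clone/lineage/colour composition of the population, not on cell positions.

* **Founder influx.** New founder B cells enter at 2 cells/h during the
  first 4 days (about 190 founders per GC). Each founder receives a fresh
  clone id and an initial budget of 6 divisions, so founder clones have
  already expanded by day 2.
* **Shape space.** Each cell carries a position on a 4-dimensional integer
  lattice; affinity for the antigen is `exp(-dist^2 / gamma^2)` with
  `gamma = 2.8` lattice units, 1 at the optimum. Somatic hypermutation
  displaces a daughter cell by one lattice unit in one random dimension
  with probability 0.5 per division. Founders start at distance 5–7 from
  the optimum: low affinity, but reachable within about half a dozen
  mutations.
* **Dark zone.** Cells with remaining division budget divide at rate
  0.125/h; both daughters inherit clone, lineage and colour and mutate
  independently. A cell that exhausts its budget moves to the light zone.
* **Light zone.** A cell is positively selected at base rate 0.03/h scaled
  by (i) its affinity relative to the current light-zone mean (soft
  competition for antigen and T-follicular-helper help), (ii) a crowding
  factor `1 / (1 + N_LZ / 300)` (limited Tfh help), and (iii) antigen
  availability `exp(-t / 700 h)` (consumption terminates the reaction).
  All rates convert to per-step probabilities as `p = 1 - exp(-rate * dt)`
  with `dt = 0.1` h. A selected cell receives a normalised help signal
  `s = a / (a + a_mean)` and a new division budget
  `round(1 + 5 s)` (dynamic number of divisions: more help, more
  divisions); it recycles to the dark zone with probability 0.8, otherwise
  it leaves as an output cell. Unselected cells die at 0.5/h once they have
  waited longer than 6 h.
* An optional antigen-presentation ramp (`antigen_rise`) can delay the
  onset of selection testing and of death by neglect; it is off by default.

These rate constants were calibrated once, against the canonical kinetics
only — the population grows to a peak of a few thousand cells around day
4–5, declines over the 21-day reaction, and cohort-mean affinity rises
steeply between days 4 and 13 — and then frozen. With `affinity_dependent =
FALSE` the selection machinery runs with all affinity dependence removed, a
control mimicking a reaction without functional selection: clonal dominance
then stays near its day-2 level.

## Staining model

A colour scheme is an ordered palette with attribution probabilities;
`black` encodes failed/absent recombination. The built-in schemes are the
measured single-allele (4-colour), double-allele tamoxifen (10-colour) and
constitutive founder columns, plus an idealised `equal10` scheme. Printed
probability columns do not sum exactly to one (the tamoxifen column sums to
0.989), so scheme construction renormalises; the target stained fraction
keeps the printed value 0.48 = 1 − 0.52.

Three protocols are implemented:

* **Founder staining** — each founder draws from the full scheme (black
  possible) when it enters the GC, i.e. cells arrive pre-stained.
* **One-shot staining** — a single pass at `t_start` stains each cell with
  probability `f_stained`.
* **Decaying tamoxifen activity** — staining calls every `dt_stain = 1` h
  with per-call probability decaying as `exp(-(t - t_start)/tau)`,
  `tau = 24` h, switched off after `tau_stainstop = 48` h. The initial
  probability is calibrated so the accumulated staining equals
  `f_stained`:
  `p0 * dt_stain = f / (tau * (1 - exp(-tau_stainstop / tau)))`.

Two numerical choices matter here. First, the calibration neglects double
staining; if each unstained cell were tested independently with the raw
per-call probability, compounding would leave only ~39% stained instead of
the calibrated 48%. A staining call therefore recombines an expected
fraction `p(t)` of the whole population, which for unstained cells means an
effective probability `p(t) * N / N_unstained` (capped at 1). Second,
tamoxifen exposure is systemic: founders that enter the GC during the
staining window arrive pre-stained with the cumulative hazard already
spent. Together these keep the cohort-mean stained fraction at the end of
staining at the calibrated value (0.49 after left-endpoint discretisation
of the decaying hazard) even though founder influx continues during
staining. With `allow_restain = TRUE`, already-stained cells additionally
redraw a visible colour with the raw per-call probability — a recombined
allele can recombine again, but never revert to unstained.

## Lineages

All cells alive at the lineage definition time `t0` (by default the
injection time) found one lineage each; two siblings found different
lineages even though they share a clone. Founders entering after `t0`
always receive fresh lineage ids flagged *late*; whether those count is an
analysis-time choice (`include_late_founders`), and cohort records carry
both variants (`l`, `l_late`). Output and dead cells drop out of every
denominator.

## Dominance statistics

For a snapshot of `N` cells: clonal dominance `F` (largest clone fraction),
lineage dominance `L` (largest lineage fraction; unassigned cells count in
`N` only), colour dominance `C` (largest single non-black colour fraction),
colour density `D` (any non-black colour), and `PDD = C * D`, the in-silico
proxy for the in-vivo normalised density score. The staining threshold
keeps a GC iff `D > T`, strictly. Ties break deterministically (lowest id;
first colour in scheme order). Each statistic is checked in the test suite
against an independently written brute-force recount on thousands of fuzzed
toy populations.

## Cohort analyses

Correlations are Pearson coefficients with 95% intervals from the Fisher
transformation, `tanh(atanh(r) ± z / sqrt(n - 3))`. The sweeps re-run
cohorts across staining days, stained fractions or colour schemes and
correlate `L` against `PDD` at day 11 post staining per threshold.

For the kept-versus-deleted comparison the lineage-dominance distributions
above and below the threshold are binned at width 0.05 and compared by
total-variation distance. The raw empirical distance between two finite
samples is biased upwards, the more so the smaller either side, and the
split sizes change with the threshold; distances are therefore compared
after subtracting a permutation null (`distance_adj`), the mean distance
when GCs are randomly reassigned to two groups of the same sizes.

## Reproducibility and problem sizes

Every run is reproducible from `(config, protocol, seed)`; cohorts give GC
`i` the seed `base_seed + i`, so any single GC can be re-simulated in
isolation. The compiled engine and the pure-R reference engine implement
the same event schedule; the R engine is the readable specification (and is
what the unit tests exercise cell by cell), the compiled engine makes
thousand-GC cohorts affordable (~0.15 s per 13-day GC), and the two are
compared statistically in the tests.

The analyses in the test suite use scaled cohorts: 500 GCs for the standard
day-2 tamoxifen cohort, 300–1000 for the lineage-definition-time analyses
(the maximum of lineage dominance across a cohort is an extreme-value
statistic, so full 1000-GC cohorts are used where that maximum is the
quantity of interest), 120–200 per condition for the ordering checks.
`scripts/acceptance.R` re-runs the headline analyses at 500–1000 GCs per
condition.

## What the generator does and does not emulate

The generator reproduces founder influx, expansion, affinity-driven
selection with recycling, colour inheritance and the staining protocols —
the ingredients the dominance analyses depend on. It does not model space
(chemokine fields, cell motility), explicit Tfh or FDC agents,
sequence-level mutation, antibody feedback, or post-GC differentiation.
Passing tests therefore validate the bookkeeping and the statistical
machinery, and show that the qualitative design conclusions (thresholds
help, earlier one-shot staining is better, fewer stained cells with a
threshold are more informative, near-equal colour probabilities beat skewed
ones) emerge from lineage/selection structure alone; they do not certify
quantitative agreement with any particular in-vivo system.

Two known limitations of the non-spatial reduction surfaced in our own
analyses. First, relative-affinity selection compounds the head start of
the earliest founders, so only a minority of a day-12 GC descends from
founders that entered after day 1; analyses that hinge on late founders
carrying stained-but-unmonitored cells are weaker here than in a full
spatial model, and the staining-day dependence of the lineage/PDD
correlation under decaying tamoxifen is flat-to-decreasing rather than
peaked at day 2–3. Second, the end-of-staining fraction lands at 0.49
(left-endpoint discretisation), which nudges the threshold at which kept
and deleted GCs agree best towards 45–50%; the two are statistically
indistinguishable in cohorts of several hundred GCs.

## A worked example

```{r example, eval = FALSE}
cfg <- gc_config(duration = 312)                 # 13 days
pr  <- staining_protocol("decay", t_start = 48)  # tamoxifen at day 2
coh <- run_cohort(cfg, pr, n_gc = 200,
                  record_times = c(96, 312), base_seed = 1)

# end-of-staining colour density ~ 0.49
mean(coh$d[coh$t == 96])

# the staining threshold rescues the lineage/PDD correlation
correlate_dominance(coh, "L", "PDD", threshold = 0,   t = 312)
correlate_dominance(coh, "L", "PDD", threshold = 0.4, t = 312)

# how often the dominant colour switched during selection
switch_fraction(coh, 96, 312, threshold = 0.4)
```
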