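# gcbrainbow

Stochastic simulation of germinal-centre (GC) B-cell reactions with
multi-colour brainbow/Confetti staining, for researchers who use heritable
colour labelling to read clonal evolution out of GCs and need to know when
that readout can be trusted.

## The problem

Cre-driven recombination of the brainbow allele tags a B cell with one of 4
colours (one allele) or 10 colour combinations (both alleles); the colour is
inherited by all progeny. In a GC — where B cells divide, hypermutate and are
selected for antibody affinity — the **colour dominance**

&nbsp;&nbsp;&nbsp;&nbsp;*C(t) = max<sub>i∈colours</sub> C<sub>i</sub>(t) / N(t)*

is used as a stand-in for the **clonal dominance**
*F(t) = max<sub>i∈clones</sub> F<sub>i</sub>(t) / N(t)* (founder staining) or
the **lineage dominance**
*L(t) = max<sub>i∈lineages</sub> L<sub>i</sub>(t) / N(t)* (tamoxifen-induced
staining, where every cell alive at the injection time founds a lineage).
Together with the colour density *D(t)* (fraction of cells with any visible
colour) and the product *PDD = C·D*, and a staining threshold *T* that keeps
a GC only if *D(t) > T*, these statistics decide how a staining experiment
should be designed: when to inject tamoxifen, how large a fraction of cells
to stain, which threshold to impose, and whether 10 colours beat 4.

`gcbrainbow` implements the full chain in one package:

* an individual-cell dark-zone/light-zone GC model (founder influx, division
  bursts, shape-space hypermutation with Gaussian affinity
  `exp(-dist²/Γ²)`, affinity-dependent selection with a dynamic number of
  divisions, recycling, output, apoptosis), with a compiled cohort engine
  and an equivalent pure-R reference engine;
* staining protocols: founder staining, one-shot staining, and tamoxifen
  with exponentially decaying recombination probability calibrated via
  `p₀·Δt = f / (τ·(1 − e^(−τ_stop/τ)))`, with optional restaining;
* clone and lineage tracking (late founders flagged), Newick genealogy
  export;
* the dominance statistics above plus cohort analyses: Pearson correlations
  with Fisher-transform confidence intervals, staining-day /
  stained-fraction / colour-scheme sweeps, kept-vs-deleted threshold
  comparison, dominant-colour switch fractions.

## A worked example

Tamoxifen-decay staining at day 2 post GC onset with the measured 10-colour
probabilities, 200 simulated GCs, analysed at day 11 post injection:

```r
library(gcbrainbow)

cfg <- gc_config(duration = 312)                 # 13 days, hours throughout
pr  <- staining_protocol("decay", t_start = 48)  # tamoxifen at day 2
coh <- run_cohort(cfg, pr, n_gc = 200, record_times = c(96, 312),
                  base_seed = 1)

mean(coh$d[coh$t == 96])
#> [1] 0.49
correlate_dominance(coh, "L", "PDD", threshold = 0,   t = 312)
#> r = 0.094 [-0.045, 0.230], n = 200
correlate_dominance(coh, "L", "PDD", threshold = 0.4, t = 312)
#> r = 0.477 [0.332, 0.600], n = 130
switch_fraction(coh, 96, 312, threshold = 0.4)
#> [1] 0.5769231
```

Reading the numbers: the cohort-mean stained fraction at the end of the
48-hour staining window matches the 48–49% calibration target; without a
staining threshold, lineage dominance and PDD are nearly uncorrelated
(r ≈ 0.09) because GCs dominated by unstained lineages hide their dominance,
while keeping only GCs stained above 40% raises the correlation to ≈ 0.48;
and 58% of the GCs kept for analysis changed their dominant colour between
the end of staining and day 11, showing that colours track selection rather
than the initial attribution lottery.

Per-GC records (`run_cohort` returns one row per GC and record time) carry
`n, f, l, l_late, c, d, pdd`, the dominant clone/lineage/colour, and mean
affinity; `write_cohort_csv()` round-trips them as tidy CSV.

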