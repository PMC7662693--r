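# jellyom

Carbon and nitrogen budgets of microbial jellyfish-detritus degradation.

## What this is for

Collapsing jellyfish blooms release detrital organic matter (jelly-OM) —
protein-rich, with a molar C:N around 4.6 — that coastal bacteria degrade
within a day or two. Quantifying such an episode is mostly careful unit
bookkeeping over a handful of standard measurements, and this package gives
that bookkeeping one tested implementation, for people running leaching or
batch-culture degradation experiments (or re-analysing published ones):

* **Leaching**: tidy concentration time series → release rates in
  µmol (mg DM)⁻¹ d⁻¹, TOC sums, DIN partitioning, LMW fractions, and
  bloom-scenario predictions (`release_rate()`, `toc_rate()`,
  `din_partition()`, `predict_enrichment()`, `bloom_load()`).
* **Batch-culture carbon budget**: exponential-window detection, community
  growth rate µ, and per-flask budgets where
  BCD = −d(DOC)/dt · 12.011, BP = dN/dt · 19.8 fg C cell⁻¹,
  BR = BCD − BP, BGE = 100·BP/BCD, aggregated replicate-first with pooled
  t-tests against controls (`detect_exponential_window()`,
  `carbon_budget()`, `aggregate_budgets()`).
* **Amino-acid / nutrient pools**: DCAA = TDHAA − DFAA, mol% profiles,
  signed net rates per growth phase (`dcaa()`, `mol_percent()`,
  `net_rate()`).
* **Proteome turnover**: PSMs per residue (PSMs/AA) as a label-free
  abundance proxy, pool totals and consumption percentages, floor-filtered
  relative-abundance tables (`psm_per_aa()`, `pool_total()`,
  `relative_abundance_table()`).
* **Community abundance**: reads-per-million normalisation
  (RPM = 10⁶·(reads/length)/Σ(reads/length)), MAG relative abundance, FISH
  absolute abundance and dilution-aware fold change (`rpm()`,
  `mag_relative_abundance()`, `fold_change()`).
* **Synthetic data with known truth**: a batch-culture generator whose
  carbon coupling *is* the budget identity, so estimators must recover the
  programmed µ and BGE exactly at zero noise (`simulate_batch_culture()`
  and friends), plus a pipeline runner (`run_pipeline()`) and CLI
  (`exec/jellyom`).

## Worked example

```r
library(jellyom)

# DOC leaching from 250 mg dry mass in 1 L, sampled over 24 h
ser <- ts_record(c(0, 6, 12, 24), c(0, 27.5, 55, 110), analyte = "DOC")
rr  <- release_rate(ser, leaching_setup(dm_mass_mg = 250, volume_L = 1))
rr
#> DOC release: 0.44 umol (mg DM)^-1 d^-1 [ols]
predict_enrichment(rr, 100)   # a 100 mg/L bloom-decay amendment
#> [1] 44                      # umol DOC per litre
```

So a decaying bloom delivering 100 mg dry mass per litre is predicted to
release 44 µmol DOC L⁻¹ — the size of the substrate pulse the microbial
community actually sees.

```r
# carbon budget of a (noiseless synthetic) amended flask
p   <- sim_params(seed = 1, noise_cv = 0)
b   <- simulate_batch_culture(p, "I")
j1  <- b[b$replicate == "J1", ]
win <- detect_exponential_window(j1[j1$analyte == "cells", ])
cb  <- carbon_budget(j1[j1$analyte == "DOC", ], j1[j1$analyte == "cells", ], win)
#> mu = 0.090 1/h  BCD = 8.82  BP = 5.74  BR = 3.09 ugC/L/h  BGE = 65.0%
```

The detected window is 0–32 h; the recovered growth rate (0.09 h⁻¹) and
growth efficiency (65%) are exactly the simulator's programmed values —
the zero-noise closure the test suite asserts to 1e-9. A BGE of 65% means
about two-thirds of the consumed carbon went into biomass rather than CO₂.

`worked_example_report()` recomputes the package's full set of desk-checks
(enrichments 44/13/11/0.6 µmol L⁻¹, C:N 4.6, TOC 0.86 µmol mg⁻¹ d⁻¹ ≈ 1% of
dry mass per day, DIN 0.01, >97% protein-pool consumption, bloom load
100 g DM m⁻³ and 2 g C m⁻³) and flags, rather than resolves, the one known
internal discrepancy (the NH₄⁺ share of DIN: 63.4% computed vs 70% as often
quoted).

## CLI

```sh
exec/jellyom simulate --seed 1 --outdir data/      # tidy CSVs + ground truth
exec/jellyom pipeline --seed 1 --outdir run1/      # full report bundle
exec/jellyom worked-example                        # printed check table
```
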