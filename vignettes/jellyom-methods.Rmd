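---
title: "Methods: carbon and nitrogen bookkeeping of jellyfish-detritus degradation"
author: "jellyom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon and nitrogen bookkeeping of jellyfish-detritus degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellyom)
```

## The problem

When a bloom of a scyphozoan jellyfish such as *Aurelia aurita* collapses,
its detrital biomass (jelly-OM) leaches a large pulse of protein-rich,
low-C:N dissolved organic matter into coastal surface water. A small guild of
opportunistic copiotrophs (*Pseudoalteromonas*, *Alteromonas*, *Vibrio*)
degrades that pulse within a day or two. Quantifying the episode requires no
exotic statistics, but a lot of disciplined unit bookkeeping: per-dry-mass
release rates, a batch-culture carbon budget, amino-acid pool accounting,
label-free proteome turnover, and length-normalised read-count abundances.
`jellyom` packages that bookkeeping with tests, so each derived number has
one authoritative implementation.

## Models and estimators

### Leaching rates

A leaching experiment suspends a known dry mass $m$ (mg) in a volume $V$ (L)
and samples concentrations $C(t)$ (umol L$^{-1}$) over 24 h. The release
rate is

$$ r = \frac{dC}{dt} \cdot \frac{24\,V}{m} \quad
   [\mathrm{\mu mol\,(mg\,DM)^{-1}\,d^{-1}}]. $$

`release_rate()` estimates $dC/dt$ either from the first and last samples
(`endpoint`) or by least squares (`ols`, the default). Leaching saturates
within a day, so the OLS fit uses the pre-plateau segment: the contiguous
*prefix* of at least three timepoints maximising $R^2$, ties broken toward
the longer prefix. On perfectly linear data every prefix ties and the full
series is used, which makes the two methods coincide exactly there (a tested
invariant). The two estimators answer slightly different questions on a
saturating curve -- the initial rate $kC_\infty$ (OLS on the rising limb)
versus the 24-h average (endpoint). Both are kept because published
per-day rates do not say which convention they follow; every report records
the method used.

Negative rates (adsorption, consumption) are reported with sign and flagged,
never clamped. Release tables are checked for internal consistency:
DIN = NH$_4^+$ + NO$_3^-$ + NO$_2^-$ and DON = TDN $-$ DIN within 5%.

One deliberate non-resolution: the DIN species rates 0.0069 + 0.0034 +
0.00058 give an NH$_4^+$ share of 63.4%, while 70% is the figure usually
quoted alongside them. `worked_example_report()` computes the share and
marks the row `flagged` instead of choosing a side.

### Growth window and carbon budget

The exponential window of a cell-count series is the contiguous window of at
least three points, ending at or before the abundance maximum, that
maximises the $R^2$ of $\ln N$ vs $t$; ties go to the longer window, then
the earlier start. Its slope is the community growth rate $\mu$ (h$^{-1}$).

Over a window the budget is

* BCD $= -\,\frac{d\,\mathrm{DOC}}{dt} \times 12.011$ (ug C L$^{-1}$ h$^{-1}$),
* BP $= \frac{dN}{dt} \times 19.8\ \mathrm{fg\,C\,cell^{-1}}$,
* BR $=$ BCD $-$ BP (exactly), and
* BGE $= 100\,$BP/BCD (exactly, when BCD $> 0$).

Assumptions worth stating: DOC drawdown is attributed entirely to
heterotrophic consumption (no abiotic loss), and BP is a *net* production --
no correction for grazing or viral lysis. BGE above 100% is possible with
noisy replicates and is flagged, not truncated.

Two design choices deserve emphasis:

1. **Aggregation order.** Treatment summaries are means of per-replicate
   values; in particular the treatment BGE is the mean of replicate-level
   BP/BCD ratios, *not* the ratio of mean BP to mean BCD. The two differ
   materially with heterogeneous replicates, and published tables that report
   mean BGE alongside mean BP and BCD are only reproducible under the
   replicate-then-average convention. The alternative remains available as a
   diagnostic by dividing the summary means.
2. **Budget window vs fit window.** With measurement noise, the max-$R^2$
   window is frequently the minimal three points, which leaves too little
   DOC drawdown relative to noise for a stable BCD. The pipeline therefore
   uses the best-fit window only for $\mu$ and computes the budget over the
   full growth window (first sample to the abundance peak) -- the
   "$\Delta$DOC during exponential growth" convention.

Between-arm comparisons use a pooled-variance two-sided t-test
(homoscedasticity assumed; Welch available behind `var_equal = FALSE`), with
the conventions p = 1 for zero variance and equal means and p = 0 (flagged)
for zero variance and unequal means.

### Amino-acid and nutrient pools

DCAA is defined by difference, DCAA = TDHAA $-$ DFAA, so the identity
DCAA + DFAA = TDHAA holds by construction; noise-driven negative DCAA is
flagged and excluded from mol% profiles. Mol% normalises a species profile
to 100 (Glu/Gln and Asp/Asn are pooled to Glx/Asx first, via an editable
map). Net rates are signed slopes (OLS default, endpoint optional) over
user-supplied phase windows; the defaults -- exponential to the abundance
peak (32 h), stationary to 46 h, senescent to 84 h -- are configuration, not
inference, because phase boundaries in batch cultures are conventionally set
by inspection.

### Proteome turnover

PSMs/AA -- peptide spectrum matches divided by residue count -- is the
label-free abundance proxy. Pool totals sum PSMs/AA over all proteins
detected at a timepoint; consumption percentages are invariant to common
rescaling of all PSMs, so they survive instrument-level intensity drift.
Proteins absent at a timepoint count as zero (not missing), otherwise
consumption percentages would be undefined. The >1% reporting floor folds
minor proteins into an "others" row but never enters pool totals.
Identification (FDR control, two-peptide rules) is upstream of this package;
the input table is assumed already filtered.

### Community abundance

RPM $= 10^6 (n_i/\ell_i) / \sum_j (n_j/\ell_j)$ for mapped reads $n$ and
feature length $\ell$; sums to exactly $10^6$ per sample, is invariant to
sequencing depth, and inversely responsive to length. Lengths are taken in
bp; the choice is immaterial as long as it is uniform. MAG relative
abundance renormalises per-MAG RPM to percentages. Fold changes of
FISH-identified populations divide the final absolute abundance by the
initial abundance *after* inoculum dilution; the dilution factor defaults to
10 (a 9:1 aged-seawater:inoculum setup) and is explicit configuration,
because published fold changes are not reconstructible without it.

## The synthetic world

`simulate_batch_culture()` states, rather than fits, a world:

| parameter | default | why |
|---|---|---|
| $\mu$ | 0.09 h$^{-1}$ | fast opportunist growth, ~2 d$^{-1}$ |
| inoculum | 5.7e5 cells mL$^{-1}$ | typical coastal abundance after 1:10 dilution |
| BGE | 0.65 | high efficiency on protein-rich substrate |
| cell carbon | 19.8 fg C cell$^{-1}$ | standard bacterioplankton conversion |
| DOC amendment | 44 umol L$^{-1}$ | 0.44 umol mg$^{-1}$ d$^{-1}$ x 100 mg L$^{-1}$ |
| DOC background | 70 umol L$^{-1}$ | oligotrophic coastal surface water |
| TDHAA amendment | 11 umol L$^{-1}$, 55% free | leachate composition |
| NH$_4^+$, PO$_4^{3-}$ slopes | 0.29, 0.016 umol L$^{-1}$ h$^{-1}$ | remineralisation by-products |
| abundance peak | 32 h, then 0.04 h$^{-1}$ decay | batch-culture crash |
| noise | 5% lognormal CV | counting/chromatography precision |

The carbon coupling is the budget identity itself: at zero noise
$\mathrm{DOC}(t) = \mathrm{DOC}_0 - (N(t)-N_0)\,f_C/(\mathrm{BGE} \cdot
12.011)$. Because DOC is then an affine function of $N$, *any* window and
either slope method return the programmed BGE exactly -- the closure the
recovery tests rely on (relative error $< 10^{-9}$ is asserted). A
mechanistic Monod formulation would be more realistic but would break this
exactness and turn closure tests into tolerance haggling; the identity
coupling keeps them honest. Sampling grids default to 0/6/12/24/32 h
(experiment I) and 0/12/32/46/56/80/84 h (experiment II), triplicate flasks
per arm.

What the generator does **not** emulate: grazing and viral mortality beyond
a phenomenological post-peak decay; leucine/tryptophan mass balance against
the DFAA pool (they are separate series with the documented shapes -- a
transient bump peaking at 3.9 umol L$^{-1}$ and a late 3.8 nmol L$^{-1}$
h$^{-1}$ rise); DOC release from lysed cells; bottle effects. A green
recovery test therefore establishes that the estimators invert the stated
generative model at realistic noise, not that they are unbiased on real
flasks.

`simulate_psm_table()` uses two decay classes -- 98% of the initial pool at
0.1185 h$^{-1}$ and degradation-resistant actin-/titin-like proteins (2%)
at 0.0419 h$^{-1}$. The two rates were solved analytically (two equations,
two unknowns, fixed 98/2 split) so a 203.45 PSMs/AA pool declines to 5.56
at 32 h and 0.13 at 84 h; they were fixed before any test was run and are
not tuned. `simulate_read_counts()` draws one multinomial with probabilities
proportional to proportion x length, the sampling model under which RPM is
unbiased for the profile.

## Numerical choices and degenerate inputs

* Atomic masses are fixed (C 12.011, N 14.007, P 30.974). Published
  dual-unit tables often disagree with umol x mass at the third digit
  because they convert unrounded source data; comparisons against printed
  ug values are made at two significant figures.
* Display rounding (2 significant figures for rates, 1 decimal for ratios)
  is applied only at report level; all internal arithmetic is full
  precision.
* $R^2$ ties in window selection break toward longer windows, then earlier
  starts, with a 1e-9 tie tolerance.
* A fitted BCD with magnitude below 1e-9 ug C L$^{-1}$ h$^{-1}$ is treated
  as zero (slopes of constant series carry ~1e-17 numeric noise) and the
  budget flagged `no_net_consumption`, with BGE undefined.
* Cell counts at or below the detection limit are dropped as missing, not
  zeroed; constant or non-increasing series raise a no-growth error rather
  than returning a degenerate window.
* Recovery tests compare noisy-data estimates against the *same estimator on
  noiseless data* where the estimand is estimator-dependent (leach rates on
  saturating curves, DFAA net rates on exponential decays).

## Stochastic recovery, as tested

Over 100 seeds, pooling the six amended flasks of both experiments per seed
(the replicate structure the summaries are designed around): the median
relative error of $\hat\mu$ at 5% lognormal noise is about 1%, asserted
< 10%; the median absolute BGE error at 2% concentration noise is about
0.2 / 1.8 / 4.0 percentage points for programmed BGE 20 / 65 / 90%,
asserted < 5. The BGE criterion uses 2% noise because BCD is a small slope
on a large background -- at 5% noise the per-flask BCD error alone exceeds
the 5-point budget for high BGE, which is an honest property of the design,
not of the estimator.

## Known limitations

* Endpoint and OLS rates differ systematically on saturating or
  exponential-shaped series; the package reports which was used but cannot
  decide for you.
* The BGE of a control arm with near-zero drawdown is numerically fragile;
  flags, not magic, are the mitigation.
* Fold-change results are only as meaningful as the supplied dilution
  factor.
* The pipeline treats phase windows as global per run, not per flask.
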