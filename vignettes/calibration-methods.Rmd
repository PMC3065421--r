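---
title: "Information-based calibration of hybridization protocols: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-based calibration of hybridization protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybcal)
```

## The calibration problem

Oligonucleotide probes are designed for an idealized effective reaction
temperature, but buffer additives and surface chemistry shift the physical
temperature at which an array actually performs best.  Hybridizing below a
probe's optimum increases cross-hybridization (non-target binding, lost
specificity); hybridizing above it weakens target binding (lost signal and
sensitivity).  `hybcal` implements a calibration strategy built on a single
idea: among candidate protocols, prefer the one under which a comparison of
two typical biological samples yields the most *information* about which
sample was measured.

## The per-gene model and its logistic dual

For each gene $g$ the log-intensity $x_g$ is modelled, conditional on the
binary sample label $y$, as Gaussian with class means $\mu_{g,0}$,
$\mu_{g,1}$ and a shared standard deviation $\sigma_g$ — exactly the
assumptions of a per-gene linear ANOVA model.  Maximum-likelihood
estimation uses the pooled variance with denominator $N$ (the ML form, not
the unbiased $N-2$ form), floored at `sigma_floor` so constant genes stay
finite.  Two equivalent experiment-level scores follow:

* the **Gaussian log-likelihood** $\sum_{g,n} \ln \mathcal N(x_{g,n};
  \mu_{g,y_n}, \sigma_g)$ (`loglik_linear()`), and
* the **naive-Bayes log-likelihood** $\sum_{g,n} \ln P(y_n \mid x_{g,n})$
  (`loglik_nb()`), where by Bayes' rule the posterior is the logistic
  function $P(y=1\mid x) = \mathrm{logit}^{-1}(w_g x + b_g)$ with
  $w_g = (\mu_{g,1}-\mu_{g,0})/\sigma_g^2$ and
  $b_g = (\mu_{g,0}^2-\mu_{g,1}^2)/(2\sigma_g^2) + \ln
  \tfrac{P(y=1)}{P(y=0)}$.

The label-independent normalization constant of the naive-Bayes likelihood
is omitted; it cancels in every protocol comparison, which is the only use
of the score.  Posteriors are clipped to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-6}$ so that log scores remain finite under
perfect separation.  The dual-representation identity (logistic form
$\equiv$ Bayes' rule on the two Gaussians) is verified to $10^{-10}$ over
random models in the test suite.

## Model-free diagnostics by cross-testing

Because the likelihood scores inherit the Gaussian assumptions, protocol
rankings are cross-checked with assumption-free measures computed by
*N*-fold cross-testing (`cross_test()`).  The folding unit is the slide:
both channel observations of a slide enter the same fold, so a slide can
never help predict itself.  With leave-one-out folding every slide serves
exactly once as the independent test sample.  From the held-out posteriors
the package computes

* the **generalization accuracy** (`generalization_accuracy()`): percent
  of correct label predictions over genes and test observations.  A
  posterior of exactly $0.5$ predicts label 0 — a deterministic tie rule
  under which an uninformative balanced experiment scores exactly 50;
* **ROC curves and mean AUC** (`roc_summary()`): per-gene threshold
  enumeration with tied scores contributing diagonal segments (trapezoid
  AUC equals the rank statistic with ties counted half).  The summary
  curve is the vertical average of per-gene true-positive rates on a fixed
  101-point false-positive-rate grid, forced through $(0,0)$ and $(1,1)$.
  Vertical averaging was chosen over pooling all gene scores because
  per-gene score scales are not comparable;
* the **mutual-information bit rate** (`mutual_information()`): per gene
  the mean of $\log_2 P(y_n\mid x_{g,n}) / P(y_n)$ over held-out
  observations, averaged over genes, with label priors taken from the
  training folds.  The estimate is deliberately not clipped at zero.

Agreement between the model-based and model-free rankings indicates that
the modelling assumptions hold to a good approximation; `score_protocol()`
reports all measures side by side.

### Known bias of the bit-rate estimate

The held-out plug-in bit rate is a finite-sample estimate.  For genes
carrying no information, the ML fit of a training fold still produces a
non-zero weight $w_g$, and evaluating such a noise-fitted classifier on
independent data has strictly negative expected log-score ratio.  The
package therefore reports slightly negative bit rates for null genes —
empirically about $-3/N$ bits per gene at $N$ observations.  This is a
generalization penalty, not a defect of the data, and it affects all
protocols equally, so protocol *rankings* are unaffected.  Interpreting
the absolute bit rate of weakly informative data, however, requires
keeping this bias in mind; label-shuffling experiments recover it rather
than zero.

## Sample-independence: stratified subsampling and rank distributions

A calibration is only useful if its optimum does not depend on the two
samples chosen for it.  `stratify_genes()` splits genes into Z/L/M/H
strata (zero/low/medium/high differential expression) by quartiles of the
standardized mean difference $d_g = |\mu_{g,1}-\mu_{g,0}|/\sigma_g$
computed on the pooled data; quartiles guarantee non-empty strata because
no threshold for the four groups is canonical, and ties are broken by
gene id for determinism.  `rank_protocols()` then draws, by default, 100
gene subsets with random Z/L/M/H compositions (flat Dirichlet weights,
subset size one quarter of the genes), scores *every* protocol on the
*same* subset (a paired comparison; unpaired subsets would drown the
signal in subset noise), and ranks protocols by `loglik_nb`.  Exact score
ties — which occur in practice only for byte-identical inputs — are
broken uniformly at random so that indistinguishable protocols share
rank 1 evenly.

The resulting protocol-by-rank frequency matrix is doubly stochastic.
`recommend_protocol()` calls every protocol whose rank-1 share reaches
half the best share a joint winner and recommends the winner with the
highest temperature, because when two protocols on opposite sides of the
optimum tie, the higher temperature minimizes cross-hybridization
potential.  The recommendation is flagged stable when the joint winners
are adjacent on the temperature-sorted grid supplied by the caller; a
50/50 split between non-neighbouring temperatures is a symptom, not a
result.  `diagnose_instability()` quantifies this with the Shannon
entropy of the rank-1 distribution (default flag above 1.5 bits) — an
uncertain rank distribution indicates that the calibration samples are
unsuitable, typically because differential expression is strongly
unidirectional.

## The synthetic-data generators

Two generators provide controlled ground truth.

**Gaussian group datasets** (`gaussian_group_dataset()`) emulate the
composition of a calibration comparison directly in log2 space: four
equal strata of 100 genes with planted effects 0/0.5/1/2 log2 units,
observation noise sd 0.3, and 6 dye-swap slides (12 channel
observations).  These defaults mirror a typical two-colour experiment:
per-gene effects between "none" and "fourfold", replicate noise of a
well-run platform, and the smallest replicate count at which
cross-testing is meaningful.  `apply_crosshyb_offset()` adds a constant
0.3 log2 offset to the truly lower-expressed channel of a random half of
the weakly expressed genes (bottom half of a stratum by baseline) —
constant across slides, because physical cross-hybridization from a given
non-target does not depend on measurement noise; for non-differential
genes the contaminated channel is a random but fixed choice.
`run_crosshyb_study()` scores nine contamination conditions relative to
the uncontaminated baseline.  Contaminating only non-expressed genes
*inflates* the likelihood (fabricated differential signal), while
contamination across all strata *degrades* it, because the likelihood
lost on truly differential genes outweighs the spurious gain — the
property that makes the measure safe for samples without a strong
regulation bias.

**The Langmuir chip simulator** (`make_chip()`, `simulate_arrays()`)
generates physically motivated intensities.  Each probe-target duplex has
enthalpy $\Delta H \sim U(-350, -250)$ kJ/mol and an entropy chosen so
that its melting midpoint (occupancy $\tfrac12$ at the reference
concentration $c_\mathrm{ref} = 10^{-3}$) falls uniformly in 52–60 °C;
the binding constant $K(T) = \exp(-\Delta G_T / RT)$ with
$\Delta G_T = \Delta H - T\Delta S$ then decreases in temperature, and
the bound fraction follows the Langmuir isotherm
$\theta = cK/(1+cK)$.  Ten percent of probes receive 1–12 non-targets
with enthalpies scaled towards zero by $U(0.5, 0.8)$, melting midpoints
3–12 K lower, and additive amplitude scales $\alpha \sim U(0.02, 0.2)$ —
cross-duplexes bind more weakly and melt earlier than their probes'
targets, so their contribution fades as temperature rises.
Cross-hybridization is additive (no competitive depletion); competition
would add parameters without changing the qualitative optimum.

Channel intensities are $A\,\theta(\mathrm{target}) + A\sum_j \alpha_j
\theta(\mathrm{nontarget}_j) + \mathrm{background}$ with amplitude
$A = 10^4$ and background 50, i.e. roughly 2.3 decades of usable dynamic
range, typical of two-colour scanners.  Base concentrations are
log-normal with median $3\times10^{-5}$ (3% of $c_\mathrm{ref}$) and
log-sd 1.5, placing the median probe at a few percent occupancy at its
design temperature and the weak tail near background — these two choices
are what give the simulator its interior temperature optimum: below it,
saturation and cross-hybridization compress and contaminate the
differential signal; above it, weak genes sink into the background.  The
resulting performance loss is steeper above the optimum than below it,
matching the behaviour of well-designed arrays.  Measurement noise is
multiplicative log-normal (sd 0.15 on log2 intensities) plus a small
additive component (sd 0.2 × background).

A calibration run measures aliquots of *one* RNA pool at every candidate
temperature.  `draw_chip_sample()` therefore draws the biological sample
(strata by largest-remainder rounding of the scenario fractions,
regulation directions under the scenario's down/up bias, concentrations)
once, and `run_temperature_study()` measures that same sample at every
grid temperature; the measurement noise is additionally shared across
temperatures within a scenario row (common random numbers), the standard
variance-reduction device for simulated paired comparisons.  The five
default scenario rows (`calibration_scenarios()`) vary the Z/L/M/H fractions
from 30/20/20/30 to 55/10/30/5 percent with a 2:1 down- vs up-regulation
bias among differential genes; a consistent rank-1 temperature across
all rows demonstrates sample-independence of the optimum.

What the generators do *not* emulate: sequence-level thermodynamics
(nearest-neighbour $\Delta G$ prediction), spatial slide artefacts, dye-
specific bias (the dye-swap metadata is carried but both dyes are
simulated identically), scanner saturation at the top end, and
correlated noise between genes.  Passing tests on this synthetic data
therefore demonstrate the internal consistency and the qualitative
mechanisms of the measures, not their quantitative behaviour on any
particular laboratory platform.

## Downstream impact analysis

`dye_swap_log_ratios()` forms per-slide, orientation-corrected log ratios
(sample-1 channel minus sample-0 channel, regardless of dye).
`de_test()` applies a per-gene one-sample two-sided t test of the mean
ratio against zero with slides − 1 degrees of freedom — the exact
reduction of a balanced two-channel dye-swap ANOVA with slide as block,
so no mixed-model machinery is needed.  Zero-variance genes follow a
documented degenerate rule (p = 0 for a non-zero mean, p = 1 otherwise).
P-values become Benjamini–Hochberg FDRs (`bh_fdr()`, delegating to
`stats::p.adjust`), and `count_significant()` counts genes with
q strictly below the cutoff (default 0.01).  `compare_protocol_de()`
splits the optimal protocol's significant genes into retained and lost
sets and summarizes their absolute fold changes — degraded protocols
lose predominantly the subtle fold changes.  `fisher_enrichment()`
reports the two-sided Fisher exact p-value (minimum-likelihood
convention, via `stats::fisher.test`) together with the *sample* odds
ratio $ad/bc$, which is the quantity a reader of a 2×2 count table
computes; note `fisher.test`'s own estimate is the conditional MLE and
differs.  Whether a one- or two-sided test is used was left open by the
calibration literature; two-sided is the conservative choice and both
pass the usual significance bound on the worked example.

## Numerical choices and degenerate inputs

* `sigma_floor = 1e-6` and posterior clip `eps = 1e-6` prevent infinite
  log scores; both only engage for exactly constant or perfectly
  separated genes.
* Location/scale normalization uses the population (1/n) standard
  deviation, consistent with ML fitting elsewhere; a zero-variance
  column is an error naming the column.
* Raw intensities are clipped at a floor (default 1.0) before log2, so
  zero or negative background-subtracted values cannot produce −∞.
* Largest-remainder rounding converts fractional stratum compositions
  into exact integer counts.
* All generators use R's global RNG: `set.seed()` makes every study
  reproducible end to end.

## Worked problem sizes

The studies shipped in the test-suite and acceptance script run at desk
scale, chosen so each completes in seconds while keeping the monitored
rates stable across seeds: contamination and sensitivity studies over 50
independent datasets of 400 (respectively 200) genes; the temperature
study on a 2,000-gene chip across six temperatures and five scenario
rows; rank stability over 100 stratified subsamples of three 400-gene
protocols.  Full-size chips (12,000 genes) run in well under a minute
each if higher resolution is wanted.

## Limitations

* The bit-rate estimator's negative null bias, discussed above.
* Quartile stratification is relative: in a sample with little true
  differential expression the "H" stratum still exists and simply holds
  the least-null genes.
* The Langmuir simulator's absolute scales (amplitude, background,
  concentration units) are dimensionless conventions; only their ratios
  matter, and none is calibrated to a specific scanner.
* Exact-tie randomization in `rank_protocols()` means rank distributions
  of genuinely identical protocols are exchangeable but not identical
  across runs with different seeds.
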