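# hybcal — quantitative calibration of microarray hybridization protocols

Microarray probes are designed for an idealized reaction temperature, but
surface chemistry and buffer additives shift the physical temperature at
which an array actually performs best.  Hybridizing too cold costs
specificity (cross-hybridization), too hot costs sensitivity (signal lost
to the noise floor) — and a deviation of a single degree Celsius can wipe
out a large fraction of the differentially expressed genes an experiment
could have detected, hitting low-copy-number regulators such as
transcription factors hardest.

`hybcal` is for laboratories and platform developers who need to calibrate
such protocols objectively from a simple comparison of two typical
biological samples.  It scores each candidate protocol by the amount of
information its measurements carry about the sample identity, checks the
result from several methodological angles, and quantifies the downstream
cost of running at a suboptimal setting.

## The measures

For each gene *g* the log-intensity *x* is modelled, conditional on the
sample label *y* ∈ {0, 1}, as Gaussian with class means μ<sub>g,0</sub>,
μ<sub>g,1</sub> and common standard deviation σ<sub>g</sub> (the per-gene
ANOVA model).  Its dual representation as a classifier has posterior

&nbsp;&nbsp;&nbsp;&nbsp;P(y = 1 | x) = logistic(w<sub>g</sub> x + b<sub>g</sub>),
&nbsp; w<sub>g</sub> = (μ<sub>g,1</sub> − μ<sub>g,0</sub>)/σ<sub>g</sub>²,
&nbsp; b<sub>g</sub> = (μ<sub>g,0</sub>² − μ<sub>g,1</sub>²)/(2σ<sub>g</sub>²) + ln P(y=1)/P(y=0).

A protocol *K* is scored by

* the model log-likelihoods Σ ln N(x; μ, σ) and Σ ln P(y | x) (naive-Bayes
  form, in nats),
* model-free diagnostics from leave-one-slide-out cross-testing:
  generalization accuracy, gene-averaged ROC curves / mean AUC, and the
  mutual-information bit rate Σ log₂ P(y|x)/P(y) per gene,
* the number of genes significant in a dye-swap differential-expression
  test at Benjamini–Hochberg FDR q < 0.01.

Sample-independence of the resulting ranking is verified by re-ranking all
protocols on 100 stratified random gene subsets (zero/low/medium/high
differential expression in random proportions); a clear winner across
subsets — with ties between temperature neighbours resolved towards the
higher temperature — makes the calibration trustworthy.  A
temperature-dependent Langmuir adsorption simulator with competitive
cross-hybridization provides ground truth for validating all of the above.

## Worked example

Three simulated protocols measuring the same 400 planted genes at
increasing noise (as at increasingly suboptimal temperatures):

```r
library(hybcal)
set.seed(1)
d_opt <- gaussian_group_dataset(noise_sd = 0.2)
d_mid <- gaussian_group_dataset(noise_sd = 0.4, truth = d_opt$truth)
d_bad <- gaussian_group_dataset(noise_sd = 0.8, truth = d_opt$truth)
protocols <- list(`51C` = d_opt$es, `52C` = d_mid$es, `54C` = d_bad$es)

score_protocol(protocols, fdr_cutoff = 0.01)
#>   protocol loglik_linear loglik_nb accuracy_pct mean_auc bitrate n_sig
#> 1      51C          1484     -1064        84.31   0.8450 0.54667   249
#> 2      52C         -1676     -1584        77.12   0.7766 0.31136   140
#> 3      54C         -5001     -2231        67.31   0.6726 0.06864    14
```

Every measure — model-based log-likelihoods, cross-tested accuracy, AUC
and bit rate, and the count of significant genes — ranks the low-noise
protocol first, and the degraded protocols lose most of their significant
genes (249 → 14).  The ranking is then stress-tested over 100 random
sample compositions:

```r
strata <- stratify_genes(pool_protocols(protocols))
rd <- rank_protocols(protocols, strata, S = 100)
rd
#> hyb_rankdist: 3 protocols, 100 subsamples of size 100
#>     rank1 rank2 rank3
#> 51C     1     0     0
#> 52C     0     1     0
#> 54C     0     0     1
recommend_protocol(rd, c(`51C` = 51, `52C` = 52, `54C` = 54))$winner
#> [1] "51C"
```

The best protocol takes rank 1 in 100% of the subsamples: the choice does
not depend on the sample composition.  Finally, the enrichment of a gene
category (here the printed transcription-factor counts of a published
calibration: 47 of 1670 genes lost at +1 °C vs 32 of 2140 detected) is
tested exactly:

```r
fisher_enrichment(matrix(c(47, 1623, 32, 2108), 2, 2))
#> Fisher p = 0.0057, odds ratio = 1.91
```

Transcription factors are almost twofold enriched among the lost genes —
subtle fold changes of low-copy-number regulators are the first casualty
of a suboptimal protocol.

A command-line front end wrapping these steps (`score`, `rank`,
`simulate` subcommands) ships in `inst/cli/hybcal.R`.

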