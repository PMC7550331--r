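---
title: "Methods: prognostic signatures and microenvironment analytics in cmsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic signatures and microenvironment analytics in cmsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmsig)
```

`cmsig` packages the transcriptomic analysis chain used to characterise
conjunctival melanoma from small FFPE bulk RNA-seq cohorts: differential
expression, a correlation-centroid prognostic signature, and
tumour-microenvironment statistics on cell-type enrichment scores. This
vignette documents the models, the tunable parameters, the synthetic-data
design, the numerical choices, and the limitations — in particular what
passing the simulation-based tests does and does not establish about real
data.

## Differential expression

Counts are normalised by median-of-ratios size factors: the reference is
the per-gene geometric mean over samples, restricted to genes with positive
counts in every sample, and each sample's factor is the median ratio of its
counts to the reference. The test is a transparent negative-binomial Wald
test:

* per-gene dispersion $\alpha$ by method of moments on normalised counts,
  with mean and variance pooled within the two contrast groups,
  $\hat\alpha = (v - m)/m^2$, floored at $10^{-8}$ and capped at 10;
* a log-link NB GLM with design (intercept, group indicator) and offsets
  $\log s_j$, fitted by iteratively reweighted least squares. Since every
  gene shares the same two-column design, the IRLS normal equations are
  2×2 and solved in closed form vectorised across all genes (50 iterations
  maximum, relative deviance-change tolerance $10^{-8}$, linear predictor
  clamped to $\pm 30$ to keep one-group-all-zero genes finite);
* Wald $z = \hat\beta_1 / \mathrm{SE}$, two-sided normal $p$,
  $\log_2\mathrm{FC} = \hat\beta_1/\ln 2$, BH adjustment over the tested
  genes only (all-zero genes are excluded from the denominator).

A gene is called differentially expressed when $|\log_2\mathrm{FC}| > 2$
(strict) and adjusted $p < 0.05$. Deliberately absent: shrinkage of fold
changes, dispersion-trend fitting, outlier (Cook's distance) and
independent filtering. These serve robustness on real data but obscure the
threshold logic the package exists to test; the stand-in's calibration is
instead established by simulation (null type-I fraction ≈ 0.05–0.08 at 6v6,
recall > 0.9 and FDR < 0.05 for planted $|\log_2\mathrm{FC}| \in [2,4]$ at
the study's sample sizes). Batch effects are removed from the *log-scale
expression* used for visualisation and signature input via
`limma::removeBatchEffect`; the count-level test itself is run on
uncorrected counts, which is the conservative reading of a
batch-by-visualisation design.

## The prognostic signature

The signature engine follows the classic three-step correlation-signature
design. Candidates are the DEG between poor and good outcome. Each
candidate is scored by the point-biserial correlation $r$ of its expression
with outcome (poor = 1, good = 0) across the outcome-labelled tumours and
ranked by $|r|$ (ties broken lexicographically by gene id, so ranking is
fully deterministic). Selection proceeds in batches of five genes in rank
order. A signature of size $k$ is evaluated by leave-one-out validation
with a correlation-centroid classifier: for held-out tumour $i$, the
per-gene class centroids are recomputed without it, and

$$\mathrm{score}(i) = \mathrm{cor}(x_i, \bar x_{\mathrm{poor}}^{(-i)}) -
  \mathrm{cor}(x_i, \bar x_{\mathrm{good}}^{(-i)}),$$

Pearson correlation taken across the $k$ signature genes. The ROC AUC of
these scores (positive class poor, ties counting one half) is the
selection criterion: $k$ advances while the AUC strictly improves and stops
immediately at AUC = 1, returning the last improving $k$.

Design choices made where the procedure was genuinely open:

* **Expression input.** Correlation and classification run on
  $\log_2(\text{normalised count} + 1)$, batch-corrected when batches are
  present. Log transformation stabilises variance so Pearson correlation is
  not dominated by the highest-expressed genes; a linear-scale input is
  supported but not the default.
* **Ranking outside the LOO loop.** Genes are ranked once on all
  outcome-labelled tumours, not re-ranked within each fold. This mirrors
  the three-step design the engine implements, but it leaks the held-out
  label into the ranking, so the LOO AUC is an optimistic estimate of
  generalisation — a property the pure-noise simulations document rather
  than hide (in-sample-selected signatures on outcome-free cohorts still
  reach high apparent AUCs).
* **Score ties.** A score of exactly 0 leaves the sample unclassified; no
  silent default class.
* **Decision band.** $\sigma$ is the sample (n−1) standard deviation of the
  *signed* diagonal distances $(c_\mathrm{poor}-c_\mathrm{good})/\sqrt2$;
  confident classification requires $|d| > \sigma$ strictly. Absolute
  distances are available via a flag.

A structural caveat: Pearson correlation is invariant to adding a constant
across genes, so if every signature gene shifts in the *same* direction
with outcome by the *same* amount, the two class centroids differ only by a
constant and the classifier loses its signal. Informative signatures need
direction- or magnitude-heterogeneous genes; with randomly signed planted
effects this occurs in the large majority of simulated cohorts, but
direction-homogeneous draws (probability $2^{1-k}$ for $k$ equal-magnitude
genes) degrade the AUC sharply. Real signatures, with unequal effect sizes
and mixed directions, are rarely affected, but the failure mode is
inherent to centroid-correlation classification.

## Microenvironment analytics

Cell-type enrichment matrices (as produced by xCell and similar tools;
scores in [0,1], 64 types by default) are compared per type with the
Mann-Whitney U test, exact (doubled smaller tail of the exact null, capped
at 1) whenever the combined sample size is at most 20 and the scores are
untied — which covers all of this design's contrasts (12v8, 6v6, 5v7,
2v10) — and a normal approximation with tie and continuity correction
otherwise. The fold change of a cell type is the log2 quotient of group
mean scores; a zero group mean leaves it undefined rather than injecting an
epsilon, because any epsilon choice silently reorders the fold-change
ranking. Significance is two-sided unadjusted $p < 0.05$, matching the
convention of enrichment heatmaps; a BH-adjusted column is emitted
alongside. Composite immune and stroma scores are arithmetic means of the
member types (sum optional); genuine xCell composite rows can be passed
through verbatim instead via a flag, since whether published composite
scores are recomputed aggregates or the tool's internal weighted scores is
generally not stated.

Clinical contingency tables use Pearson chi-square with Yates continuity
correction applied to 2×2 tables only — the convention that reproduces all
published p-values of the study's patient-characteristics tables (0.081,
0.135, 0.261, 0.439, > 0.999) — with Fisher's exact test available as the
small-sample companion. No minimum-expected-count rejection is applied
(small cohorts routinely violate it); a warning is attached instead.

## The synthetic cohort generator

The generator emulates the count-level structure of the study design — it
is the package's test bed, not a data replica. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| samples | 6 poor / 6 good / 8 control | the study layout |
| genes | 2000 | desk-scale stand-in for the ~20k expressed genes; scale is a config field |
| baseline log2 mean | uniform [2, 10] | spans low- to high-expressed genes |
| dispersion α | log-uniform [0.05, 0.5] | conventional bulk RNA-seq range |
| library size factors | log-normal(0, 0.3) | moderate depth variation |
| tumour DEG | 150 at \|log2FC\| ∈ [2, 4], random sign | clearly above the DEG threshold |
| outcome genes | 20 at \|log2FC\| ∈ [2, 3], random sign | matches the published signature size |
| clinical flags | 5 recurrence, 2 metastasis among the 6 poor tumours | the study's outcome mix |

Counts are NB with variance $\mu + \alpha\mu^2$; the truth tables state the
parameterisation explicitly so the DE stage and the generator cannot drift
apart. Outcome genes are disjoint from tumour DEG by default, making
signature-recovery tests unambiguous. Enrichment matrices are Beta(2, 20)
at baseline (sparse scores with mean ≈ 0.09, the regime typical of
deconvolution output) with ±δ shifts (default 0.15) applied to designated
types in tumours, clamped to [0,1]; the default partition (40 immune / 14
stroma / 10 other, 8 enriched and 4 depleted types) echoes the published
16-up/8-down significant mix. Everything is deterministic given the config
seed.

What the generator does **not** emulate: 3′-end sequencing bias, UMI
structure, FFPE degradation, gene-gene correlation, dispersion-mean trends,
and the signature spillover of real deconvolution scores. Passing the
recovery tests therefore shows the *procedures* are implemented correctly
and calibrated under their stated model — not that the biological results
of any real cohort would reproduce.

## Problem sizes and determinism

Simulation-based tests use 2000-gene cohorts at the study's sample sizes,
with 10–100 seeds per property (type-I calibration, DEG recall/FDR,
signature recovery, enrichment power); the pure-noise signature sweep uses
500-gene cohorts over 50 seeds. These sizes make the full suite run in
well under a minute while leaving Monte-Carlo margins comfortably wide.
All selection machinery is deterministic: ranking ties are lexicographic,
the AUC trace is reproducible bit for bit, and generators consume a single
integer seed recorded in their truth output together with the RNG kind.

## Known limitations

* The LOO AUC is optimistically biased because ranking precedes the LOO
  loop (see above); the package documents rather than "fixes" this, since
  the fix (full nested cross-validation) would change the published
  procedure being implemented.
* The NB Wald stand-in is slightly anti-conservative at very small n
  (null type-I ≈ 0.08 at 6v6); its MoM dispersion is noisier than
  shrinkage-based estimators, which costs a little power near the
  fold-change threshold.
* Exact DESeq2 or xCell concordance is out of scope by design; their roles
  are filled by transparent, simulation-validated stand-ins behind the
  same interfaces.
* Over-representation analysis is a generic hypergeometric test on
  user-supplied GMT collections; it does not retrieve GO annotation.
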