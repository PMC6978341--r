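---
title: "Family variance scores: models, choices and limits"
author: "famvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family variance scores: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The score

For a gene family with $n$ members and a single sample's linear-scale
expression vector $v$ (RSEM-like units), the percent-of-family profile is
$x_i = 100\, v_i / \sum_j v_j$ and the family variance score is the
population variance of that profile:

$$\mathrm{FVS} = \frac{1}{n}\sum_{i=1}^{n} (x_i - \bar x)^2 .$$

The score ranges from $0$ (all members contribute equally) to
$100^2 (n-1)/n^2$ (one member carries the whole signal); for the 19-member
aldehyde dehydrogenase (ALDH) superfamily the maximum is
$10000 \cdot 18 / 361 \approx 498.6$.  Applied to ALDH, a high score flags a
tumor dominated by a single isoform — the situation in which an
isoform-selective inhibitor has a defined target — and a low score flags
diverse isoform usage.

Three conventions are deliberate and worth stating because alternatives
exist:

* **Percent scale, not proportions.**  With $x$ on a 0–1 scale the maximum
  for $n = 19$ would be $\approx 0.05$; published scores for head-and-neck
  cell lines exceed 100, so the 0–100 scale is the only consistent reading.
* **Population variance** (divide by $n$), not the $n-1$ sample variance.
* **$n$ is the full family size**, counting members with zero expression.
  Dropping unexpressed members would change both the mean and the
  denominator and destroy comparability across samples.

The score is invariant to rescaling of $v$ (sequencing depth, library size)
and to reordering of members, and it requires *linear-scale* input:
percent shares of log-transformed values are not meaningful, and the package
does not attempt to detect or undo an upstream log transform.

Samples whose family total is zero have no defined profile; they are
excluded from scoring with a warning rather than silently scored 0.

## Stratification

Two splits are provided, mirroring the two uses in cohort analysis:

* `median`: low iff score $\le$ median. Samples exactly at the median go to
  the low group — an explicit tie rule, chosen for determinism, not an
  inference about any published convention.
* `quartile25`: low iff score $<$ the 25th percentile, so the high group is
  the top 75%.  Percentiles use linear interpolation between order
  statistics (R type 7); definitions differ only at small $n$ and the
  threshold actually used is always reported in the output.

## Association tests

Fisher's exact test (score group × tumor class) uses the probability-mass
two-sided convention — all tables with the observed margins whose
hypergeometric probability does not exceed the observed one.  The sample
odds ratio $ad/bc$ is reported, with zero/infinite values flagged rather
than truncated, and zero-margin tables return $p = 1$ with a degenerate
flag.  Spearman correlation (score vs stemness index) drops incomplete
pairs and uses the $t$-approximation on $n-2$ df, adequate at cohort sizes;
an exact permutation option exists for $n \le 10$.  The rank-sum comparison
enumerates the exact null for tie-free samples with $n_1+n_2 \le 12$ and
otherwise uses the normal approximation with tie and continuity
corrections.  These are the conventions of the mainstream statistical
ecosystems; they are stated because other conventions (e.g. doubling the
one-sided Fisher p) exist.

## Survival

Follow-up is truncated at a horizon — 60 months for five-year analyses,
applied *before* both the Kaplan–Meier/log-rank comparison and the Cox
models, so that all survival outputs refer to the same window.  Subjects
followed beyond the horizon are administratively censored at it.

The per-isoform scan fits univariate Cox models with the Efron tie
approximation (month-resolution registry data are heavily tied; Breslow is
available).  Hazard ratios are per unit of $\log_2(\mathrm{expr}+1)$ by
default: per-unit-RSEM hazard ratios conflate effect size with abundance
and are not comparable across genes of very different expression.  The
scale is recorded in the output attributes, and published per-isoform
hazard ratios computed on unstated covariate scales should not be expected
to match numerically.  Confidence intervals are Wald from the observed
information, the convention of tabulated univariate scans.  Cohorts with
fewer than two events, constant covariates, and diverging (monotone
partial likelihood) fits are skipped with warnings rather than reported.

## Sorted-population enrichment

Relative expression of each family member in sorted high- vs low-activity
populations uses the $\Delta\Delta C_t$ method with an assumed
amplification efficiency of 2 and a designated reference gene.  Replicates
are paired by index (replicate $i$ high vs replicate $i$ low) and the
profile reports the mean and s.e.m. of per-replicate folds
(mean-of-folds).  The alternative — fold of mean $\Delta C_t$ — differs
only at second order for small cycle noise; mean-of-folds was chosen
because it yields a per-replicate dispersion estimate directly.  The
enriched-gene count uses a configurable threshold defaulting to 5-fold,
and dominance ties are flagged, not broken.

## Limiting-dilution frequency

The single-hit Poisson model assumes each graft of $d$ cells forms a tumor
with probability $1 - e^{-df}$, $f$ the initiating-cell frequency.  The
log-likelihood over dose rows $(d_j, n_j, k_j)$,

$$\ell(f) = \sum_j k_j \log(1 - e^{-d_j f}) - (n_j - k_j)\, d_j f,$$

is maximized in $t = \log f$ ($\ell$ is concave in $t$) by a safeguarded
Brent bracket on the analytic score followed by a Newton polish, to well
below $10^{-10}$ in $t$; a single-dose assay reproduces the closed form
$f = -\log(1 - k/n)/d$ to machine precision.  The default 95% interval is
Wald on $\log f$ from the observed information — the convention of the
dilution-assay calculators this module replaces — with a profile-likelihood
interval available because Wald intervals misbehave near boundaries.
Degenerate assays (no responders anywhere, or responders everywhere) sit on
a boundary: the point estimate is flagged and an exact one-sided bound from
the likelihood itself is reported, e.g. the upper bound
$-\log(0.05)/\sum_j n_j d_j$ when no graft takes.  Arm comparison is a
1-df likelihood-ratio test of shared vs arm-specific $f$, plus the fold
ratio of the two MLEs.  Incidence is treated as a binary endpoint;
time-to-palpation is not modeled.  Simulated coverage of the Wald interval
at $f = 10^{-4}$ with doses $10^3/10^4/10^5$ and 10 animals per dose is
about 94% over 1,000 replicates.

## The synthetic cohort generator

The generator exists so that every pipeline stage has a seeded,
download-free test surface with known ground truth.  It emulates the
*statistical structure* the analyses assume, not any real dataset:

* **Composition.**  Each sample's family composition is Dirichlet: the
  dominant-isoform class uses concentration 8 on one member (ALDH1A3, the
  commonly dominant isoform in this setting) and 0.3 elsewhere; the
  diverse class uses symmetric concentration 3.  Dirichlet concentration
  directly controls percent-profile dispersion — exactly what the score
  measures — giving class median scores of roughly 180 vs 8, which bracket
  most of the published cell-line range (28–313) from both sides.
* **Abundance.**  Compositions are scaled by a LogNormal(log 1000, 0.5)
  family total to an RSEM-like linear scale.  The score is
  scale-invariant, so this only exercises the normalization path.
* **Stemness.**  `mrnasi = clamp01(0.35 + 0.04 z + N(0, 0.12))` with `z`
  the standardized true score; the implied latent correlation (~0.3) is of
  the same order as published score–stemness correlations.
* **Survival.**  Exponential event times with per-class baseline hazards
  0.004 and 0.012 per month (about 79% and 49% five-year survival, typical
  of the two tumor classes) and log-hazard −0.3 per SD of the score (high
  variance protective); censoring Uniform(0, 120) months.

Every draw comes from one seeded stream, so a cohort is a pure function of
(configuration, seed).  What the generator does **not** emulate: batch
effects, GC-content artefacts, within-tumor heterogeneity, non-family
genes, competing risks, or informative censoring.  A pipeline that passes
on synthetic cohorts is internally consistent and recovers known
parameters; that says nothing about normalization or confounding issues in
real cohort data.

## Problem sizes and numerical settings

The shipped validation suites use: 1,000 random profiles for the score
invariants (tolerances $10^{-9}$ for invariances, $10^{-12}$ against a
two-pass oracle); the full single-dose grid $1 \le k < n \le 50$ at
relative tolerance $10^{-10}$; 1,000 seeded assays for interval coverage;
100 replicates at $n = 500$ per hazard ratio for Cox recovery (mean log-HR
within 0.1); and 50 seeded cohorts at 200 samples/class for the
end-to-end pattern (class difference by Fisher, positive score–stemness
correlation, prognostic top-75% group).  These sizes make the whole suite
run in well under a minute per module while leaving Monte-Carlo margins
far from the asserted thresholds.

## Known limitations

* Gene matching is exact-string after uppercasing; no alias resolution.
  A renamed symbol silently becomes a "missing member", which is why the
  default missing-member policy is to error rather than impute zero.
* The cytokeratin family ships as the 37 human epithelial keratin symbols;
  only the family *size* is externally anchored, and the definition file is
  plain text precisely so users can substitute their own roster.
* Per-isoform hazard ratios depend on the covariate scale; cross-study
  numeric comparison requires knowing that scale.
* The limiting-dilution module fits one frequency per arm; multi-hit
  models, heterogeneous-frequency models and >2-arm trend tests are out of
  scope.
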