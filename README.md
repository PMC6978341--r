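# famvar

Bulk tumor transcriptomes rarely say *which* member of an enzyme family is
doing the work. For the 19-member aldehyde dehydrogenase (ALDH)
superfamily — whose activity marks cancer-initiating cells — that question
is clinically concrete: a tumor dominated by a single isoform is a
candidate for isoform-selective inhibition, while a tumor spreading
expression across many isoforms is not. `famvar` quantifies this with a
per-sample **family variance score**: member expression is converted to
percent of the family total,

```
x_i = 100 * v_i / sum(v),      FVS = sum_i (x_i - mean(x))^2 / n,
```

the population variance of the percent profile. The score is 0 for
perfectly even usage and `100^2 (n-1)/n^2` (~498.6 for n = 19) when one
isoform carries everything; it is invariant to sequencing depth and member
order. Around the score the package implements the complete downstream
analysis used in head-and-neck cancer cohort studies:

* percent-of-family profiles, cohort scoring and high/low stratification
  (median or top-75%/bottom-25% splits);
* association tests: Fisher exact (score group × tumor class), Spearman
  (score vs stemness index mRNAsi), Wilcoxon rank-sum;
* five-year Kaplan–Meier curves with log-rank comparison and a per-isoform
  univariate Cox scan (Efron ties, Wald CIs);
* ΔΔCt enrichment profiles of sorted ALDH-high vs ALDH-low populations,
  with dominant-isoform calls;
* single-hit Poisson estimation of cancer-initiating-cell frequency from
  limiting-dilution assays, with arm comparison and fold depletion;
* a seeded synthetic-cohort generator with known ground truth, so every
  stage is testable without external downloads.

It is written for computational biologists analyzing TCGA-like bulk
RNA-seq cohorts with clinical annotation, and for lab scientists reducing
qPCR and limiting-dilution experiments.

## Worked example

Score a synthetic two-class cohort (dominant-isoform class vs
diverse-isoform class, 200 samples each) and run the cohort analyses:

```r
library(famvar)

co     <- generate_cohort(synthetic_config(n_per_class = 200, seed = 1))
aldh   <- load_builtin_family("ALDH")
scores <- score_cohort(co$matrix, aldh)
head(scores, 3)
#>   sample_id      avs n_members n_missing_in_matrix
#> 1     S0001 249.7230        19                   0
#> 2     S0002 251.1574        19                   0
#> 3     S0003 156.2284        19                   0

tapply(scores$avs, co$clinical$class_label, median)
#> HPV-/p53HRmut  HPV16+/p53WT
#>      7.928412    174.845536
```

The dominant-isoform class scores ~175 at the median, the diverse class ~8.
A median split separates the classes (Fisher), the score tracks the
stemness index (Spearman), and the high-score group has distinct five-year
survival (log-rank):

```r
tab <- group_class_table(stratify(scores, "median"), co$clinical)
fisher_exact_2x2(tab)$p_value
#> [1] 1.942643e-119

merged <- merge(scores, co$clinical, by = "sample_id")
sp <- spearman_test(merged$avs, merged$mrnasi)
c(rho = sp$estimate, p = sp$p_value)
#>          rho            p
#> 3.351884e-01 5.864489e-12

g4 <- merge(stratify(scores, "quartile25"), co$clinical, by = "sample_id")
tr <- truncate_followup(g4$time, g4$event, horizon = 60)
lr <- logrank_test(tr$time, tr$event, g4$group)
c(chisq = lr$chisq, p = lr$p_value)
#>        chisq            p
#> 2.422295e+01 8.580373e-07
```

Limiting-dilution assays reduce to an initiating-cell frequency per arm
and a fold depletion between arms:

```r
control   <- dilution_assay(c(1e3, 1e4, 1e5), c(10, 10, 10), c(4, 9, 10), arm = "control")
knockdown <- dilution_assay(c(1e3, 1e4, 1e5), c(10, 10, 10), c(0, 1, 3), arm = "knockdown")
cmp <- compare_arms(control, knockdown)
cmp$fit_a$reciprocal; cmp$fit_b$reciprocal
#> [1] "1/3,316"
#> [1] "1/236,102"
c(fold = cmp$fold, p = cmp$p_value)
#>         fold            p
#> 7.120804e+01 5.467629e-15
```

Here the knockdown arm's frequency is ~71-fold lower than control
(likelihood-ratio p < 0.001): the initiating-cell pool is depleted.

See `vignettes/family-variance-methods.Rmd` for the model conventions,
the synthetic generator's parameters, and numerical choices.

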