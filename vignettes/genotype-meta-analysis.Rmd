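---
title: "Genotype-count meta-analysis: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-count meta-analysis: models, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemeta)
```

## The problem

Candidate-gene case-control studies of a biallelic variant report, per
cohort, genotype counts (here Val/Val, Val/Met, Met/Met at BDNF
Val66Met, rs6265) split by phenotype arm (current smokers vs never
smokers for the smoking-persistence contrast). Individually these
cohorts are small-to-moderate and their results conflict; the
meta-analytic task is to pool them on a common effect scale while
checking the assumptions that make pooling meaningful: genotype counts
consistent with Hardy-Weinberg equilibrium (HWE) in controls, limited
between-study heterogeneity, and no evidence that small unfavourable
studies are missing from the literature.

`genemeta` stores the raw 2x3-per-arm counts (the way such tables are
published) and derives everything downstream, so any genetic model can
be applied without re-extracting data.

## Genetic models and sign conventions

A `study_set` row collapses to a 2x2 table under:

* **dominant** (default): Val/* vs Met/Met — the package default
  because Val is the major allele and the carrier contrast is the one
  with usable published results for this variant;
* **recessive**: Val/Val vs Met/*;
* **allelic**: Val vs Met alleles (two per subject, so table margins
  double);
* **additive**: no single 2x2 exists; it is realised as a
  Cochran-Armitage trend test with Val-dose scores 0/1/2
  (`cochran_armitage_trend()`).

Two conventions are fixed deliberately: exposure is always the
Val-containing category and cases are always the first arm of the
contrast, so OR > 1 uniformly means "Val carriers maintain smoking
more". Published forest plots leave these conventions implicit; fixing
them removes sign ambiguity from every downstream module.

HWE is tested on the never-smoker (control) arm by default — deviation
in controls is the standard genotyping-quality flag; testing cases
conflates HWE failure with true association. The chi-square uses the
estimated Val-allele frequency, expected counts `(p^2, 2pq, q^2) * n`,
1 df. A monomorphic arm returns `chi2 = 0, p = 1` with a flag rather
than dividing by zero expected counts.

## Effect estimation and pooling

Per study, `log OR` with the Woolf variance `1/a + 1/b + 1/c + 1/d`.
The continuity-correction default is `add_half_if_zero`: 0.5 is added
to **all four** cells of a table containing any zero, before both the
point estimate and the variance. The packaged cohorts contain no zero
cells, so their results are correction-free; the policy matters only
for user-supplied or simulated sparse tables.

Three pooling engines are provided:

* `pool_fixed_iv()` — inverse-variance weights; the package's
  fixed-effects default. Although Mantel-Haenszel weighting is the
  textbook fixed-effects method for count data, the subgroup and
  cumulative values this package is validated against are reproduced to
  printed precision by inverse-variance weighting, so that is the
  default; MH remains available and both are reported by
  `run_pipeline()`.
* `pool_fixed_mh()` — Mantel-Haenszel with the
  Robins-Breslow-Greenland SE. On dense tables like the packaged
  fixture it agrees with inverse variance within 1% relative.
* `pool_random_dl()` — DerSimonian-Laird. The moment estimator is the
  only tau-squared estimator offered (no REML or Paule-Mandel): it is
  the method the validated analysis used, and offering one estimator
  keeps "random effects" unambiguous in reports. When `Q <= k - 1`
  the tau-squared truncates to zero and random effects coincide with
  fixed effects exactly — the all-cohorts fixture run exercises this.

Numerical choices: the 95% multiplier is the exact quantile 1.959964
rather than 1.96 (bounds are reported to three decimals downstream);
two-sided p values come from the standard normal; `I2 = max(0,
100 (Q - df)/Q)` is truncated at zero so homogeneous sets report
exactly 0.0 rather than small negative values.

## Publication-bias diagnostics

`egger_test()` is the classical unweighted regression of the
standardized effect `y_i/se_i` on precision `1/se_i`; only the
intercept's two-sided t-test (k − 2 df) is consumed. Weighted Egger
variants exist; the unweighted form is the most common reading of
"Egger's regression test" and the variant choice only matters near the
decision boundary. Exactly collinear input (zero residual variance)
would make the t statistic 0/0; the implementation detects it via the
residual sigma and reports p = 1 for a zero intercept (p = 0
otherwise), which is the correct limit.

`trim_and_fill()` implements the Duval-Tweedie iteration with the L0
(signed-rank sum) and R0 (rightmost run) estimators, trimming on the
heavy side (chosen by the Egger intercept sign under `side = "auto"`),
re-pooling with fixed effects inside the loop — the original authors'
recommendation, since random-effects weights are themselves distorted
by the bias being corrected — and imputing mirror-image studies with
variances copied. The adjusted estimate is reported under both fixed
and random models. A behavioural note encoded in the tests: under
perfect base symmetry the R0 run length counts the planted extreme
studies plus at most the tied mirror point, so planting `m` extra
rightmost studies yields `k0 = m - 1`, not `m`; this matches the
reference implementation in `metafor` and is a property of the
estimator, not a bug.

## Robustness analyses

`leave_one_out()` re-pools omitting each study in turn (fixed IV by
default, matching the validated analysis). `cumulative_by_year()`
groups ties by publication year — cohorts published the same year enter
in one step — because the cumulative trajectory is indexed by year and
the first validated point (1.422 in 2007) is reproduced only by pooling
both 2007 cohorts together. The final cumulative row equals the
all-studies pooling exactly, by construction.

## The synthetic-data generator

`simulate_study()` draws control genotypes multinomially from HWE
proportions at a specified Val-allele frequency, draws a study-level
log OR as `log(true_or) + N(0, tau^2)`, multiplies the Val/* genotype
odds (relative to Met/Met) by that OR and renormalises before drawing
case genotypes. The generator parameterises the **dominant-model OR
directly** rather than a per-allele logistic model: the analysis under
test is dominant-model, so parameter recovery is exact by construction,
which is what makes bias and coverage experiments sharp.

Defaults mirror the populations in the packaged cohorts: presets
`asian_like` (Val frequency 0.515) and `caucasian_like` (0.784), eight
studies of 500 cases / 500 controls, true OR 1.25 (the magnitude of the
validated association), tau = 0. One seeded RNG stream per
`simulate_meta()` call, studies drawn in order, so a single integer
reproduces a whole meta-analysis.

What the generator does **not** emulate: linkage disequilibrium with
neighbouring variants, covariates and gene-environment interaction,
genotyping error (its cohorts always satisfy HWE in expectation),
unequal arm sizes within a study, and literature-level selection
effects. Passing recovery tests therefore demonstrate that the
estimators are correctly implemented and calibrated under the stated
sampling model — not that real published literatures are free of the
biases the diagnostics screen for.

Test problem sizes were chosen to put Monte-Carlo error well below the
tolerances checked: 200 replicates for bias/coverage/size experiments
(empirical type-I error is then estimated to within about ±0.015), 30-40
replicates for tau-squared consistency and heterogeneity monotonicity,
which only assert directional or ±30% relative claims.

## Known limitations and open edges

* Two printed numbers in the validated analysis are not reproducible
  from its own published count table (which sums to N = 10,160 overall
  and 4,661 Caucasian, against printed Ns of 10,490 and 4,991): the
  Caucasian-stratum I² (printed 18.9 vs 24.7 from the counts) and the
  claim that every leave-one-out pooling stays significant (omitting
  the 2012 Asian cohort gives p = 0.062 from the counts). The package
  reports what the counts imply.
* The overall pooled P computes to 0.019 against a printed 0.021; the
  residual gap is attributed to the originating software's internals
  and sits within the documented tolerance.
* No Hartung-Knapp small-k adjustment, prediction intervals,
  meta-regression, Begg-Mazumdar test or selection models; the scope is
  the workflow above.
* `run_pipeline()` skips strata with fewer than `min_cohorts = 2`
  cohorts (a one-cohort "meta-analysis" is just that study), logging
  the skip rather than failing.
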