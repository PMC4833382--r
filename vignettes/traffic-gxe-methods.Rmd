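---
title: "Methods: stratified gene-environment interaction scans with a robust score test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified gene-environment interaction scans with a robust score test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescan)
```

## The scientific problem

`gxescan` implements a genome-wide interaction study (GWIS) for a binary
disease outcome in a case-control cohort: per variant, does an environmental
exposure's association with disease depend on genotype?  The motivating
setting is residential traffic exposure — distance in meters from the primary
residence to the nearest major roadway, a proxy for traffic-related air
pollution — and peripheral arterial disease (PAD), analysed separately in two
ancestry strata of very different size (on the order of 1,600 and 550
subjects) with divergent allele frequencies and LD structure.

The cohort data such analyses are run on are access-restricted, so the
package ships a synthetic-cohort generator that reproduces the statistical
structure the analysis assumes (two ancestry strata, Balding-Nichols
frequency divergence, block LD, right-skewed exposure, ~6.3% outcome
prevalence).  Every stage of the pipeline is exercised and validated on
generated data.

## The per-variant model

For subject $i$, with additive genotype $G_i \in \{0,1,2\}$ (minor-allele
count), exposure $E_i$ (distance scaled by its interquartile range, so
effects are per IQR), and covariates $X_i$ (age, sex, ancestry principal
components; optionally BMI and binary clinical indicators):

$$\operatorname{logit} P(Y_i = 1) =
  \beta_0 + \beta_G G_i + \beta_E E_i + \beta_{G \times E} G_i E_i +
  \gamma^\top X_i .$$

The scan reports the Wald estimate, standard error and odds ratio
$e^{\beta_{G\times E}}$ (per minor allele per exposure IQR) from the full
maximum-likelihood fit, while significance of the interaction comes from a
**robust score test** evaluated at the null fit (all terms except
$G \times E$):

* score: $U = \sum_i z_i (y_i - \hat p_i)$ with $z_i = G_i E_i$ and
  $\hat p_i$ the null fitted probabilities;
* projection: $a = z - X (X^\top W X)^{-1} X^\top W z$ with
  $W = \mathrm{diag}(\hat p (1 - \hat p))$, where $X$ here is the null
  design including $G$ and $E$;
* empirical (sandwich-type) variance:
  $V_{\text{rob}} = \sum_i a_i^2 (y_i - \hat p_i)^2$;
* statistic $T = U^2 / V_{\text{rob}} \sim \chi^2_1$ under the null.

The model-based variance $a^\top W z$ is returned alongside for diagnostics.
The score test needs only the null fit, is the locally most powerful
asymptotic test, and the empirical variance protects the variance estimate
against higher-moment misspecification that the product term $G E$ is
particularly exposed to when $E$ is long-tailed.

**Convergence policy.**  IRLS with at most 50 iterations and tolerance
$10^{-8}$.  Separation is detected through diverging coefficients on the
per-column-SD scale (any $|\hat\beta_j| \cdot \mathrm{sd}(X_j) > 15$), not
through boundary fitted probabilities: a genuine strong interaction with a
long-tailed exposure legitimately produces fitted values near 1, whereas
separation always sends a scaled coefficient towards infinity.
Non-converged, separated, or zero-variance fits are flagged and excluded
from p-value reporting rather than silently dropped.

## QC, stratification, and scan mechanics

Filters run in a fixed order: variant call rate (default $\ge 0.98$), then
subject call rate ($\ge 0.98$) over retained variants, then MAF.  The MAF
boundary is *inclusive* ($\ge 0.05$): published MAF columns print values of
exactly 0.05 among retained variants, so the open-interval reading would
contradict the tables; the threshold is configurable.  Missing genotypes are
handled per-variant complete-case, the standard GWAS convention.

Principal components are computed per stratum from standardized genotypes
(centred at $2\hat p$, scaled by $\sqrt{2 \hat p(1-\hat p)}$, missing set to
0 after centring), with component signs fixed by the largest-magnitude
loading.  Outlier-removal iterations of the original Eigenstrat procedure
are omitted — the scores are only used as adjustment covariates.  The
number of components per stratum is configurable and defaults to 2 for
every stratum (the source analysis states "two" only for the smaller
cohort and leaves the other count unspecified; we decline to guess and
expose it as a parameter).

Each stratum is scanned independently: exposure re-scaled by the stratum
IQR, MAF filter applied within stratum, genotype recoded to the stratum's
minor allele (so odds ratios are per minor allele for each ancestry), and
hits tagged at the genome-wide ($p < 5\times10^{-8}$) and suggestive
($p < 1\times10^{-5}$) tiers.

## Genomic-control F-test (GCF) recalibration

Inflation is estimated as $\lambda_m = \mathrm{median}(T) / 0.4549$, the
median of the observed score statistics over the $\chi^2_1$ median,
optionally on a seeded subsample.  Recalibrated p-values refer $T/\lambda_m$
to the upper tail of $F(1, 100)$; the second degree of freedom is
configurable with 100 as the published default, and $df_2 = \infty$ recovers
the $\chi^2_1$ tail exactly.  The finite-$df_2$ tail is strictly heavier, so
GCF p-values are conservative relative to plain genomic control.  By
default a stratum is recalibrated only when its $\lambda_m > 1$, matching
an analysis that corrected its smaller cohort only.

**What our calibration experiments show.**  With ~500 subjects at 6.3%
prevalence (roughly 32 cases) and a log-normal exposure, the robust score
statistic's null distribution is *not* a scaled $\chi^2_1$: its median is
inflated (seed-dependent $\lambda_m$ estimates around 1.0-1.25, with values
near 1.22 typical) while its 5% tail rejection stays inside the exact
binomial 99% interval.  The two facts together imply that a median-based
rescale over-corrects the tail — and indeed, after injecting a known
constant inflation, GCF adjustment yields a conservative rejection rate
(~0.02-0.03 at nominal 0.05).  On genuinely $\chi^2$-distributed statistics
the estimate-and-adjust round trip restores nominal calibration exactly, as
the inflation-control test suite verifies.  This is worth knowing when
interpreting a small-cohort GWIS: a median $\lambda_m$ of ~1.2 at ~34 cases
can arise from small-sample behaviour of the sandwich variance alone,
without any population stratification, and correcting by it errs on the
conservative side.

## Meta-analysis across strata

Per-cohort effects are first aligned to a common effect allele (sign-flip
the beta and complement the frequency when cohort B's effect allele is
cohort A's other allele).  Strand-ambiguous pairs (A/T, C/G) whose
frequencies cannot arbitrate the strand (both MAFs in $[0.4, 0.6]$, a
conventional window) are flagged unresolvable and excluded.  The combined
estimate is fixed-effect inverse-variance:
$w_k = 1/se_k^2$, $\hat\beta = \sum w_k \beta_k / \sum w_k$,
$se = (\sum w_k)^{-1/2}$, two-sided normal p.  The MAF filter is relaxed for
meta-analysis: a variant is combined when its MAF is $\ge 0.05$ in at least
one cohort.  Weights come only from Wald standard errors of the full model
(an inverse-variance scheme requires betas and SEs; the published workflow
likewise fed effect estimates to a standard meta-analysis tool), and
GCF-adjusted p-values are never back-transformed into weights.
Classification tags mirror the published decision rules: replication means
suggestive in one stratum with $p < 0.05$ in the other; consistency means
the same direction of effect after alignment.

## Stability screening

Published top hits were screened by removing outliers and refitting; an
order-of-magnitude change in the odds ratio or p-value marks a result as
statistically unstable, and interaction SEs above 10 are filtered outright.
The outlier rule here is operationalized as |standardized Pearson residual|
> 4 in the full model (the source describes only visual inspection of
residual plots; 4 is far-tail under a correctly specified model and
configurable).  A refit that fails to converge is unstable by definition.
The constructed-contamination test shows the rule catching the canonical
failure mode: a real interaction masked by a few extreme
genotype-times-exposure controls, whose removal moves the p-value by
orders of magnitude.  Note that the robust score statistic itself is fairly
resistant to single influential points (each point's score contribution is
self-normalized by the empirical variance), so instability typically
manifests through the Wald estimate or through clusters of contaminants.

## The synthetic cohort generator

* **Genotypes.**  Ancestral frequencies uniform on a configurable range
  (default 0.05-0.5); stratum frequencies from the Balding-Nichols
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ model (default $F_{st} = 0.1$, a
  deliberately strong divergence so that PC adjustment is exercised); within
  LD blocks (default 10 variants) a latent AR(1) Gaussian with correlation
  $\rho$ (default 0.3) thresholded at the Hardy-Weinberg genotype-class
  quantiles, so marginals are HWE and adjacent-variant $r^2$ decays
  geometrically.  Missing calls are injected completely at random (default
  rate 0.002, typical array-era call rates), since the QC under test uses
  only call rates.  A multi-stratum config with $F_{st} = 0$ and $\rho > 0$
  is rejected: LD cannot generate between-stratum divergence.
* **Exposure.**  Log-normal distance in meters, default
  $\mu = 6.09, \sigma = 1$ on the log scale, giving an IQR near 641 m — the
  published exposure IQR.  Only the IQR is reported in the source; the
  log-normal shape is an assumption (right-skew is characteristic of
  distance-to-feature measures) and both parameters are config-exposed.
* **Outcome.**  Bernoulli with the logistic model above; the intercept is
  calibrated by root-finding so the *expected* prevalence over the simulated
  covariate distribution hits the target (default 0.0634, the genotyped
  cohort's PAD prevalence) within 0.002; calibration failure is an error,
  never silent.  The exposure main effect defaults to $\log(0.88)$ per IQR
  of distance — magnitude from the published race-and-sex-adjusted
  association, signed so that greater distance from traffic is protective
  (the source text states the direction inconsistently; we adopt the
  physiologic reading).  Default age and sex effects (0.03/year, -0.3 for
  female) are typical of PAD risk models; per-stratum age and sex
  distributions default to the published cohort table.
* **Determinism.**  One integer seed; genotype and phenotype substreams are
  derived from it by fixed offsets; an identical config is bit-identical
  across runs.

What the generator does *not* emulate: realistic recombination maps and
demographic history, spatially autocorrelated exposure surfaces, exposure
measurement error correlated with covariates, and non-random missingness.
Passing tests therefore demonstrate the statistical machinery is correct
under the stated model, not that real-data confounding is handled beyond
what PC adjustment provides.

## Numerical choices and degenerate inputs

* Quartiles are type-7 (linear interpolation), the R default; the IQR
  convention is stated because published IQRs rarely specify one.
* The 2x2 cohort-table test uses the capped Yates correction
  $c = \min(0.5, |O - E|)$; the continuity-corrected convention reproduces
  the published borderline p-value (0.90) that the uncorrected test does
  not (~0.82), which is how the convention was identified.  Correction is
  on by default and toggleable.
* Zero-IQR exposure, all-missing variants, zero table margins, and empty
  post-QC panels raise descriptive errors; monomorphic variants are
  excluded from PCA and flagged in LD computations.
* PCA requires $k < \min(n_{\text{subjects}} - 1, n_{\text{snps}})$ —
  centring consumes one degree of freedom.
* Ties in the scan ordering are resolved by genomic position within
  stratum; all output files are written deterministically and
  checksummed in a run manifest.

## Problem sizes used by the test and validation suites

The bundled validation runs are sized to be exact about distributional
claims while remaining quick: null calibration uses 2,000 variants at 500
subjects against exact binomial 99% bounds; effect recovery uses single
fits at 20,000 subjects (planted odds ratios 2.0 and 3.45) and
median-over-40-replicate checks at 2,500 subjects; pipeline determinism
uses two strata of 250/120 subjects over 120 variants.  These sizes are the
package's validation design and are all config-exposed, so any of the
checks can be rerun at larger scale.

## Known limitations

* The score/Wald hybrid (score p-values, Wald effect sizes) follows the
  published analysis; near the significance boundary the two can disagree,
  and the meta-analysis inherits the Wald side.
* Median-based genomic control corrects a scaled-$\chi^2$ alternative; as
  shown above, small-case-count robust-score inflation is not of that form
  and GCF then over-corrects.
* Only biallelic variants and the GT-only VCF dialect are supported.
* The stability screen's residual rule is one operationalization of
  "examined residual plots"; influence-based diagnostics (Cook's distance)
  would flag high-leverage contaminants that residuals alone can mask.
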