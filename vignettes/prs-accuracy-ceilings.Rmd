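---
title: "Models and methods: PRS accuracy ceilings from captured heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: PRS accuracy ceilings from captured heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsceiling)
```

## The question

A polygenic risk score built from GWAS summary statistics can, at best,
recover the genetic variance carried by the variants the GWAS observed.
This package quantifies that ceiling along three links: how much
heritability a variant panel *captures* (array + LD tagging vs. full
imputation), how capture depends on the coupling between allele frequency
and effect size (the alpha model), and how captured heritability translates
into a maximum achievable AUC under the liability-threshold model. A
simulation pipeline (noisy marginal GWAS effects, shrinkage weighting,
out-of-sample scoring) demonstrates the convergence of realized AUC to that
ceiling as the training sample grows.

## The liability-threshold model and the AUC ceiling

Disease status is a thresholded latent liability: an individual is a case
iff their liability — a standard normal sum of a genetic score with
variance $h^2$ and independent environmental noise with variance $1-h^2$ —
exceeds $T = \Phi^{-1}(1-K)$, where $K$ is the prevalence. With
$z = \varphi(T)$, the mean liability of cases is $i = z/K$ and of controls
$v = -z/(1-K)$ (truncated-normal means; `liability_params()`). A predictor
capturing all of $h^2$ then attains approximately

$$\mathrm{AUC}_{\max} = \Phi\!\left(
  \frac{(i-v)\,h^2}{\sqrt{h^2\left[(1 - h^2 i (i-T)) + (1 - h^2 v (v-T))\right]}}
\right).$$

The square root in the denominator is essential: the expression under it is
the variance of the case–control difference of the predictor, so omitting
it is dimensionally inconsistent and fails the simulation check below.
`auc_max()` returns 0.5 at $h^2 = 0$ by continuity and raises a distinct
error if the variance term is non-positive (pathological $h^2$, $K$
combinations outside the approximation's working range).

`validate_auc_max()` checks the approximation against direct simulation
(genetic score $g \sim N(0, h^2)$, liability $g + N(0, 1-h^2)$, empirical
AUC of $g$ against case status). Over $h^2 \in [0.2, 0.7]$ and
$K \in [0.01, 0.25]$ with $5\times10^5$ individuals per cell the absolute
disagreement stays below 0.01; the test suite and the acceptance script
recompute this. Conditional ceilings substitute the captured share:
`conditional_auc_max(h2, prop, K) = auc_max(h2 * prop, K)`.

## Captured heritability

With effects $\beta_i$ on standardized dosages, $h^2 = \sum_i \beta_i^2$
(this identity is the reason the package interprets $\beta$ on the
standardized scale; the per-allele effect is $\beta/\sqrt{2pq}$). Two
capture metrics:

- $h^2_G = \sum_{i \in S} \beta_i^2 + \sum_{j \notin S} \beta_j^2 \rho_j^2$
  — the array's reach, where $\rho_j^2$ is the **adjusted** $R^2$ of the
  multiple regression of untyped variant $j$'s true dosage on all genotyped
  dosages within ±1.5 Mb (`tagging_rho2()`; window configurable).
- $h^2_I = \sum_i \beta_i^2 r^2_{\mathrm{imput},i}$ — the reach of full
  imputation, with $r^2_{\mathrm{imput}}$ the squared correlation between
  true and imputed dosage (`imputation_r2()`).

Numerical conventions, chosen once and asserted in tests:

- Genotyped variants get $\rho^2 = r^2_{\mathrm{imput}} = 1$: they are
  their own perfect imputations, which makes the two formulas coincide when
  every variant is typed.
- Adjusted (not raw) $R^2$ is used for tagging; negative adjusted values
  are clamped to 0 so $h^2_G$ stays non-negative. Whether to clamp was an
  open choice; clamping is the conservative one.
- If a tagging window holds as many predictors as observations (impossible
  at biobank scale, possible on desk-scale panels), the $n/10$ predictors
  with largest marginal correlation are kept and the fit is flagged
  `"screened"`.
- A window with no genotyped variant yields $\rho^2 = 0$ with a warning; a
  constant dosage column (no carriers in the sample) yields 0 with a flag,
  and a constant *true* column in `imputation_r2()` is a distinct error
  class rather than a silent 0.

## The alpha model and its attenuated variant

`sample_alpha_effects()` draws
$\beta_i \mid p_i \sim N(0, \sigma^2_{g,\alpha} [2p_i(1-p_i)]^\alpha)$ over
$\alpha \in [-1.5, 0]$ (values outside warn rather than error). The
*realized* $\sum \beta_i^2$ is rescaled to the target $h^2$ exactly — not
just in expectation — so the capture-metric identities above are exact and
testable to machine precision; $\sigma^2_{g,\alpha}$ is drawn uniformly on
$[0,1]$ and reported after rescaling for transparency.

The attenuated model multiplies prior variances by
$w_i = \min(1, (p_i/p_0)^\tau)$ before renormalization (fixed point on the
variance scale, tolerance $10^{-10}$, 100-iteration cap). The weighting
function in the original analysis is not fully specified in public text;
this multiplicative cap is the package's own declared scheme satisfying the
intended property (reduced rare-variant contribution), not a
reconstruction. $\tau = 0$ reproduces the plain alpha model draw-for-draw
under the same seed.

`capture_proportion_curve()` reports $E[h^2_G/h^2]$ and $E[h^2_I/h^2]$
across an $\alpha$ grid, either by Monte-Carlo averaging over effect draws
(`n_rep > 0`) or by the analytic expectation
$\sum_i c_i w_i / \sum_i w_i$ with $w_i = (2p_iq_i)^\alpha$ (`n_rep = 0`),
which is noise-free and strictly monotone when capture quality rises with
MAF.

## Best-fit alpha and ceiling reports

GWAS-based heritability estimates are usually derived from genotyped
variants plus well-imputed common variants, so $h^2_G$ should approximate
them given the right $\alpha$. `best_fit_alpha()` solves
$h^2_{\mathrm{total}} \cdot \mathrm{prop}_G(\alpha) = \mathrm{median}(h^2_{\mathrm{GWAS}})$
by bisection (tolerance $10^{-4}$) on the tabulated curve, using monotone
linear interpolation — an isotonic pass absorbs Monte-Carlo wiggle, and
decoupling the solver from simulation noise was the reason for tabulating
rather than re-simulating inside the root-finder. A median outside the
attainable range errors with the attainable interval, rather than
extrapolating.

`ceiling_report()` then emits three ceilings per disease:
$\mathrm{AUC}_{\mathrm{twin}}$ from total (twin-study) heritability,
$\mathrm{AUC}_{\mathrm{GWAS}}$ from the median GWAS estimate, and
$\mathrm{AUC}_{\mathrm{imputed}}$ from
$h^2_{\mathrm{twin}} \cdot \mathrm{prop}_I(\hat\alpha)$. The packaged
`disease_parameters()` table carries twin heritabilities of 0.55 (CAD),
0.72 (T2D), 0.27 (breast cancer), 0.49 (AD, APOE excluded), 0.70 (asthma)
and 0.75 (BMI); its prevalences and five-estimate GWAS heritability lists
are **flagged placeholders** — registry prevalences and real
summary-statistic heritability estimates are scalar inputs the user must
supply for substantive use.

## GWAS machinery

$N_{\mathrm{eff}} = 4/(1/N_{\mathrm{case}} + 1/N_{\mathrm{control}})$ is
reported both raw and rounded to the nearest integer (the rounded form is
what published study tables print). The per-variant filter keeps variants
with $N_{\mathrm{eff,SNP}}$ in 50%–110% of the expected maximum, which
defaults to the study-level maximum because the reference point is not
standardized across pipelines. AUC uses the Mann–Whitney rank statistic
with midrank ties; its variance uses Hanley–McNeil by default (the
estimator behind published AUC variances is typically unnamed) with DeLong
behind a flag, and the all-pairs concordance oracle plus an independent
ROC implementation cross-check both in the tests. Meta-analysis is plain
inverse-variance pooling. Top-stratum odds ratios use a 2×2 table with the
Woolf CI; ties at the stratum cutoff are broken by seeded rank so the
stratum size is exact, and zero cells error with the cell named.

The convergence simulation is deliberately an *emulation* of
summary-statistic PRS training, valid in the independent-variant regime:
marginal estimates $\hat\beta_i = \beta_i + N(0, 1/n)$, infinitesimal
posterior-mean shrinkage $\gamma = \hat\beta \cdot h^2/(h^2 + m/n)$, and
scoring of an independent Gaussian test cohort. It is not an
LD-aware Gibbs-sampling PRS method; its purpose is the shape and asymptote
of the accuracy–sample-size curve, which it reproduces (terminal AUC within
0.01 of `auc_max` at $n = 100\,m/h^2$ with $m = 2000$, $h^2 = 0.3$,
$K = 0.1$, 20 replicates — the sizes the test suite runs).

## The synthetic-data generator

The generator's defaults are the package's study conditions, fixed once:

- **MAF spectrum**: density $\propto 1/p$ on $[10^{-4}, 0.5]$ (log-uniform),
  mimicking a rare-dominated sequencing spectrum; a uniform option exists
  for controlled experiments.
- **LD**: haplotypes from a latent Gaussian AR(1) field; the latent
  correlation between consecutive variants is
  `ld_strength^(gap/mean_spacing)` (default 0.95 at the mean spacing of
  25 kb), reset at 100-variant block boundaries. Thresholding at the
  frequency-matched quantile turns latent values into haplotype alleles;
  two haplotypes sum to dosage. LD therefore decays with physical distance
  and is cheap and reproducible.
- **Array design**: `geno_maf_biased(0.05)` puts every variant with
  MAF ≥ 5% on the array, the common-variant bias of real arrays.
- **Imputation**: target $r^2$ is logistic in $\log_{10}$ MAF (constants
  fixed so the mean target over off-array variants is ≈ 0.50), and the
  imputed dosage is $r \cdot z_{\mathrm{true}} + \sqrt{1-r^2}\,\varepsilon$
  rescaled to dosage units and clipped to $[0,2]$. Clipping attenuates the
  correlation and shifts the mean, so a few recalibration passes adjust the
  pre-clip correlation and re-center the column until the realized $r^2$
  and expected allele dosage match their targets; both properties are
  asserted within sampling error in the tests.
- **Phenotypes**: liability = standardized genetic score +
  $N(0, 1-h^2)$, case iff above $T$.
- **Seeds**: one top-level seed fans out to named substreams
  (`substream_seed`), so regenerating one component never perturbs another.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: coalescent haplotype structure (a rare variant's
dosage correlation with common array variants is bounded near
MAF$_\mathrm{rare}$/MAF$_\mathrm{common}$ under the threshold model, so the
panel-wide mean $\rho^2$ on the default panel is ≈ 0.08–0.12, well below
the ≈ 0.5 mean imputation quality; real cohorts show a smaller gap because
real haplotype sharing tags rare variants better), selection-driven
LD–effect coupling, annotation-dependent causal enrichment, phasing, and
reference-panel imputation algorithms. The qualitative structure that the
downstream analyses rely on — imputation quality above array tagging, both
rising with MAF, positively correlated with each other (≈ 0.7 on the
default panel), and capture proportions increasing in $\alpha$ — is
reproduced and asserted.

Annotation tracks are interval sets with coverage fractions log-spaced
across a requested range (real annotation compendia span
0.001%–65% coverage); each track anchors one interval on a variant so
every track is testable. Coordinates are 1-based inclusive internally;
BED files are read and written as 0-based half-open with explicit
conversion.

## Enrichment regressions

`univariate_enrichment()` regresses per-variant imputation quality on a
binary annotation indicator. For binary predictors the unstandardized slope
*is* the in/out group-mean difference (asserted on every fit), and the
standardized coefficient is the Pearson correlation — "standardized" was an
open choice, resolved as z-scoring both sides, with the unstandardized
slope also reported. The adjusted model conditions on gene-structure
indicator columns, drops collinear adjusters (reported), and errors if the
focal indicator itself is collinear. Multiple testing defaults to
Bonferroni at $0.05/K$ (BH available); the choice of test behind
rare-fraction contrasts is a two-proportion z-test. All three choices are
documented rather than inherited, because the upstream analysis names none
of them. Degenerate inputs (a track covering all variants or none) are
distinct error classes, not silent zeros.

## Problem sizes and runtime

The default demonstration sizes — 2,000 × 2,000 calibrated panels,
$5\times10^5$ individuals per liability-simulation cell, 20-replicate
convergence curves up to $n = 6.7\times10^5$, 50,000-variant enrichment
scans, 500-replicate null calibrations at 1,099 tracks — were chosen so the
whole suite runs in about a minute on one CPU while keeping Monte-Carlo
error comfortably inside every asserted tolerance. All are arguments, not
constants.

## Known limitations

- $\rho^2$ and $r^2_{\mathrm{imput}}$ are sample quantities on the
  generated cohort; no shrinkage for estimation noise is applied.
- The convergence emulation assumes independent variants; with LD the
  marginal-estimator noise model and the shrinkage factor are both wrong in
  detail (use it for shapes and asymptotes, not absolute rates).
- The liability phenotype builds its genetic score on standardized
  dosages; under strong LD the realized score variance can exceed the
  nominal $h^2$, so prevalence calibration is exact only for weak-LD or
  independent panels.
- Twin-study heritabilities are upper-bound proxies for additive variance;
  everything downstream inherits that bias.
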