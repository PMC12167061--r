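# prsceiling

Tools for studying how polygenic risk score (PRS) discrimination converges
with GWAS sample size, and what bounds it.

PRS accuracy for common diseases has grown with GWAS sample size but is
flattening: even an infinitely large GWAS cannot recover genetic variance
carried by variants the study never observes. `prsceiling` implements the
quantitative machinery behind that statement:

- **Captured heritability.** For a trait with liability-scale heritability
  h² = Σᵢ βᵢ² (βᵢ the effect of standardized variant i), the share
  recoverable from a genotyping array is
  h²_G = Σ_{i∈S} βᵢ² + Σ_{j∉S} βⱼ² ρⱼ², where S is the genotyped subset and
  ρⱼ² is the adjusted R² of untyped variant j on its genotyped neighbours
  (±1.5 Mb). The share recoverable from all imputed variants is
  h²_I = Σᵢ βᵢ² r²ᵢₘₚᵤₜ,ᵢ with r²ᵢₘₚᵤₜ the squared correlation between
  sequenced and imputed dosage.
- **The alpha model.** Effects are drawn βᵢ ~ N(0, σ²_{g,α} · [2pᵢ(1−pᵢ)]^α):
  α = 0 spreads heritability evenly across variants, negative α concentrates
  it on rare, poorly tagged variants. An attenuated variant of the model
  damps rare-variant contributions by w = min(1, (p/p₀)^τ). A "best-fit" α
  is calibrated so that h²_G matches the median of GWAS-based heritability
  estimates.
- **The liability-threshold AUC ceiling.** For prevalence K and captured
  heritability h², the maximum achievable AUC is
  Φ( (i−v)·h² / √( h²[(1 − h²·i·(i−T)) + (1 − h²·v·(v−T))] ) ) with
  T = Φ⁻¹(1−K), z = φ(T), i = z/K, v = −z/(1−K), validated in-package
  against liability simulation.
- **GWAS plumbing.** Effective sample sizes Neff = 4/(1/Ncase + 1/Nctrl),
  per-variant Neff filters (50%–110% of the expected maximum), PRS = γᵗX
  scoring with allele-flip handling, rank-statistic AUC with Hanley–McNeil
  (or DeLong) variance, inverse-variance AUC meta-analysis, top-stratum
  odds ratios, and simulated GWAS→shrinkage→scoring convergence curves.
- **Annotation enrichment.** OLS regressions of imputation quality on
  functional-annotation indicators (optionally adjusted for gene-structure
  categories), Bonferroni control, and MAF-by-annotation contrasts.

Everything runs on a bundled synthetic-data generator (rare-skewed MAF
spectrum, distance-decaying LD, MAF-biased array design, MAF-dependent
imputation quality, liability-threshold phenotypes), so the full analysis
is testable on a desktop with no data access.

## Worked example

```r
library(prsceiling)

# a calibrated synthetic cohort: 2,000 individuals x 2,000 variants,
# common variants on the array, MAF-dependent imputation quality
panel <- calibrated_panel(n = 2000, m = 2000, seed = 1)
cap   <- capture_table(panel)
glance(cap)
#> # A tibble: 1 × 6
#>       m n_genotyped mean_r2_imput mean_rho2 cor_rho2_r2 window_bp
#> 1  2000         542         0.507    0.0814       0.696   1500000

# expected capture proportions across the alpha grid
curve <- capture_proportion_curve(cap, alphas = seq(-1.5, 0, 0.25),
                                  n_rep = 100, seed = 1)
curve
#>   alpha  prop_G prop_I
#> 1 -1.5  0.00627  0.118
#> ...
#> 7  0    0.328    0.640

# best-fit alpha: which exponent makes the array-captured heritability
# match the median GWAS-based estimate?
fit <- best_fit_alpha(h2_total = 0.55,
                      h2_gwas_estimates = c(0.10, 0.12, 0.14, 0.17, 0.20),
                      curve = curve)
fit$alpha_fit
#> [1] -0.103

# AUC ceilings at prevalence 0.06
auc_max(0.55, 0.06)          # from total (twin) heritability: 0.906
auc_max(fit$h2_target, 0.06) # from GWAS-captured heritability: 0.719
```

Mean imputation quality (0.51) exceeds mean array tagging (0.08) and the
two are positively coupled through MAF (cor 0.70), so `prop_I` dominates
`prop_G` at every α and both rise steeply as α → 0: the more heritability
sits on common variants, the more of it existing panels capture. The gap
between the two AUC ceilings is the headroom that denser variant coverage
(more imputed or sequenced variants) could unlock; `autoplot()` methods
exist for capture curves, convergence curves, ceiling reports and
enrichment scans.

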