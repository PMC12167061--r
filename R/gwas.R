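#' Effective sample size of a case/control GWAS
#'
#' `Neff = 4 / (1/Ncase + 1/Ncontrol)`, the harmonic-mean rescaling that
#' puts cohorts with unequal case/control counts on a common unit (a
#' balanced study of `n` cases and `n` controls has `Neff = 2n`).
#' Vectorised.
#'
#' @param n_case,n_control Positive counts.
#' @return The raw (unrounded) effective sample size; round for reporting.
#' @examples
#' effective_sample_size(5000, 50000)    # 18181.8 -> reported as 18182
#' effective_sample_size(1000, 1000)     # 2000
#' @export
effective_sample_size <- function(n_case, n_control) {
  if (any(n_case <= 0) || any(n_control <= 0)) {
    abort("case and control counts must be positive")
  }
  4 / (1 / n_case + 1 / n_control)
}

#' Build a GWAS study table
#'
#' @param label Study labels.
#' @param n_case,n_control Counts.
#' @return A tibble with `label`, `n_case`, `n_control`, `n_eff` (raw) and
#'   `n_eff_reported` (nearest integer).
#' @export
gwas_study <- function(label, n_case, n_control) {
  neff <- effective_sample_size(n_case, n_control)
  tibble(label = label, n_case = n_case, n_control = n_control,
         n_eff = neff, n_eff_reported = as.integer(round(neff)))
}

#' Per-variant effective-sample-size filter
#'
#' Keeps variants whose per-variant `Neff` lies within `[lower, upper]`
#' times the expected maximum (default 50%-110%), dropping variants absent
#' from many contributing cohorts or with inflated counts, both of which
#' miscalibrate regression coefficients.
#'
#' @param neff_snp Per-variant effective sample sizes.
#' @param expected_max Reference maximum; defaults to `max(neff_snp)`.
#' @param lower,upper Fractional bounds.
#' @return Logical keep-mask with attributes `n_removed`, `threshold_lo`,
#'   `threshold_hi`.
#' @export
per_variant_neff_filter <- function(neff_snp, expected_max = max(neff_snp),
                                    lower = 0.5, upper = 1.1) {
  if (expected_max <= 0) abort("expected_max must be positive")
  keep <- neff_snp >= lower * expected_max & neff_snp <= upper * expected_max
  structure(keep, n_removed = sum(!keep),
            threshold_lo = lower * expected_max,
            threshold_hi = upper * expected_max)
}

#' Polygenic score from per-variant weights
#'
#' `PRS = gamma' X` per individual. Allele orientation is resolved through
#' the optional `flip` column of the weights: a flipped variant is scored
#' on `2 - dosage` (counting the other allele).
#'
#' @param weights Tibble with `gamma` (length-M) and optionally `flip`
#'   (logical).
#' @param panel A `genotype_panel`.
#' @param dosage_source `"imputed"`, `"true"`, or `"genotyped"` (genotyped
#'   variants only, others contribute zero).
#' @return Numeric score vector, one value per individual.
#' @export
prs_score <- function(weights, panel,
                      dosage_source = c("imputed", "true", "genotyped")) {
  dosage_source <- match.arg(dosage_source)
  stopifnot(inherits(panel, "genotype_panel"))
  m <- nrow(panel$meta)
  if (nrow(weights) != m) abort("weights not aligned with panel variants")
  x <- switch(dosage_source,
    imputed = panel$imputed_dosage %||%
      abort("panel has no imputed dosages"),
    true = panel$true_dosage,
    genotyped = panel$true_dosage
  )
  gamma <- weights$gamma
  if (dosage_source == "genotyped") gamma[!panel$meta$is_genotyped] <- 0
  flip <- if ("flip" %in% names(weights)) weights$flip else rep(FALSE, m)
  if (any(is.na(flip))) abort("unresolvable allele orientation (NA flip)")
  g_eff <- ifelse(flip, -gamma, gamma)
  offset <- 2 * sum(gamma[flip])
  drop(x %*% g_eff) + offset
}

#' Simulated marginal GWAS effect estimates
#'
#' Desk-scale stand-in for summary-statistic training in the
#' independent-variant regime: the estimate for each standardized variant
#' is the true effect plus `N(0, 1/n_gwas)` sampling noise (the marginal
#' estimator's asymptotic variance).
#'
#' @param effects An `effect_profile`.
#' @param n_gwas Training-study sample size (`>= 1`).
#' @param seed Top-level seed (`"gwas_effects"` substream).
#' @return Numeric vector of estimated effects.
#' @export
simulate_gwas_effects <- function(effects, n_gwas, seed = 1) {
  if (n_gwas < 1) abort("n_gwas must be >= 1")
  set_stream_seed(seed, "gwas_effects")
  effects$beta + rnorm(nrow(effects), 0, sqrt(1 / n_gwas))
}

#' Infinitesimal shrinkage weights
#'
#' Posterior-mean shrinkage of noisy marginal estimates under an
#' infinitesimal prior: `gamma = b * beta_hat` with
#' `b = h2 / (h2 + m / n_gwas)`. Emulates LD-aware Bayesian PRS weighting
#' in the independent-variant regime.
#'
#' @param beta_hat Estimated effects.
#' @param n_gwas Training sample size.
#' @param m_variants Number of variants.
#' @param h2 Heritability in `[0, 1]`.
#' @return A tibble of `PrsWeights` (`index`, `gamma`) with attribute
#'   `shrinkage`.
#' @export
shrink_weights <- function(beta_hat, n_gwas, m_variants, h2) {
  if (h2 < 0 || h2 > 1) abort("h2 must be in [0, 1]")
  b <- if (h2 == 0) 0 else h2 / (h2 + m_variants / n_gwas)
  structure(tibble(index = seq_along(beta_hat), gamma = b * beta_hat),
            shrinkage = b)
}
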