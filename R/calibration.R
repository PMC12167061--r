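curve_interp <- function(curve, col) {
  stopifnot(inherits(curve, "capture_curve"))
  x <- curve$alpha
  y <- curve[[col]]
  # enforce monotone non-decreasing tabulated values before linear
  # interpolation (Monte-Carlo curves can wiggle slightly)
  y <- isoreg(x, y)$yf
  approxfun(x, y, rule = 2)
}

#' Best-fit alpha matching GWAS-based heritability
#'
#' Solves for the frequency-coupling exponent `alpha` at which the
#' heritability captured by genotyped variants, `h2_total * prop_G(alpha)`,
#' equals the median of the supplied GWAS-based heritability estimates.
#' `prop_G(alpha)` is taken from a tabulated [capture_proportion_curve()]
#' with monotone linear interpolation, and the root is found by bisection.
#'
#' @param h2_total Total (e.g. twin-study) liability-scale heritability.
#' @param h2_gwas_estimates Numeric vector of GWAS-based heritability
#'   estimates (typically five); the median is matched.
#' @param curve A `capture_curve` from [capture_proportion_curve()].
#' @param bracket Search interval for `alpha`.
#' @param tol Bisection tolerance on `alpha`.
#' @return One-row tibble: `alpha_fit`, `h2_target` (the median),
#'   `h2_at_fit`, `attainable_lo`, `attainable_hi`, `iterations`.
#'   If the median lies outside the attainable range the error names the
#'   attainable interval.
#' @export
best_fit_alpha <- function(h2_total, h2_gwas_estimates, curve,
                           bracket = c(-1.5, 0), tol = 1e-4) {
  f <- curve_interp(curve, "prop_G")
  med <- median(h2_gwas_estimates)
  lo <- bracket[1]
  hi <- bracket[2]
  f_lo <- h2_total * f(lo)
  f_hi <- h2_total * f(hi)
  if (med < min(f_lo, f_hi) - 1e-12 || med > max(f_lo, f_hi) + 1e-12) {
    abort(sprintf(
      "median GWAS h2 (%.4g) outside attainable range [%.4g, %.4g] over alpha in [%g, %g]",
      med, min(f_lo, f_hi), max(f_lo, f_hi), lo, hi
    ), class = "prsceiling_alpha_unattainable")
  }
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if ((h2_total * f(mid) - med) * (f_lo - med) > 0) {
      lo <- mid
      f_lo <- h2_total * f(lo)
    } else {
      hi <- mid
    }
    it <- it + 1L
    if (it > 200L) break
  }
  a <- (lo + hi) / 2
  tibble(alpha_fit = a, h2_target = med, h2_at_fit = h2_total * f(a),
         attainable_lo = min(h2_total * f(bracket[1]), h2_total * f(bracket[2])),
         attainable_hi = max(h2_total * f(bracket[1]), h2_total * f(bracket[2])),
         iterations = it)
}

#' Packaged disease parameter defaults
#'
#' Twin-study liability-scale heritabilities for the six diseases the
#' package's worked examples follow: coronary artery disease 0.55, type 2
#' diabetes 0.72, breast cancer 0.27, Alzheimer disease (APOE excluded)
#' 0.49, asthma 0.70, BMI/obesity 0.75. Prevalence values and the five
#' per-disease GWAS-based heritability estimates are editable placeholders
#' (`placeholder = TRUE`), not sourced estimates: real analyses should
#' overwrite them with registry prevalences and summary-statistic-based
#' heritability estimates.
#'
#' @return A tibble with `label`, `prevalence`, `h2_twin`, `h2_gwas`
#'   (list-column of five estimates), `placeholder`.
#' @export
disease_parameters <- function() {
  tibble(
    label = c("CAD", "T2D", "breast_cancer", "AD", "asthma", "BMI"),
    prevalence = c(0.06, 0.10, 0.13, 0.10, 0.08, 0.30),
    h2_twin = c(0.55, 0.72, 0.27, 0.49, 0.70, 0.75),
    h2_gwas = list(
      c(0.14, 0.18, 0.22, 0.26, 0.30),
      c(0.18, 0.24, 0.28, 0.34, 0.40),
      c(0.10, 0.13, 0.15, 0.17, 0.20),
      c(0.08, 0.12, 0.16, 0.20, 0.24),
      c(0.15, 0.20, 0.25, 0.30, 0.35),
      c(0.18, 0.22, 0.27, 0.32, 0.38)
    ),
    placeholder = TRUE
  )
}

#' Per-disease AUC ceiling report
#'
#' For each disease, fits the best-fit `alpha` matching the median
#' GWAS-based heritability, then reports three AUC ceilings: from the twin
#' heritability (`auc_twin`), from the median GWAS heritability
#' (`auc_gwas`), and from the twin heritability scaled by the imputed
#' capture proportion at the fitted alpha (`auc_imputed`, with
#' `h2_imputed = h2_twin * prop_I(alpha_fit)`).
#'
#' @param config A tibble like [disease_parameters()] (`label`,
#'   `prevalence`, `h2_twin`, `h2_gwas` list-column).
#' @param curve A `capture_curve` giving `prop_G` and `prop_I` vs alpha.
#' @return A `ceiling_report` tibble, one row per disease.
#' @export
ceiling_report <- function(config, curve) {
  if (!nrow(config)) {
    out <- tibble(label = character(), K = numeric(), h2_twin = numeric(),
                  h2_gwas_median = numeric(), alpha_fit = numeric(),
                  h2_imputed = numeric(), auc_twin = numeric(),
                  auc_gwas = numeric(), auc_imputed = numeric())
    return(structure(out, class = c("ceiling_report", class(out))))
  }
  fI <- curve_interp(curve, "prop_I")
  rows <- pmap(config[c("label", "prevalence", "h2_twin", "h2_gwas")],
               function(label, prevalence, h2_twin, h2_gwas) {
    fit <- best_fit_alpha(h2_twin, h2_gwas, curve)
    h2_med <- median(h2_gwas)
    h2_imp <- h2_twin * fI(fit$alpha_fit)
    tibble(
      label = label, K = prevalence, h2_twin = h2_twin,
      h2_gwas_median = h2_med, alpha_fit = fit$alpha_fit,
      h2_imputed = h2_imp,
      auc_twin = auc_max(h2_twin, prevalence),
      auc_gwas = auc_max(h2_med, prevalence),
      auc_imputed = auc_max(h2_imp, prevalence)
    )
  })
  out <- list_rbind(rows)
  structure(out, class = c("ceiling_report", class(out)))
}
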