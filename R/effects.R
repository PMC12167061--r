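new_effect_profile <- function(tbl, alpha, sigma2_g_alpha, h2_target,
                               attenuation = NULL) {
  structure(
    tbl,
    alpha = alpha, sigma2_g_alpha = sigma2_g_alpha, h2_target = h2_target,
    attenuation = attenuation,
    class = c("effect_profile", class(tbl))
  )
}

effects_core <- function(maf, alpha, h2_target, weights, attenuation,
                         seed) {
  if (!length(maf)) abort("empty maf vector")
  if (h2_target < 0 || h2_target > 1) abort("h2_target must be in [0, 1]")
  if (alpha < -1.5 || alpha > 0) {
    warn("alpha outside the usual [-1.5, 0] grid")
  }
  m <- length(maf)
  set_stream_seed(seed, "effects")
  sigma2 <- runif(1)  # prior scale, recorded post-rescaling
  v <- sigma2 * (2 * maf * (1 - maf))^alpha * weights
  z <- rnorm(m)
  beta <- sqrt(v) * z
  s <- sum(beta^2)
  if (h2_target == 0 || s == 0) {
    beta <- rep(0, m)
    scale2 <- 0
  } else {
    scale2 <- h2_target / s
    beta <- beta * sqrt(scale2)
  }
  sigma2_post <- sigma2 * scale2
  tbl <- tibble(
    index = seq_len(m),
    maf = maf,
    beta = beta,
    prior_variance = sigma2_post * (2 * maf * (1 - maf))^alpha * weights
  )
  new_effect_profile(tbl, alpha = alpha, sigma2_g_alpha = sigma2_post,
                     h2_target = h2_target, attenuation = attenuation)
}

#' Sample per-variant effects under the alpha model
#'
#' Draws standardized-scale effects `beta_i ~ N(0, sigma2 * [2 p_i (1 -
#' p_i)]^alpha)`, the classical frequency-coupled prior: `alpha = 0` gives
#' every variant the same expected contribution to heritability, while
#' negative `alpha` gives rare variants larger per-allele effects. The
#' realized sum of squared effects is rescaled to equal `h2_target` exactly,
#' so `h2 = sum(beta^2)` holds as an identity (beta is the effect on the
#' standardized genotype; the per-allele effect is `beta / sqrt(2pq)`).
#'
#' @param maf Length-M vector of allele frequencies.
#' @param alpha Frequency-coupling exponent, usually in `[-1.5, 0]`.
#' @param h2_target Liability-scale heritability in `[0, 1]`.
#' @param seed Top-level seed (`"effects"` substream).
#' @return An `effect_profile` tibble (`index`, `maf`, `beta`,
#'   `prior_variance`) with attributes `alpha`, `sigma2_g_alpha` (recorded
#'   after rescaling), `h2_target`.
#' @examples
#' eff <- sample_alpha_effects(runif(100, 0.01, 0.5), alpha = -1,
#'                             h2_target = 0.5, seed = 1)
#' sum(eff$beta^2)
#' @export
sample_alpha_effects <- function(maf, alpha, h2_target, seed = 1) {
  effects_core(maf, alpha, h2_target, weights = rep(1, length(maf)),
               attenuation = NULL, seed = seed)
}

#' Sample effects under the attenuated alpha model
#'
#' Like [sample_alpha_effects()] but damping rare-variant contributions:
#' prior variances are multiplied by `w_i = min(1, (p_i / p0)^tau)` and
#' renormalized to `h2_target` by fixed-point iteration (relative change of
#' all variances below `tol`). `tau = 0` reproduces the plain alpha model
#' exactly (same draws under the same seed).
#'
#' @inheritParams sample_alpha_effects
#' @param p0 MAF pivot in `(0, 0.5]` below which attenuation applies.
#' @param tau Attenuation exponent, `>= 0`.
#' @param tol Fixed-point tolerance.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @export
sample_attenuated_effects <- function(maf, alpha, h2_target, p0, tau,
                                      tol = 1e-10, max_iter = 100,
                                      seed = 1) {
  if (p0 <= 0 || p0 > 0.5) abort("p0 must be in (0, 0.5]")
  if (tau < 0) abort("tau must be >= 0")
  w <- pmin(1, (maf / p0)^tau)
  if (sum(w) == 0) abort("attenuation weights all zero")
  prof <- effects_core(maf, alpha, h2_target, weights = w,
                       attenuation = list(p0 = p0, tau = tau, tol = tol),
                       seed = seed)
  # renormalization fixed point on the prior variances (converges once the
  # scale is stable; kept explicit so non-convergence is detectable)
  v <- prof$prior_variance
  if (sum(v) > 0 && h2_target > 0) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      v_new <- v * (h2_target / sum(v))
      if (max(abs(v_new - v) / pmax(v, 1e-300)) < tol) {
        v <- v_new
        converged <- TRUE
        break
      }
      v <- v_new
    }
    if (!converged) abort("attenuation renormalization did not converge")
    prof$prior_variance <- v
  }
  prof
}

#' @export
print.effect_profile <- function(x, ...) {
  at <- attr(x, "attenuation")
  cat(sprintf(
    "<effect_profile> M = %d, alpha = %g, h2 = %g%s\n",
    nrow(x), attr(x, "alpha"), attr(x, "h2_target"),
    if (is.null(at)) "" else sprintf(", attenuated (p0 = %g, tau = %g)",
                                     at$p0, at$tau)
  ))
  NextMethod()
}
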