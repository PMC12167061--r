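#' Simulate liability-threshold case/control phenotypes
#'
#' The liability is the standardized genetic score (dosages standardized
#' column-wise, weighted by the effect profile) plus independent
#' `N(0, 1 - h2)` noise; an individual is a case iff the liability exceeds
#' the prevalence threshold `T = qnorm(1 - K)`. Under weak LD the liability
#' has unit variance in expectation and the case fraction matches `K`.
#'
#' @param panel A `genotype_panel`.
#' @param effects An `effect_profile` aligned with the panel.
#' @param k_prev Disease prevalence `K` in `(0, 1)`.
#' @param seed Top-level seed (`"phenotype"` substream).
#' @return A `phenotype_set` tibble (`individual`, `genetic_score`,
#'   `liability`, `case`) with attributes `prevalence_target`, `h2_used`,
#'   `threshold`.
#' @export
simulate_liability_phenotype <- function(panel, effects, k_prev, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (k_prev <= 0 || k_prev >= 1) abort("prevalence must be in (0, 1)")
  beta <- effects$beta
  if (length(beta) != nrow(panel$meta)) {
    abort("effect profile does not match panel size")
  }
  h2 <- sum(beta^2)
  if (h2 > 1 + 1e-12) abort("h2 = sum(beta^2) exceeds 1")
  h2 <- min(h2, 1)

  x <- panel$true_dosage
  mu <- colMeans(x)
  sdv <- sqrt(colSums(sweep(x, 2, mu)^2) / (nrow(x) - 1))
  w <- ifelse(sdv > 0, beta / ifelse(sdv > 0, sdv, 1), 0)
  g <- drop(x %*% w) - sum(mu * w)

  set_stream_seed(seed, "phenotype")
  liab <- g + rnorm(panel$n_individuals, 0, sqrt(max(0, 1 - h2)))
  thr <- qnorm(1 - k_prev)
  out <- tibble(
    individual = seq_len(panel$n_individuals),
    genetic_score = g,
    liability = liab,
    case = liab > thr
  )
  structure(out, prevalence_target = k_prev, h2_used = h2, threshold = thr,
            class = c("phenotype_set", class(out)))
}
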