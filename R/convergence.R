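#' PRS accuracy as a function of GWAS sample size
#'
#' Simulates, for each training sample size in `n_grid`, the full pipeline
#' in the independent-variant regime: noisy marginal effect estimates
#' ([simulate_gwas_effects()]), infinitesimal shrinkage
#' ([shrink_weights()]), scoring of an independent test cohort of `n_test`
#' individuals drawn from the liability-threshold model at prevalence `K`,
#' and AUC estimation ([auc_with_se()]). Averaged over `reps` replicates.
#' The curve rises non-linearly with `n_gwas` and converges to the
#' liability-threshold ceiling `auc_max(h2, K)`.
#'
#' @param effects An `effect_profile` (its `h2_target` and size set the
#'   genetic architecture).
#' @param K Prevalence.
#' @param n_grid Increasing vector of training sample sizes.
#' @param n_test Test-cohort size per replicate.
#' @param reps Replicates per grid point.
#' @param seed Top-level seed.
#' @return A `convergence_curve` tibble: `n_gwas`, `auc_mean`, `auc_se`
#'   (SE of the mean over replicates), `auc_ceiling`.
#' @export
convergence_curve <- function(effects, K, n_grid, n_test = 5000, reps = 20,
                              seed = 1) {
  if (is.unsorted(n_grid, strictly = FALSE)) {
    abort("n_grid must be increasing")
  }
  m <- nrow(effects)
  beta <- effects$beta
  h2 <- sum(beta^2)
  thr <- qnorm(1 - K)
  ceiling_auc <- auc_max(h2, K)

  aucs <- matrix(NA_real_, reps, length(n_grid))
  for (r in seq_len(reps)) {
    set_stream_seed(seed, paste0("conv_test_", r))
    x <- matrix(rnorm(n_test * m), n_test, m)
    g <- drop(x %*% beta)
    liab <- g + rnorm(n_test, 0, sqrt(max(0, 1 - h2)))
    case <- liab > thr
    if (!any(case) || all(case)) next
    for (k in seq_along(n_grid)) {
      bh <- simulate_gwas_effects(
        effects, n_grid[k],
        seed = substream_seed(seed, paste0("conv_train_", r, "_", k))
      )
      w <- shrink_weights(bh, n_grid[k], m, h2)
      s <- drop(x %*% w$gamma)
      aucs[r, k] <- auc_with_se(s, case)$auc
    }
  }
  out <- tibble(
    n_gwas = n_grid,
    auc_mean = colMeans(aucs, na.rm = TRUE),
    auc_se = apply(aucs, 2, function(a) {
      a <- a[!is.na(a)]
      sd(a) / sqrt(length(a))
    }),
    auc_ceiling = ceiling_auc
  )
  structure(out, h2 = h2, K = K, reps = reps,
            class = c("convergence_curve", class(out)))
}
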