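#' Imputation quality of a single variant
#'
#' Squared Pearson correlation between the true (sequenced) and imputed
#' dosage of one variant — identical to the R-squared of the univariate
#' regression of one on the other — clamped to `[0, 1]`.
#'
#' @param true_col True dosage vector.
#' @param imputed_col Imputed dosage vector, same length (`>= 3`).
#' @return Scalar r-squared. A constant imputed column gives 0 (no signal);
#'   a constant true column is an error of class
#'   `prsceiling_constant_variant`.
#' @export
imputation_r2 <- function(true_col, imputed_col) {
  if (length(true_col) != length(imputed_col) || length(true_col) < 3) {
    abort("dosage vectors must have equal length >= 3")
  }
  if (sd(true_col) == 0) {
    abort("true dosage is constant: r2 undefined",
          class = "prsceiling_constant_variant")
  }
  if (sd(imputed_col) == 0) return(0)
  min(1, max(0, cor(true_col, imputed_col)^2))
}

rho2_fit <- function(y, x_mat, n_keep_overflow = NULL) {
  n <- length(y)
  p <- ncol(x_mat)
  flag <- "ok"
  if (p == 0) {
    return(list(rho2 = 0, flag = "no_predictor"))
  }
  if (sd(y) == 0) {
    return(list(rho2 = 0, flag = "constant_variant"))
  }
  if (p >= n - 2) {
    k <- n_keep_overflow %||% max(1L, floor(n / 10))
    marg <- abs(suppressWarnings(cor(y, x_mat)))
    marg[is.na(marg)] <- 0
    x_mat <- x_mat[, order(-marg)[seq_len(min(k, p))], drop = FALSE]
    p <- ncol(x_mat)
    flag <- "screened"
  }
  keep <- apply(x_mat, 2, sd) > 0
  x_mat <- x_mat[, keep, drop = FALSE]
  p <- ncol(x_mat)
  if (p == 0) return(list(rho2 = 0, flag = "no_predictor"))
  fit <- stats::lm.fit(cbind(1, x_mat), y)
  rank_p <- fit$rank - 1L
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - 1 - rank_p)
  list(rho2 = min(1, max(0, adj)), flag = flag)
}

#' Array-tagging quality of an untyped variant
#'
#' Adjusted R-squared of the multiple regression of an untyped variant's
#' true dosage on all genotyped dosages within a physical window (default
#' +/- 1.5 Mb), i.e. how well the array tags the variant through LD.
#' Negative adjusted values are clamped to 0. If the window holds no
#' genotyped variant the result is 0 with a warning; if it holds `>= n - 2`
#' predictors, the `n/10` with largest marginal correlation are used
#' (flagged `"screened"` in the `flag` attribute).
#'
#' @param panel A `genotype_panel` with a genotyped subset designated.
#' @param j Index of an untyped variant.
#' @param window_bp Window half-width in base pairs.
#' @return Scalar adjusted R-squared with attribute `flag`.
#' @export
tagging_rho2 <- function(panel, j, window_bp = 1.5e6) {
  stopifnot(inherits(panel, "genotype_panel"))
  meta <- panel$meta
  if (meta$is_genotyped[j]) abort("variant j is genotyped; rho2 = 1 by convention")
  in_window <- meta$is_genotyped &
    meta$chrom == meta$chrom[j] &
    abs(meta$pos - meta$pos[j]) <= window_bp
  if (!any(in_window)) {
    warn("no genotyped variant in window; rho2 = 0")
    return(structure(0, flag = "no_predictor"))
  }
  fit <- rho2_fit(panel$true_dosage[, j],
                  panel$true_dosage[, in_window, drop = FALSE])
  structure(fit$rho2, flag = fit$flag)
}

#' Per-variant capture table
#'
#' Computes, for every variant, the imputation quality `r2_imput` (squared
#' correlation between true and imputed dosage) and the array-tagging
#' quality `rho2` (adjusted R-squared on genotyped neighbours within
#' `window_bp`). Genotyped variants get `rho2 = 1` and `r2_imput = 1` by
#' convention: they are their own perfect imputation, which makes the two
#' captured-heritability formulas agree when every variant is typed.
#'
#' @param panel A `genotype_panel` after [designate_genotyped()] and
#'   [emulate_imputation()].
#' @param window_bp Tagging window half-width in base pairs.
#' @return A `capture_table` tibble: `index`, `maf`, `is_genotyped`,
#'   `r2_imput`, `rho2`, `rho2_flag`.
#' @export
capture_table <- function(panel, window_bp = 1.5e6) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(panel$imputed_dosage)) {
    abort("panel has no imputed dosages; run emulate_imputation() first")
  }
  meta <- panel$meta
  m <- nrow(meta)
  r2 <- rep(1, m)
  rho2 <- rep(1, m)
  flag <- rep("genotyped", m)
  untyped <- which(!meta$is_genotyped)
  for (j in untyped) {
    tc <- panel$true_dosage[, j]
    r2[j] <- if (sd(tc) == 0) 0 else
      min(1, max(0, suppressWarnings(cor(tc, panel$imputed_dosage[, j]))^2,
                 na.rm = TRUE))
    in_window <- meta$is_genotyped &
      meta$chrom == meta$chrom[j] &
      abs(meta$pos - meta$pos[j]) <= window_bp
    if (!any(in_window)) {
      rho2[j] <- 0
      flag[j] <- "no_predictor"
    } else {
      fit <- rho2_fit(tc, panel$true_dosage[, in_window, drop = FALSE])
      rho2[j] <- fit$rho2
      flag[j] <- fit$flag
    }
  }
  out <- tibble(
    index = meta$index, maf = meta$maf, is_genotyped = meta$is_genotyped,
    r2_imput = r2, rho2 = rho2, rho2_flag = flag
  )
  structure(out, window_bp = window_bp,
            class = c("capture_table", class(out)))
}

check_aligned <- function(effects, capture) {
  if (nrow(effects) != nrow(capture)) {
    abort("effects and capture table lengths differ")
  }
}

#' Heritability captured by the genotyped panel
#'
#' `h2_G = sum_S beta^2 + sum_{not S} beta^2 * rho2`: genotyped variants
#' contribute their full effect, untyped variants only the share tagged by
#' nearby array variants.
#'
#' @param effects An `effect_profile`.
#' @param capture A `capture_table` aligned with it.
#' @return Scalar.
#' @export
h2_genotyped <- function(effects, capture) {
  check_aligned(effects, capture)
  b2 <- effects$beta^2
  s <- capture$is_genotyped
  sum(b2[s]) + sum(b2[!s] * capture$rho2[!s])
}

#' Heritability captured by all imputed variants
#'
#' `h2_I = sum beta^2 * r2_imput`: every causal effect weighted by its
#' imputation quality.
#'
#' @inheritParams h2_genotyped
#' @return Scalar.
#' @export
h2_imputed <- function(effects, capture) {
  check_aligned(effects, capture)
  sum(effects$beta^2 * capture$r2_imput)
}

#' Captured-heritability summary
#'
#' @inheritParams h2_genotyped
#' @return One-row tibble with `h2_total`, `h2_G`, `h2_I`, `prop_G =
#'   h2_G / h2_total`, `prop_I = h2_I / h2_total`.
#' @export
capture_summary <- function(effects, capture) {
  h2 <- sum(effects$beta^2)
  hg <- h2_genotyped(effects, capture)
  hi <- h2_imputed(effects, capture)
  tibble(h2_total = h2, h2_G = hg, h2_I = hi,
         prop_G = if (h2 > 0) hg / h2 else NA_real_,
         prop_I = if (h2 > 0) hi / h2 else NA_real_)
}

#' Expected capture proportions across the alpha grid
#'
#' For each frequency-coupling exponent `alpha`, the expected fractions of
#' heritability recoverable from genotyped variants (`prop_G`, via LD
#' tagging) and from all imputed variants (`prop_I`). With `n_rep > 0` the
#' proportions are averaged over `n_rep` alpha-model effect draws; with
#' `n_rep = 0` the analytic expectation is used (`prop = sum(c_i w_i) /
#' sum(w_i)` with `w_i = [2 p_i (1-p_i)]^alpha` and `c_i` the per-variant
#' capture weight), which is noise-free and monotone when capture rises
#' with MAF.
#'
#' @param capture A `capture_table`.
#' @param alphas Grid of exponents.
#' @param n_rep Effect draws per grid point (0 for analytic expectation).
#' @param seed Top-level seed.
#' @return A `capture_curve` tibble: `alpha`, `prop_G`, `prop_I`.
#' @export
capture_proportion_curve <- function(capture,
                                     alphas = seq(-1.5, 0, by = 0.05),
                                     n_rep = 0, seed = 1) {
  stopifnot(inherits(capture, "capture_table"))
  cg <- ifelse(capture$is_genotyped, 1, capture$rho2)
  ci <- capture$r2_imput
  rows <- purrr::imap(alphas, function(a, k) {
    if (n_rep == 0) {
      w <- (2 * capture$maf * (1 - capture$maf))^a
      tibble(alpha = a, prop_G = sum(cg * w) / sum(w),
             prop_I = sum(ci * w) / sum(w))
    } else {
      pg <- pi_ <- numeric(n_rep)
      for (r in seq_len(n_rep)) {
        eff <- sample_alpha_effects(capture$maf, a, h2_target = 1,
                                    seed = substream_seed(seed, paste0("curve", k, "_", r)))
        b2 <- eff$beta^2
        pg[r] <- sum(b2 * cg)
        pi_[r] <- sum(b2 * ci)
      }
      tibble(alpha = a, prop_G = mean(pg), prop_I = mean(pi_))
    }
  })
  out <- list_rbind(rows) |> arrange(.data$alpha)
  structure(out, n_rep = n_rep, class = c("capture_curve", class(out)))
}
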