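#' AUC with standard error
#'
#' AUC via the rank (Mann-Whitney) statistic with midrank ties; variance by
#' the Hanley-McNeil formula (default) or DeLong's method.
#'
#' @param scores Numeric predictor.
#' @param labels Logical or 0/1 case indicator; both classes required.
#' @param group Optional label carried into the output.
#' @param method `"hanley"` or `"delong"`.
#' @return An `auc_estimate` one-row tibble: `group`, `auc`, `variance`,
#'   `se`, `n_case`, `n_control`.
#' @export
auc_with_se <- function(scores, labels, group = NA_character_,
                        method = c("hanley", "delong")) {
  method <- match.arg(method)
  case <- as.logical(labels)
  n1 <- as.numeric(sum(case))
  n0 <- as.numeric(sum(!case))
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
            (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  } else {
    # DeLong: variance from placement values
    cs <- scores[case]
    ct <- scores[!case]
    v10 <- vapply(cs, function(s) mean(s > ct) + 0.5 * mean(s == ct),
                  numeric(1))
    v01 <- vapply(ct, function(s) mean(cs > s) + 0.5 * mean(cs == s),
                  numeric(1))
    v <- stats::var(v10) / n1 + stats::var(v01) / n0
  }
  v <- max(v, .Machine$double.eps)
  out <- tibble(group = group, auc = auc, variance = v, se = sqrt(v),
                n_case = n1, n_control = n0)
  structure(out, method = method, class = c("auc_estimate", class(out)))
}

#' Inverse-variance AUC meta-analysis
#'
#' Precision-weighted pooling of per-group AUC estimates:
#' `AUC = sum(AUC_i / var_i) / sum(1 / var_i)`, with combined
#' `SE = sqrt(1 / sum(1 / var_i))`.
#'
#' @param estimates Tibble with columns `auc` and `variance` (e.g. rows
#'   from [auc_with_se()] bound together).
#' @return One-row tibble: `auc`, `variance`, `se`, `n_groups`.
#' @export
meta_auc <- function(estimates) {
  if (!nrow(estimates)) abort("empty estimate list")
  if (any(estimates$variance <= 0)) abort("variances must be positive")
  w <- 1 / estimates$variance
  tibble(
    auc = sum(estimates$auc * w) / sum(w),
    variance = 1 / sum(w),
    se = sqrt(1 / sum(w)),
    n_groups = nrow(estimates)
  )
}

#' Odds ratio comparing a top PRS stratum to the remainder
#'
#' 2x2 contingency odds ratio for disease in the top `top_fraction` of the
#' score distribution versus everyone else, with the Woolf (log-OR normal)
#' confidence interval. Ties at the cutoff are broken by rank under a fixed
#' seed so the stratum size is exact.
#'
#' @param scores,labels As in [auc_with_se()].
#' @param top_fraction Fraction defining the top stratum (e.g. 0.05, 0.01).
#' @param conf_level CI level.
#' @param seed Seed for tie-breaking.
#' @return One-row tibble: `top_fraction`, `odds_ratio`, `ci_lo`, `ci_hi`,
#'   and the four cell counts. A zero cell is an error of class
#'   `prsceiling_degenerate_table` naming the empty cell.
#' @export
strata_odds_ratio <- function(scores, labels, top_fraction = 0.05,
                              conf_level = 0.95, seed = 1) {
  case <- as.logical(labels)
  n <- length(scores)
  k <- max(1L, round(top_fraction * n))
  set_stream_seed(seed, "strata_ties")
  ord <- order(-scores, sample.int(n))
  top <- logical(n)
  top[ord[seq_len(k)]] <- TRUE
  a <- sum(top & case)      # cases in top stratum
  b <- sum(top & !case)     # controls in top stratum
  c_ <- sum(!top & case)    # cases in remainder
  d <- sum(!top & !case)    # controls in remainder
  cells <- c(cases_top = a, controls_top = b, cases_rest = c_,
             controls_rest = d)
  if (any(cells == 0)) {
    abort(paste0("degenerate 2x2 table; zero cell(s): ",
                 paste(names(cells)[cells == 0], collapse = ", ")),
          class = "prsceiling_degenerate_table")
  }
  or <- (a * d) / (b * c_)
  se_log <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble(top_fraction = top_fraction, odds_ratio = or,
         ci_lo = exp(log(or) - zq * se_log),
         ci_hi = exp(log(or) + zq * se_log),
         cases_top = a, controls_top = b, cases_rest = c_,
         controls_rest = d)
}
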