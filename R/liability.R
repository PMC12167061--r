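#' Liability-threshold quantities for a given prevalence
#'
#' For prevalence `K`, the liability threshold is `T = qnorm(1 - K)`, `z`
#' is the standard normal density at `T`, `i = z / K` is the mean liability
#' of cases and `v = -z / (1 - K)` the mean liability of controls (truncated
#' normal means above/below the threshold).
#'
#' @param K Prevalence in `(0, 1)`.
#' @param h2 Optional liability-scale heritability to attach.
#' @return A `liability_model` list with `K`, `h2`, `T`, `z`, `i_mean`,
#'   `v_mean`.
#' @examples
#' liability_params(0.1)
#' @export
liability_params <- function(K, h2 = NA_real_) {
  if (K <= 0 || K >= 1) abort("K must be in (0, 1)")
  T_ <- qnorm(1 - K)
  z <- dnorm(T_)
  structure(
    list(K = K, h2 = h2, T = T_, z = z, i_mean = z / K,
         v_mean = -z / (1 - K)),
    class = "liability_model"
  )
}

#' @export
print.liability_model <- function(x, ...) {
  cat(sprintf(
    "<liability_model> K = %g: T = %.5f, z = %.5f, i = %.5f, v = %.5f%s\n",
    x$K, x$T, x$z, x$i_mean, x$v_mean,
    if (is.na(x$h2)) "" else sprintf(", h2 = %g", x$h2)
  ))
  invisible(x)
}

#' Maximum achievable AUC under the liability-threshold model
#'
#' The normal-theory approximation for the AUC of a predictor capturing
#' all of the liability-scale heritability `h2` at prevalence `K`:
#' `Phi( (i - v) h2 / sqrt( h2 [ (1 - h2 i (i - T)) + (1 - h2 v (v - T)) ] ) )`
#' with `T`, `i`, `v` from [liability_params()]. Returns 0.5 at `h2 = 0` by
#' continuity. Strictly increasing in `h2`, increasing as `K` falls.
#'
#' @param h2 Liability-scale heritability in `[0, 1]` (vectorised).
#' @param K Prevalence in `(0, 1)`.
#' @return AUC in `[0.5, 1)`. A non-positive variance term (pathological
#'   `h2`, `K` combination) raises an error of class
#'   `prsceiling_auc_degenerate`.
#' @examples
#' auc_max(0.5, 0.1)
#' @export
auc_max <- function(h2, K) {
  if (any(h2 < 0 | h2 > 1)) abort("h2 must be in [0, 1]")
  lp <- liability_params(K)
  i <- lp$i_mean
  v <- lp$v_mean
  T_ <- lp$T
  den2 <- h2 * ((1 - h2 * i * (i - T_)) + (1 - h2 * v * (v - T_)))
  out <- rep(0.5, length(h2))
  pos <- h2 > 0
  if (any(pos & den2 <= 0)) {
    abort("non-positive variance term in AUC approximation",
          class = "prsceiling_auc_degenerate")
  }
  out[pos] <- pnorm((i - v) * h2[pos] / sqrt(den2[pos]))
  out
}

#' Conditional maximum AUC from a captured proportion
#'
#' Substitutes the captured heritability `h2_total * captured_proportion`
#' (e.g. `h2_G` or `h2_I` as a share of the total) into [auc_max()].
#'
#' @param h2_total Total liability-scale heritability.
#' @param captured_proportion Share of `h2_total` captured, in `[0, 1]`.
#' @param K Prevalence.
#' @export
conditional_auc_max <- function(h2_total, captured_proportion, K) {
  if (any(captured_proportion < 0 | captured_proportion > 1)) {
    abort("captured_proportion must be in [0, 1]")
  }
  auc_max(h2_total * captured_proportion, K)
}

rank_auc <- function(scores, case) {
  n1 <- as.numeric(sum(case))
  n0 <- as.numeric(sum(!case))
  r <- rank(scores)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Validate the AUC approximation by simulation
#'
#' For each `(h2, K)` cell, simulates `n_sim` individuals with independent
#' genetic score `g ~ N(0, h2)`, liability `g + N(0, 1 - h2)`, case status
#' `liability > T`, and compares the empirical AUC of `g` against the
#' closed form.
#'
#' @param h2_grid,K_grid Grids of heritabilities and prevalences (defaults
#'   span the ranges the approximation is intended for).
#' @param n_sim Individuals per cell.
#' @param seed Top-level seed (one substream per cell).
#' @return An `auc_validation` tibble: `h2`, `K`, `auc_formula`,
#'   `auc_empirical`, `abs_diff`. Warns if a cell expects fewer than 50
#'   cases.
#' @export
validate_auc_max <- function(h2_grid = c(0.2, 0.45, 0.7),
                             K_grid = c(0.01, 0.1, 0.25),
                             n_sim = 5e5, seed = 1) {
  cells <- tidyr::expand_grid(h2 = h2_grid, K = K_grid)
  if (any(cells$K * n_sim < 50)) {
    warn("n_sim too small: a cell expects fewer than 50 cases")
  }
  rows <- pmap(cells, function(h2, K) {
    set_stream_seed(seed, sprintf("validate_%g_%g", h2, K))
    g <- rnorm(n_sim, 0, sqrt(h2))
    liab <- g + rnorm(n_sim, 0, sqrt(1 - h2))
    case <- liab > qnorm(1 - K)
    emp <- if (h2 == 0) 0.5 else rank_auc(g, case)
    f <- auc_max(h2, K)
    tibble(h2 = h2, K = K, auc_formula = f, auc_empirical = emp,
           abs_diff = abs(f - emp))
  })
  out <- list_rbind(rows)
  structure(out, n_sim = n_sim, class = c("auc_validation", class(out)))
}
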