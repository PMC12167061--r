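#' Tidiers for package objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns per-unit
#' rows (variants, grid cells), `glance()` a one-row summary.
#'
#' @param x A package object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy genotype_panel
#' @export
tidy.genotype_panel <- function(x, ...) {
  freq <- colMeans(x$true_dosage) / 2
  x$meta |> mutate(realized_maf = pmin(freq, 1 - freq))
}

#' @rdname tidiers
#' @method glance genotype_panel
#' @export
glance.genotype_panel <- function(x, ...) {
  tibble(
    n_individuals = x$n_individuals,
    n_variants = nrow(x$meta),
    n_genotyped = sum(x$meta$is_genotyped),
    mean_maf = mean(x$meta$maf),
    has_imputed = !is.null(x$imputed_dosage)
  )
}

#' @rdname tidiers
#' @method tidy effect_profile
#' @export
tidy.effect_profile <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @method glance effect_profile
#' @export
glance.effect_profile <- function(x, ...) {
  at <- attr(x, "attenuation")
  tibble(
    m = nrow(x),
    alpha = attr(x, "alpha"),
    h2_target = attr(x, "h2_target"),
    h2_realized = sum(x$beta^2),
    sigma2_g_alpha = attr(x, "sigma2_g_alpha"),
    attenuated = !is.null(at),
    p0 = if (is.null(at)) NA_real_ else at$p0,
    tau = if (is.null(at)) NA_real_ else at$tau
  )
}

#' @rdname tidiers
#' @method tidy liability_model
#' @export
tidy.liability_model <- function(x, ...) {
  tibble(term = c("T", "z", "i_mean", "v_mean"),
         value = c(x$T, x$z, x$i_mean, x$v_mean))
}

#' @rdname tidiers
#' @method glance liability_model
#' @export
glance.liability_model <- function(x, ...) {
  tibble(K = x$K, h2 = x$h2, T = x$T, z = x$z,
         i_mean = x$i_mean, v_mean = x$v_mean,
         auc_max = if (is.na(x$h2)) NA_real_ else auc_max(x$h2, x$K))
}

#' @rdname tidiers
#' @method glance capture_table
#' @export
glance.capture_table <- function(x, ...) {
  un <- !x$is_genotyped
  tibble(
    m = nrow(x),
    n_genotyped = sum(x$is_genotyped),
    mean_r2_imput = mean(x$r2_imput[un]),
    mean_rho2 = mean(x$rho2[un]),
    cor_rho2_r2 = cor(x$rho2[un], x$r2_imput[un]),
    window_bp = attr(x, "window_bp") %||% NA_real_
  )
}

#' @rdname tidiers
#' @method glance convergence_curve
#' @export
glance.convergence_curve <- function(x, ...) {
  tibble(
    h2 = attr(x, "h2"), K = attr(x, "K"), reps = attr(x, "reps"),
    auc_ceiling = x$auc_ceiling[1],
    terminal_auc = x$auc_mean[nrow(x)],
    terminal_gap = x$auc_ceiling[1] - x$auc_mean[nrow(x)]
  )
}

#' @rdname tidiers
#' @method glance auc_validation
#' @export
glance.auc_validation <- function(x, ...) {
  tibble(n_cells = nrow(x), n_sim = attr(x, "n_sim"),
         max_abs_diff = max(x$abs_diff), mean_abs_diff = mean(x$abs_diff))
}
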