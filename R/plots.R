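#' Plot capture proportions across the alpha grid
#'
#' @param object A `capture_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot capture_curve
#' @export
autoplot.capture_curve <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("prop_G", "prop_I"), names_to = "panel",
                        values_to = "proportion") |>
    mutate(panel = dplyr::recode(.data$panel,
                                 prop_G = "genotyped (LD tagging)",
                                 prop_I = "all imputed"))
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha, .data$proportion,
                                   linetype = .data$panel)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c("all imputed" = "solid",
                                              "genotyped (LD tagging)" = "dashed")) +
    ggplot2::labs(x = expression(alpha),
                  y = "proportion of heritability captured",
                  linetype = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a PRS convergence curve
#'
#' AUC against GWAS sample size (log scale) with the liability-threshold
#' ceiling as a horizontal reference.
#'
#' @param object A `convergence_curve`.
#' @param ... Unused.
#' @method autoplot convergence_curve
#' @export
autoplot.convergence_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_gwas, .data$auc_mean)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$auc_ceiling),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$auc_mean - 1.96 * .data$auc_se,
                   ymax = .data$auc_mean + 1.96 * .data$auc_se),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "GWAS effective sample size", y = "AUC") +
    ggplot2::theme_minimal()
}

#' Plot per-disease AUC ceilings
#'
#' @param object A `ceiling_report`.
#' @param ... Unused.
#' @method autoplot ceiling_report
#' @export
autoplot.ceiling_report <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("auc_twin", "auc_imputed", "auc_gwas"),
                        names_to = "ceiling", values_to = "auc") |>
    mutate(ceiling = dplyr::recode(.data$ceiling,
                                   auc_twin = "twin h2",
                                   auc_imputed = "imputed capture",
                                   auc_gwas = "GWAS h2"))
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$auc,
                                   fill = .data$ceiling)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = "maximum achievable AUC", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment scan
#'
#' Standardized enrichment coefficients by annotation category, with the
#' multiple-testing-significant tracks highlighted.
#'
#' @param object An `enrichment_scan` tibble.
#' @param ... Unused.
#' @method autoplot enrichment_scan
#' @export
autoplot.enrichment_scan <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$delta_std,
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = NULL, y = "standardized coefficient",
                  colour = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
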