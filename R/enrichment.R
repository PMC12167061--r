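#' Univariate annotation enrichment of imputation quality
#'
#' Ordinary least squares of per-variant imputation quality on a binary
#' annotation indicator, `r2 ~ delta * A`. For a binary predictor the
#' unstandardized slope equals the difference in group means
#' (`mean_r2_in - mean_r2_out`); `delta_std` z-scores both response and
#' predictor (i.e. the Pearson correlation). The p-value is the usual OLS
#' t-test on the slope.
#'
#' @param r2 Length-M vector of imputation r-squared values.
#' @param indicator Length-M binary (0/1) annotation membership.
#' @param annotation,category Labels carried into the result.
#' @return An `enrichment_result` one-row tibble: `annotation`, `category`,
#'   `delta`, `delta_std`, `p_value`, `mean_r2_in`, `mean_r2_out`, `n_in`,
#'   `n_out`, `adjusted`. A constant indicator (track covering all or no
#'   variants) is an error of class `prsceiling_constant_indicator`.
#' @export
univariate_enrichment <- function(r2, indicator, annotation = "A",
                                  category = NA_character_) {
  if (length(r2) != length(indicator)) abort("length mismatch")
  if (!all(indicator %in% c(0, 1))) abort("indicator must be binary 0/1")
  if (length(unique(indicator)) < 2) {
    abort("constant indicator: enrichment undefined",
          class = "prsceiling_constant_indicator")
  }
  m <- length(r2)
  ind <- as.numeric(indicator)
  in_ <- ind == 1
  mean_in <- mean(r2[in_])
  mean_out <- mean(r2[!in_])
  delta <- mean_in - mean_out
  rho <- cor(r2, ind)
  if (is.na(rho)) rho <- 0
  tstat <- if (abs(rho) >= 1) Inf else rho * sqrt((m - 2) / (1 - rho^2))
  p <- if (m - 2 < 1) NA_real_ else 2 * pt(-abs(tstat), df = m - 2)
  out <- tibble(
    annotation = annotation, category = category,
    delta = delta, delta_std = rho, p_value = p,
    mean_r2_in = mean_in, mean_r2_out = mean_out,
    n_in = sum(in_), n_out = sum(!in_), adjusted = FALSE
  )
  structure(out, class = c("enrichment_result", class(out)))
}

#' Gene-structure-adjusted annotation enrichment
#'
#' Partial slope of imputation quality on a focal annotation, conditioning
#' on a matrix of gene-structure (e.g. GENCODE-category) indicators:
#' `r2 ~ delta * A + sum_k delta_k * A_k`. Collinear adjuster columns are
#' dropped (and reported); a focal indicator collinear with the adjusters
#' is an error. With no (or all-zero) adjusters the fit reduces to
#' [univariate_enrichment()].
#'
#' @inheritParams univariate_enrichment
#' @param gencode_indicators M x k matrix of adjuster indicators (may have
#'   zero columns).
#' @return An `enrichment_result` tibble with `adjusted = TRUE` and
#'   attribute `dropped_adjusters`.
#' @export
adjusted_enrichment <- function(r2, indicator, gencode_indicators,
                                annotation = "A",
                                category = NA_character_) {
  if (length(unique(indicator)) < 2) {
    abort("constant indicator: enrichment undefined",
          class = "prsceiling_constant_indicator")
  }
  g <- as.matrix(gencode_indicators)
  if (nrow(g) == 0 || ncol(g) == 0) {
    g <- matrix(numeric(0), nrow = length(r2), ncol = 0)
  }
  if (is.null(colnames(g)) && ncol(g) > 0) {
    colnames(g) <- paste0("adj", seq_len(ncol(g)))
  }
  keep <- if (ncol(g)) apply(g, 2, function(col) length(unique(col)) > 1)
          else logical(0)
  dropped <- colnames(g)[!keep]
  g <- g[, keep, drop = FALSE]
  ind <- as.numeric(indicator)
  x <- cbind(focal = ind, g)
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    # identify whether the focal column is the redundant one
    qr_noi <- qr(cbind(1, g))
    if (qrx$rank == qr_noi$rank) {
      abort("focal indicator collinear with adjusters",
            class = "prsceiling_collinear_focal")
    }
    # drop redundant adjusters instead
    pivot_keep <- qrx$pivot[seq_len(qrx$rank)]
    adj_cols <- setdiff(pivot_keep, c(1, 2)) - 2L
    dropped <- c(dropped, setdiff(colnames(g), colnames(g)[adj_cols]))
    g <- g[, adj_cols, drop = FALSE]
    x <- cbind(focal = ind, g)
  }
  dat <- data.frame(.r2 = r2, .focal = ind)
  if (ncol(g)) dat <- cbind(dat, as.data.frame(g))
  fit <- stats::lm(.r2 ~ ., data = dat)
  sm <- summary(fit)$coefficients
  slope <- sm[".focal", "Estimate"]
  p <- sm[".focal", "Pr(>|t|)"]
  in_ <- ind == 1
  out <- tibble(
    annotation = annotation, category = category,
    delta = slope,
    delta_std = slope * sd(ind) / sd(r2),
    p_value = p,
    mean_r2_in = mean(r2[in_]), mean_r2_out = mean(r2[!in_]),
    n_in = sum(in_), n_out = sum(!in_), adjusted = TRUE
  )
  structure(out, dropped_adjusters = dropped,
            class = c("enrichment_result", class(out)))
}

#' Multiple-testing control for enrichment scans
#'
#' Flags p-values significant after Bonferroni correction (`p <
#' alpha_level / K`, the default) or Benjamini-Hochberg FDR control.
#'
#' @param p_values Vector of p-values.
#' @param alpha_level Family-wise (or FDR) level.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Tibble with `p_value`, `significant`; attribute `threshold`
#'   (the Bonferroni cutoff `alpha_level / K`, `NA` for BH).
#' @export
multiple_testing <- function(p_values, alpha_level = 0.05,
                             method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("invalid p-values")
  }
  k <- length(p_values)
  if (method == "bonferroni") {
    thr <- alpha_level / k
    sig <- p_values < thr
  } else {
    thr <- NA_real_
    sig <- p.adjust(p_values, "BH") < alpha_level
  }
  structure(tibble(p_value = p_values, significant = sig),
            threshold = thr, method = method)
}

#' MAF distributions by annotation category
#'
#' For each track: the cumulative MAF distribution of variants inside vs
#' outside the track on a fixed grid, and a two-proportion z-test comparing
#' the rare-variant fractions (`maf < rare_cutoff`) inside vs outside.
#'
#' @param panel A `genotype_panel` (or its meta tibble).
#' @param annotations An `annotation_set`.
#' @param rare_cutoff MAF below which a variant counts as rare.
#' @param grid MAF grid for the cumulative curves.
#' @return A `maf_annotation_summary` list with `cdf` (tibble: `track`,
#'   `category`, `maf`, `cdf_in`, `cdf_out`) and `tests` (tibble: `track`,
#'   `category`, `rare_frac_in`, `rare_frac_out`, `z`, `p_value`).
#' @export
maf_by_annotation <- function(panel, annotations, rare_cutoff = 0.01,
                              grid = 10^seq(-4, log10(0.5), length.out = 40)) {
  meta <- if (inherits(panel, "genotype_panel")) panel$meta else panel
  ind <- annotate_variants(meta, annotations)
  key <- as_tibble(annotations) |>
    select("track", "category") |>
    dplyr::distinct()
  per_track <- purrr::map(seq_len(ncol(ind)), function(t) {
    a <- ind[, t] == 1
    if (!any(a) || all(a)) {
      abort(sprintf("track %s has a degenerate in/out split", colnames(ind)[t]))
    }
    cdf <- tibble(
      track = colnames(ind)[t],
      maf = grid,
      cdf_in = stats::ecdf(meta$maf[a])(grid),
      cdf_out = stats::ecdf(meta$maf[!a])(grid)
    )
    rin <- sum(meta$maf[a] < rare_cutoff)
    rout <- sum(meta$maf[!a] < rare_cutoff)
    pt_ <- suppressWarnings(
      prop.test(c(rin, rout), c(sum(a), sum(!a)), correct = FALSE)
    )
    z <- sign(rin / sum(a) - rout / sum(!a)) * sqrt(pt_$statistic)
    tests <- tibble(
      track = colnames(ind)[t],
      rare_frac_in = rin / sum(a), rare_frac_out = rout / sum(!a),
      z = unname(z), p_value = pt_$p.value
    )
    list(cdf = cdf, tests = tests)
  })
  out <- list(
    cdf = list_rbind(map(per_track, "cdf")) |> left_join(key, by = "track"),
    tests = list_rbind(map(per_track, "tests")) |> left_join(key, by = "track")
  )
  structure(out, rare_cutoff = rare_cutoff,
            class = "maf_annotation_summary")
}

#' Enrichment scan over an annotation set
#'
#' Runs [univariate_enrichment()] (optionally the GENCODE-adjusted model)
#' for every track of an annotation set against per-variant imputation
#' quality, then applies [multiple_testing()].
#'
#' @param capture A `capture_table` (its `r2_imput` is the response).
#' @param panel A `genotype_panel` aligned with the capture table.
#' @param annotations An `annotation_set`.
#' @param adjust_gencode If `TRUE`, condition each non-gencode track on the
#'   gencode-category tracks.
#' @param alpha_level,method Passed to [multiple_testing()].
#' @return Tibble of `enrichment_result` rows plus a `significant` column;
#'   attribute `threshold`.
#' @export
enrichment_scan <- function(capture, panel, annotations,
                            adjust_gencode = FALSE, alpha_level = 0.05,
                            method = "bonferroni") {
  ind <- annotate_variants(panel, annotations)
  key <- as_tibble(annotations) |>
    select("track", "category") |>
    dplyr::distinct()
  cats <- setNames(key$category, key$track)
  gencode_cols <- ind[, cats[colnames(ind)] == "gencode", drop = FALSE]
  rows <- purrr::map(colnames(ind), function(tr) {
    focal <- ind[, tr]
    if (length(unique(focal)) < 2) return(NULL)
    if (adjust_gencode && cats[[tr]] != "gencode" && ncol(gencode_cols)) {
      tryCatch(
        adjusted_enrichment(capture$r2_imput, focal, gencode_cols,
                            annotation = tr, category = cats[[tr]]),
        prsceiling_collinear_focal = function(e) NULL
      )
    } else {
      univariate_enrichment(capture$r2_imput, focal, annotation = tr,
                            category = cats[[tr]])
    }
  })
  out <- list_rbind(purrr::compact(rows))
  mt <- multiple_testing(out$p_value, alpha_level, method)
  out$significant <- mt$significant
  structure(out, threshold = attr(mt, "threshold"),
            class = c("enrichment_scan", class(out)))
}
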