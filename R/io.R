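#' Write and read a genotype panel as plain text
#'
#' Writes `variant_meta.tsv` (metadata plus per-variant quality targets),
#' `true_dosage.tsv` / `imputed_dosage.tsv` (individuals x variants,
#' tab-separated, no header) and a `panel.json` sidecar carrying `n`, `m`
#' and the generation parameters.
#'
#' @param panel A `genotype_panel`.
#' @param dir Output directory (created if missing).
#' @return `write_panel()` returns `dir` invisibly; `read_panel()` a
#'   `genotype_panel`.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(panel$meta, file.path(dir, "variant_meta.tsv"))
  utils::write.table(panel$true_dosage, file.path(dir, "true_dosage.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(panel$imputed_dosage)) {
    utils::write.table(panel$imputed_dosage,
                       file.path(dir, "imputed_dosage.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  header <- list(
    n = panel$n_individuals, m = nrow(panel$meta),
    has_imputed = !is.null(panel$imputed_dosage),
    params = attr(panel, "params")
  )
  jsonlite::write_json(header, file.path(dir, "panel.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "panel.json"),
                                simplifyVector = TRUE)
  meta <- readr::read_tsv(file.path(dir, "variant_meta.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  true_d <- as.matrix(readr::read_tsv(
    file.path(dir, "true_dosage.tsv"), col_names = FALSE,
    show_col_types = FALSE, progress = FALSE
  ))
  dimnames(true_d) <- NULL
  imp <- NULL
  if (isTRUE(header$has_imputed)) {
    imp <- as.matrix(readr::read_tsv(
      file.path(dir, "imputed_dosage.tsv"), col_names = FALSE,
      show_col_types = FALSE, progress = FALSE
    ))
    dimnames(imp) <- NULL
  }
  meta$chrom <- as.character(meta$chrom)
  new_genotype_panel(as_tibble(meta), true_d, imp,
                     params = header$params)
}

#' Write an effect profile as tab-separated text
#'
#' @param effects An `effect_profile`.
#' @param path File path.
#' @export
write_effects <- function(effects, path) {
  readr::write_tsv(as_tibble(effects), path)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  as_tibble(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write / read a capture table as tab-separated text
#'
#' @param capture A `capture_table`.
#' @param path File path.
#' @export
write_capture <- function(capture, path) {
  readr::write_tsv(as_tibble(capture), path)
  invisible(path)
}

#' @rdname write_capture
#' @export
read_capture <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(as_tibble(out), class = c("capture_table", class(as_tibble(out))))
}

#' Minimal VCF export of true dosages
#'
#' Writes a GT-only VCF v4.2 of the panel's true (sequenced) genotypes:
#' dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, with placeholder REF/ALT
#' alleles. Intended for interchange with standard variant tooling, not as
#' a faithful sequencing representation.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path (plain text).
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- panel$n_individuals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=prsceiling",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("ind%04d", seq_len(n))), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(panel$meta))) {
    gt <- gt_code[panel$true_dosage[, j] + 1]
    writeLines(paste(c(
      panel$meta$chrom[j], panel$meta$pos[j],
      sprintf("var%06d", panel$meta$index[j]), "A", "G", ".", "PASS", ".",
      "GT", gt
    ), collapse = "\t"), con)
  }
  invisible(path)
}
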