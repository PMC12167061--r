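# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Default calibrated study panel + capture table (moderate size).
cached_study <- function() {
  if (is.null(.fixture_cache$panel)) {
    .fixture_cache$panel <- calibrated_panel(n = 1500, m = 1000, seed = 42)
    .fixture_cache$capture <- capture_table(.fixture_cache$panel)
  }
  list(panel = .fixture_cache$panel, capture = .fixture_cache$capture)
}

# Hand-built panel from an explicit dosage matrix (variants in columns).
make_panel <- function(dosage, maf = NULL, pos = NULL, genotyped = NULL,
                       imputed = NULL) {
  m <- ncol(dosage)
  freq <- colMeans(dosage) / 2
  meta <- tibble::tibble(
    index = seq_len(m),
    chrom = "22",
    pos = pos %||% as.integer(seq_len(m) * 1000L),
    maf = maf %||% pmin(pmax(freq, 1e-4), 0.5),
    is_genotyped = genotyped %||% rep(FALSE, m)
  )
  prsceiling:::new_genotype_panel(meta, dosage, imputed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force adjusted R^2 via explicit normal equations (independent
# oracle for tagging_rho2 on small panels).
brute_rho2 <- function(panel, j, window_bp = 1.5e6) {
  meta <- panel$meta
  y <- panel$true_dosage[, j]
  w <- which(meta$is_genotyped & meta$chrom == meta$chrom[j] &
               abs(meta$pos - meta$pos[j]) <= window_bp)
  x <- panel$true_dosage[, w, drop = FALSE]
  x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  if (ncol(x) == 0) return(0)
  xc <- scale(x, scale = FALSE)
  yc <- y - mean(y)
  b <- solve(crossprod(xc), crossprod(xc, yc))
  r2 <- 1 - sum((yc - xc %*% b)^2) / sum(yc^2)
  n <- length(y)
  p <- ncol(xc)
  min(1, max(0, 1 - (1 - r2) * (n - 1) / (n - 1 - p)))
}

# All-pairs concordance AUC (independent oracle for auc_with_se).
brute_auc <- function(scores, case) {
  cs <- scores[as.logical(case)]
  ct <- scores[!as.logical(case)]
  tot <- 0
  for (s in cs) tot <- tot + sum(s > ct) + 0.5 * sum(s == ct)
  tot / (length(cs) * length(ct))
}
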