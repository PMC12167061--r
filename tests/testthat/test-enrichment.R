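test_that("the univariate slope equals the group-mean difference", {
  # exact two-point fit
  out <- univariate_enrichment(c(0, 1), c(0, 1))
  expect_equal(out$delta, 1)
  expect_equal(out$delta_std, 1)

  set.seed(31)
  r2 <- runif(500)
  ind <- rbinom(500, 1, 0.3)
  out <- univariate_enrichment(r2, ind)
  expect_equal(out$delta, mean(r2[ind == 1]) - mean(r2[ind == 0]),
               tolerance = 1e-12)
  expect_equal(out$delta_std, cor(r2, ind), tolerance = 1e-12)
  # agrees with lm()
  fit <- stats::lm(r2 ~ ind)
  expect_equal(out$delta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(out$p_value, summary(fit)$coefficients[2, 4],
               tolerance = 1e-10)

  expect_error(univariate_enrichment(r2, rep(1, 500)),
               class = "prsceiling_constant_indicator")
  expect_error(univariate_enrichment(r2, rep(0.5, 500)), "binary")
})

test_that("a planted coding-like r2 deficit is recovered", {
  set.seed(32)
  m <- 20000
  ind <- rbinom(m, 1, 0.2)
  r2 <- pmin(1, pmax(0, 0.40 - 0.13 * ind + rnorm(m, 0, 0.1)))
  out <- univariate_enrichment(r2, ind, annotation = "cds_like",
                               category = "gencode")
  expect_lt(out$delta_std, 0)
  se <- sqrt(0.1^2 / out$n_in + 0.1^2 / out$n_out)
  expect_lt(abs(out$delta - (-0.13)), 2 * se + 0.003)
  expect_lt(abs(out$mean_r2_in - 0.27), 2 * 0.1 / sqrt(out$n_in) + 0.003)
  expect_lt(abs(out$mean_r2_out - 0.40), 2 * 0.1 / sqrt(out$n_out) + 0.003)
  expect_lt(out$p_value, 1e-10)
})

test_that("gene-structure adjustment conditions the focal slope", {
  set.seed(33)
  m <- 5000
  gencode <- rbinom(m, 1, 0.3)
  # focal track enriched inside the gencode-like track that carries the shift
  focal <- rbinom(m, 1, ifelse(gencode == 1, 0.6, 0.1))
  r2 <- pmin(1, pmax(0, 0.4 - 0.15 * gencode + rnorm(m, 0, 0.1)))

  uni <- univariate_enrichment(r2, focal)
  adj <- adjusted_enrichment(r2, focal, cbind(gencode = gencode))
  expect_lt(abs(adj$delta), abs(uni$delta))  # attenuated toward zero
  expect_true(adj$adjusted)

  # empty adjuster set reproduces the univariate fit
  adj0 <- adjusted_enrichment(r2, focal, matrix(0, m, 2))
  expect_equal(adj0$delta, uni$delta, tolerance = 1e-12)
  expect_equal(adj0$p_value, uni$p_value, tolerance = 1e-9)

  # focal duplicated among adjusters: collinearity is an error
  expect_error(adjusted_enrichment(r2, focal, cbind(focal)),
               class = "prsceiling_collinear_focal")
})

test_that("multiple-testing control flags at the corrected threshold", {
  mt1 <- multiple_testing(0.04)
  expect_equal(attr(mt1, "threshold"), 0.05)
  expect_true(mt1$significant)

  mt <- multiple_testing(rep(1, 100))
  expect_false(any(mt$significant))
  expect_equal(attr(mt, "threshold"), 0.05 / 100)

  p <- c(1e-6, 0.01, 0.2)
  expect_identical(multiple_testing(p)$significant,
                   p < 0.05 / 3)
  expect_error(multiple_testing(c(0.5, 1.2)), "invalid")
})

test_that("null p-values are uniform and false flags match Bonferroni", {
  set.seed(34)
  # uniformity: one fit per replicate at moderate size
  m <- 2000
  ind <- rbinom(m, 1, 0.3)
  pvals <- vapply(1:300, function(r) {
    univariate_enrichment(rnorm(m), ind)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)

  # Bonferroni at K tracks: about alpha false flags per replicate set
  k <- 200
  reps <- 100
  indmat <- matrix(rbinom(m * k, 1, 0.3), m, k)
  flags <- vapply(1:reps, function(r) {
    r2 <- rnorm(m)
    rho <- suppressWarnings(cor(r2, indmat))
    tstat <- rho * sqrt((m - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), m - 2)
    sum(multiple_testing(as.numeric(p))$significant)
  }, numeric(1))
  # total false flags ~ Poisson(reps * 0.05)
  expect_lt(abs(sum(flags) - reps * 0.05), 4 * sqrt(reps * 0.05) + 1)
})

test_that("MAF distributions by annotation detect planted rare enrichment", {
  set.seed(35)
  p <- generate_panel(n = 10, m = 4000, seed = 35)
  ann <- generate_annotations(p, k = 2, coverage_range = c(0.2, 0.4),
                              seed = 35)
  ind <- annotate_variants(p, ann)

  # plant rare enrichment inside track 1 by overwriting in-track MAFs
  p2 <- p
  in1 <- ind[, 1] == 1
  p2$meta$maf[in1] <- maf_rare_skewed(1e-4, 0.05) |> sample_maf(sum(in1))

  s <- maf_by_annotation(p2, ann, rare_cutoff = 0.01)
  t1 <- s$tests[s$tests$track == colnames(ind)[1], ]
  expect_gt(t1$rare_frac_in, t1$rare_frac_out)
  expect_gt(t1$z, 0)
  expect_lt(t1$p_value, 1e-4)

  # CDF curves are proper distribution functions
  cdf <- s$cdf
  for (tr in unique(cdf$track)) {
    cc <- cdf[cdf$track == tr, ]
    expect_true(all(diff(cc$cdf_in) >= 0))
    expect_true(all(diff(cc$cdf_out) >= 0))
    expect_equal(cc$cdf_in[nrow(cc)], 1)
    expect_equal(cc$cdf_out[nrow(cc)], 1)
  }

  # matched distributions are not flagged (independence null)
  p0 <- generate_panel(n = 10, m = 4000, seed = 36)
  ann0 <- generate_annotations(p0, k = 2, coverage_range = c(0.2, 0.4),
                               seed = 36)
  s0 <- maf_by_annotation(p0, ann0, rare_cutoff = 0.01)
  expect_gt(min(s0$tests$p_value), 0.001)
})

test_that("the enrichment scan runs across an annotation set", {
  st <- cached_study()
  ann <- generate_annotations(st$panel, k = 8,
                              coverage_range = c(0.05, 0.5), seed = 40)
  scan <- enrichment_scan(st$capture, st$panel, ann)
  expect_lte(nrow(scan), 8L)
  expect_true(all(c("delta_std", "p_value", "significant") %in%
                    colnames(scan)))
  expect_equal(attr(scan, "threshold"), 0.05 / nrow(scan))

  scan_adj <- enrichment_scan(st$capture, st$panel, ann,
                              adjust_gencode = TRUE)
  expect_true(any(scan_adj$adjusted))
})
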