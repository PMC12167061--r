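test_that("effective sample size reproduces published study values", {
  # six case/control designs with known reported Neff
  studies <- gwas_study(
    label = c("cad_biobank_5k", "cad_c4d", "cad_nikpay", "t2d_mahajan",
              "asthma_moffatt", "ad_kunkle", "balanced"),
    n_case = c(5000, 15420, 60801, 74124, 10365, 21982, 1000),
    n_control = c(50000, 15062, 123504, 824006, 16110, 41944, 1000)
  )
  expect_identical(studies$n_eff_reported,
                   c(18182L, 30478L, 162973L, 272026L, 25228L, 57693L,
                     2000L))
  expect_equal(effective_sample_size(1000, 1000), 2000)
  expect_error(effective_sample_size(0, 10), "positive")
})

test_that("per-variant Neff filter excludes both boundary violations", {
  neff <- c(1, 0.49, 0.5, 0.8, 1.1, 1.11, 0.2) * 1000
  keep <- per_variant_neff_filter(neff, expected_max = 1000)
  expect_identical(as.logical(keep),
                   c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(attr(keep, "n_removed"), 3L)
  expect_true(all(per_variant_neff_filter(rep(500, 5), 500)))
  expect_error(per_variant_neff_filter(1:3, expected_max = 0))
})

test_that("PRS scoring handles orientation flips exactly", {
  dosage <- matrix(c(0, 1, 2,
                     2, 1, 0,
                     1, 2, 0), nrow = 3)
  p <- make_panel(dosage)
  w0 <- tibble::tibble(gamma = c(0, 0, 0))
  expect_equal(prs_score(w0, p, "true"), c(0, 0, 0))

  w1 <- tibble::tibble(gamma = c(1, 0, 0))
  expect_equal(prs_score(w1, p, "true"), dosage[, 1])

  # hand-computed inner product with the second variant flipped:
  # score_i = g1 * x1 + g2 * (2 - x2) + g3 * x3
  w <- tibble::tibble(gamma = c(0.5, -1, 2), flip = c(FALSE, TRUE, FALSE))
  expected <- 0.5 * dosage[, 1] - 1 * (2 - dosage[, 2]) + 2 * dosage[, 3]
  expect_equal(prs_score(w, p, "true"), expected)

  # genotyped-only scoring zeroes untyped contributions
  p$meta$is_genotyped <- c(TRUE, FALSE, TRUE)
  expect_equal(prs_score(w, p, "genotyped"),
               0.5 * dosage[, 1] + 2 * dosage[, 3])
  expect_error(prs_score(tibble::tibble(gamma = 1), p, "true"), "aligned")
})

test_that("rank AUC equals the all-pairs concordance oracle", {
  set.seed(4)
  for (r in 1:20) {
    n <- sample(6:50, 1)
    scores <- sample(1:10, n, replace = TRUE)  # forces ties
    case <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(case) || all(case)) next
    est <- auc_with_se(scores, case)
    expect_equal(est$auc, brute_auc(scores, case), tolerance = 1e-12)
  }
  expect_equal(auc_with_se(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_error(auc_with_se(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC variance estimators agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(300)
  case <- runif(300) < stats::plogis(scores)
  est <- auc_with_se(scores, case, method = "delong")
  ro <- pROC::roc(response = case, predictor = scores, quiet = TRUE,
                  direction = "<")
  expect_equal(est$auc, as.numeric(pROC::auc(ro)), tolerance = 1e-12)
  expect_equal(est$se, sqrt(pROC::var(ro)), tolerance = 1e-6)
})

test_that("inverse-variance meta-analysis pools as hand-computed", {
  one <- tibble::tibble(auc = 0.62, variance = 0.003)
  expect_equal(meta_auc(one)$auc, 0.62)
  expect_equal(meta_auc(one)$se, sqrt(0.003))

  eq <- tibble::tibble(auc = c(0.6, 0.7), variance = c(0.01, 0.01))
  expect_equal(meta_auc(eq)$auc, 0.65)

  two <- tibble::tibble(auc = c(0.6, 0.7), variance = c(0.01, 0.0025))
  out <- meta_auc(two)
  expect_equal(out$auc, 0.68, tolerance = 1e-12)
  expect_equal(out$se, sqrt(1 / 500), tolerance = 1e-12)
  expect_lte(out$variance, min(two$variance))
  expect_error(meta_auc(two[0, ]), "empty")
})

test_that("top-stratum odds ratios match direct 2x2 arithmetic", {
  scores <- 20:1
  case <- seq_len(20) %in% c(1, 2, 3, 6, 7)
  out <- strata_odds_ratio(scores, case, top_fraction = 0.25)
  expect_identical(c(out$cases_top, out$controls_top, out$cases_rest,
                     out$controls_rest), c(3L, 2L, 2L, 13L))
  expect_equal(out$odds_ratio, (3 * 13) / (2 * 2), tolerance = 1e-12)
  se <- sqrt(1 / 3 + 1 / 2 + 1 / 2 + 1 / 13)
  expect_equal(out$ci_lo, exp(log(9.75) - qnorm(0.975) * se),
               tolerance = 1e-10)

  # independence: OR near 1 at large n
  set.seed(2)
  s <- rnorm(20000)
  cs <- runif(20000) < 0.2
  or <- strata_odds_ratio(s, cs, 0.05)
  expect_lt(abs(log(or$odds_ratio)), 0.3)

  # perfect separation with few cases: zero cell signalled by location
  expect_error(
    strata_odds_ratio(c(10, 9, 1:8), c(TRUE, TRUE, rep(FALSE, 8)),
                      top_fraction = 0.2),
    class = "prsceiling_degenerate_table"
  )
})

test_that("simulated GWAS noise and shrinkage follow their closed forms", {
  maf <- runif(400, 0.05, 0.5)
  eff <- sample_alpha_effects(maf, -0.5, 0.3, seed = 12)
  bh <- simulate_gwas_effects(eff, n_gwas = 250, seed = 12)
  expect_equal(stats::var(bh - eff$beta), 1 / 250, tolerance = 0.25)
  expect_identical(bh, simulate_gwas_effects(eff, 250, seed = 12))
  # consistency: noise vanishes at large n
  bh_big <- simulate_gwas_effects(eff, n_gwas = 1e8, seed = 12)
  expect_lt(max(abs(bh_big - eff$beta)), 1e-3)

  w <- shrink_weights(bh, n_gwas = 20000, m_variants = 2000, h2 = 0.3)
  expect_equal(attr(w, "shrinkage"), 0.75)
  expect_equal(w$gamma, 0.75 * bh)
  expect_true(all(shrink_weights(bh, 100, 2000, 0)$gamma == 0))
})
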