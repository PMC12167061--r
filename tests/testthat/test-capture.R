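test_that("imputation_r2 matches the closed-form Pearson computation", {
  expect_equal(imputation_r2(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0)), 1)
  expect_equal(imputation_r2(c(0, 1, 2, 1, 0), 2 - c(0, 1, 2, 1, 0)), 1)
  # hand-expanded Pearson on the 5-point vectors: r^2 = 1.6^2 / (2.8 * 1.2)
  expect_equal(imputation_r2(c(0, 1, 2, 1, 0), c(0, 1, 1, 1, 0)), 16 / 21,
               tolerance = 1e-12)
  expect_equal(imputation_r2(c(0, 1, 2), c(1, 1, 1)), 0)
  expect_error(imputation_r2(c(1, 1, 1), c(0, 1, 2)),
               class = "prsceiling_constant_variant")
  expect_error(imputation_r2(1:2, 1:2), "length")
})

test_that("tagging_rho2 matches the normal-equations oracle on small panels", {
  for (s in 1:5) {
    p <- generate_panel(n = 120, m = 8, ld_strength = 0.6,
                        maf_spec = maf_uniform(0.15, 0.5),
                        mean_spacing_bp = 1000, seed = s) |>
      designate_genotyped(geno_fraction(0.5), seed = s)
    for (j in which(!p$meta$is_genotyped)) {
      expect_equal(as.numeric(tagging_rho2(p, j)), brute_rho2(p, j),
                   tolerance = 1e-10)
    }
  }
})

test_that("tagging_rho2 handles perfect, absent and screened predictors", {
  # duplicated genotyped variant: perfect tagging
  x <- generate_panel(n = 150, m = 4, ld_strength = 0,
                      maf_spec = maf_uniform(0.2, 0.5), seed = 9)
  dup <- cbind(x$true_dosage, x$true_dosage[, 1])
  p <- make_panel(dup, genotyped = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                  pos = as.integer(c(1, 2, 3, 4, 5) * 1000L))
  expect_equal(as.numeric(tagging_rho2(p, 5)), 1, tolerance = 1e-9)

  # independent variant: ~ 0 after adjustment and clamping
  expect_lt(as.numeric(tagging_rho2(p, 3)), 0.05)

  # no genotyped variant in window: 0 with a warning
  p2 <- make_panel(x$true_dosage,
                   genotyped = c(TRUE, FALSE, FALSE, FALSE),
                   pos = as.integer(c(1e6, 9e6, 9.1e6, 9.2e6)))
  expect_warning(r <- tagging_rho2(p2, 2), "no genotyped")
  expect_equal(as.numeric(r), 0)

  # genotyped variant requested: conventionally 1, signalled
  expect_error(tagging_rho2(p2, 1), "genotyped")

  # predictor overflow triggers marginal screening
  big <- generate_panel(n = 30, m = 40, ld_strength = 0.5,
                        maf_spec = maf_uniform(0.2, 0.5),
                        mean_spacing_bp = 100, seed = 2) |>
    designate_genotyped(geno_fraction(0.9), seed = 2)
  j <- which(!big$meta$is_genotyped)[1]
  r <- tagging_rho2(big, j)
  expect_identical(attr(r, "flag"), "screened")
  expect_true(r >= 0 && r <= 1)
})

test_that("captured-heritability formulas reduce to their identities", {
  maf <- c(0.1, 0.2, 0.3)
  eff <- sample_alpha_effects(maf, -0.5, 0.6, seed = 1)

  cap_all <- structure(
    tibble::tibble(index = 1:3, maf = maf,
                   is_genotyped = c(TRUE, TRUE, TRUE),
                   r2_imput = c(1, 1, 1), rho2 = c(1, 1, 1),
                   rho2_flag = "genotyped"),
    class = c("capture_table", class(tibble::tibble()))
  )
  expect_equal(h2_genotyped(eff, cap_all), 0.6, tolerance = 1e-12)
  expect_equal(h2_imputed(eff, cap_all), 0.6, tolerance = 1e-12)

  cap_none <- cap_all
  cap_none$is_genotyped <- FALSE
  cap_none$r2_imput <- 0
  cap_none$rho2 <- 0
  expect_equal(h2_genotyped(eff, cap_none), 0)
  expect_equal(h2_imputed(eff, cap_none), 0)
})

test_that("captured-heritability sums match direct arithmetic", {
  eff <- structure(
    tibble::tibble(index = 1:3, maf = c(0.1, 0.2, 0.3),
                   beta = sqrt(c(0.1, 0.2, 0.3)),
                   prior_variance = NA_real_),
    class = c("effect_profile", class(tibble::tibble()))
  )
  cap <- structure(
    tibble::tibble(index = 1:3, maf = c(0.1, 0.2, 0.3),
                   is_genotyped = c(TRUE, FALSE, FALSE),
                   r2_imput = c(1, 0.5, 0.25), rho2 = c(1, 0.5, 0.25),
                   rho2_flag = "ok"),
    class = c("capture_table", class(tibble::tibble()))
  )
  expect_equal(h2_genotyped(eff, cap), 0.1 + 0.1 + 0.075, tolerance = 1e-12)

  eff2 <- eff[1:2, ]
  cap2 <- cap[1:2, ]
  cap2$is_genotyped <- FALSE
  cap2$r2_imput <- c(0.5, 0.25)
  expect_equal(h2_imputed(eff2, cap2), 0.1 * 0.5 + 0.2 * 0.25,
               tolerance = 1e-12)
  expect_error(h2_genotyped(eff2, cap), "lengths differ")
})

test_that("capture summaries respect sandwich bounds on real draws", {
  st <- cached_study()
  for (a in c(-1.2, -0.6, 0)) {
    eff <- sample_alpha_effects(st$capture$maf, a, 0.5, seed = 30 + a * 10)
    s <- capture_summary(eff, st$capture)
    expect_true(s$h2_G >= 0 && s$h2_G <= s$h2_total + 1e-12)
    expect_true(s$h2_I >= 0 && s$h2_I <= s$h2_total + 1e-12)
  }
})

test_that("with genotyped variants perfectly imputed and r2 >= rho2, h2_I >= h2_G", {
  st <- cached_study()
  cap <- st$capture
  cap$r2_imput <- pmax(cap$r2_imput, cap$rho2)  # enforce the premise
  eff <- sample_alpha_effects(cap$maf, -0.8, 0.5, seed = 77)
  expect_gte(h2_imputed(eff, cap), h2_genotyped(eff, cap) - 1e-12)
})

test_that("capture proportion curves rise with alpha on the calibrated panel", {
  st <- cached_study()
  cv <- capture_proportion_curve(st$capture, alphas = c(-1.5, -0.75, 0),
                                 n_rep = 50, seed = 5)
  expect_gt(cv$prop_I[3], cv$prop_I[1])
  expect_gt(cv$prop_G[3], cv$prop_G[1])
  expect_true(all(cv$prop_G >= 0 & cv$prop_G <= 1))
  expect_true(all(cv$prop_I >= 0 & cv$prop_I <= 1))

  # degenerate panel: perfect imputation means prop_I is identically 1
  cap1 <- st$capture
  cap1$r2_imput <- 1
  cv1 <- capture_proportion_curve(cap1, alphas = c(-1, 0), n_rep = 0)
  expect_equal(cv1$prop_I, c(1, 1), tolerance = 1e-12)

  # analytic and Monte-Carlo curves agree
  cva <- capture_proportion_curve(st$capture, alphas = c(-0.75), n_rep = 0)
  cvm <- capture_proportion_curve(st$capture, alphas = c(-0.75), n_rep = 200,
                                  seed = 6)
  expect_equal(cvm$prop_G, cva$prop_G, tolerance = 0.05)
})
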