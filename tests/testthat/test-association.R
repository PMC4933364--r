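test_that("binary-exposure fit matches the 2x2 closed form", {
  y <- c(rep(1, 100), rep(0, 100))
  x <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  fit <- fit_logistic_dosage(y, x)
  expect_true(fit$converged)
  expect_equal(fit$or, (30 * 90) / (70 * 10), tolerance = 1e-6)
  woolf_se <- sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90)
  expect_equal(fit$se, woolf_se, tolerance = 1e-6)
  expect_equal(fit$ci_lower, exp(fit$beta - 1.96 * fit$se))
})

test_that("allele relabelling flips beta and leaves the P-value unchanged", {
  set.seed(14)
  cc <- quick_cc(200, 200, 0.3, 1.4)
  f1 <- fit_logistic_dosage(cc$phenotype, cc$dosage)
  f2 <- fit_logistic_dosage(cc$phenotype, 2 - cc$dosage)
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-7)
  expect_equal(f2$p, f1$p, tolerance = 1e-7)
  expect_equal(f2$se, f1$se, tolerance = 1e-7)
})

test_that("an uncorrelated covariate barely moves the estimate", {
  set.seed(15)
  diffs <- vapply(1:60, function(i) {
    cc <- quick_cc(150, 150, 0.3, 1.3)
    z <- rnorm(300)
    fit_logistic_dosage(cc$phenotype, cc$dosage, covariates = cbind(z = z))$beta -
      fit_logistic_dosage(cc$phenotype, cc$dosage)$beta
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 1e-3)
})

test_that("degenerate inputs are reported, never silently estimated", {
  expect_error(fit_logistic_dosage(rep(1, 10), rbinom(10, 2, 0.5)),
               "at least one case")
  fit <- fit_logistic_dosage(rep(c(0, 1), 10), rep(1, 20))
  expect_false(fit$converged)
  expect_equal(fit$note, "constant_dosage")
  # complete separation
  y <- c(rep(1, 20), rep(0, 20))
  x <- c(rep(2, 20), rep(0, 20))
  fit <- fit_logistic_dosage(y, x)
  expect_false(fit$converged)
  expect_true(nzchar(fit$note))
})

test_that("region scans return one row per variant and keep failures", {
  panel <- small_panel(n_variants = 15, seed = 19)
  design <- simulation_design("var0008", causal_or = 1.6, n_studies = 1,
                              cases_per_study = 200, controls_per_study = 200,
                              seed = 21)
  s <- simulate_case_control(panel, design)[[1]]
  scan <- run_region_scan(s)
  expect_equal(nrow(scan), 15)
  expect_true(all(c("chrom", "position") %in% names(scan)))
  one <- run_region_scan(s, variant_ids = "var0008")
  expect_equal(nrow(one), 1)
  expect_warning(empty <- run_region_scan(s, variant_ids = character(0)),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("the planted causal variant ranks among the smallest P-values", {
  panel <- small_panel(n_variants = 40, seed = 23)
  hits <- vapply(1:25, function(i) {
    design <- simulation_design("var0020", causal_or = 1.5, n_studies = 1,
                                cases_per_study = 400,
                                controls_per_study = 400, seed = 3000 + i)
    s <- simulate_case_control(panel, design)[[1]]
    scan <- run_region_scan(s)
    ranked <- scan$variant_id[order(scan$p)]
    match("var0020", ranked) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
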