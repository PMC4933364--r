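test_that("a single unit passes through unchanged", {
  m <- ivw_fixed(0.10, 0.05)
  expect_equal(m$beta_meta, 0.10)
  expect_equal(m$se_meta, 0.05)
  expect_equal(m$k, 1L)
  expect_true(m$degenerate)
  expect_equal(m$p_het, 1)
})

test_that("equal-weight units average and the variance halves", {
  m <- ivw_fixed(c(0.10, 0.30), c(0.05, 0.05))
  expect_equal(m$beta_meta, 0.20)
  expect_equal(m$se_meta, 0.05 / sqrt(2), tolerance = 1e-12)
  # duplicated unit halves the variance relative to the single unit
  single <- ivw_fixed(0.2, 0.1)
  dup <- ivw_fixed(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(dup$se_meta, single$se_meta / sqrt(2), tolerance = 1e-12)
})

test_that("order invariance and range containment hold", {
  set.seed(41)
  for (i in 1:30) {
    k <- sample(2:8, 1)
    beta <- rnorm(k, 0.1, 0.2)
    se <- runif(k, 0.02, 0.3)
    m1 <- ivw_fixed(beta, se)
    perm <- sample(k)
    m2 <- ivw_fixed(beta[perm], se[perm])
    expect_equal(m1$beta_meta, m2$beta_meta)
    expect_equal(m1$q, m2$q)
    expect_gte(m1$beta_meta, min(beta)); expect_lte(m1$beta_meta, max(beta))
    expect_lte(m1$se_meta, min(se))
  }
})

test_that("Cochran's Q matches the hand example and the chi-square tail", {
  h <- cochran_q(c(0.10, 0.30), c(0.05, 0.05))
  expect_equal(h$q, 8, tolerance = 1e-12)
  expect_equal(h$df, 1L)
  expect_equal(h$p_het, pchisq(8, 1, lower.tail = FALSE))
  expect_equal(h$p_het, 0.00468, tolerance = 1e-3)
  expect_equal(cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3))$q, 0)
})

test_that("results agree with metafor's fixed-effects fit", {
  skip_if_not_installed("metafor")
  set.seed(43)
  for (i in 1:10) {
    k <- sample(3:10, 1)
    beta <- rnorm(k, 0.15, 0.1)
    se <- runif(k, 0.03, 0.2)
    ours <- ivw_fixed(beta, se)
    ref <- metafor::rma(yi = beta, sei = se, method = "FE")
    expect_equal(ours$beta_meta, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$se_meta, ref$se, tolerance = 1e-8)
    expect_equal(ours$q, ref$QE, tolerance = 1e-8)
    expect_equal(ours$p_het, ref$QEp, tolerance = 1e-8)
  }
})

test_that("non-converged units are excluded and k reflects it", {
  m <- ivw_fixed(c(0.1, 5, 0.2), c(0.05, 0.01, 0.05),
                 converged = c(TRUE, FALSE, TRUE))
  expect_equal(m$k, 2L)
  expect_equal(m$beta_meta, 0.15)
  expect_error(ivw_fixed(c(1, 2), c(0.1, 0.1), converged = c(FALSE, FALSE)),
               "k = 0")
})

test_that("meta_scan groups stacked per-study scans by variant", {
  panel <- small_panel(n_variants = 10, seed = 29)
  design <- simulation_design("var0005", causal_or = 1.4, n_studies = 3,
                              cases_per_study = 150, controls_per_study = 150,
                              seed = 31)
  studies <- simulate_case_control(panel, design)
  scans <- lapply(studies, run_region_scan)
  meta <- meta_scan(scans)
  expect_equal(nrow(meta), 10)
  expect_true(all(meta$k == 3))
  expect_equal(meta$position, sort(meta$position))
})
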