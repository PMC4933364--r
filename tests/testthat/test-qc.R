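# Independent HWE oracle: enumerate heterozygote counts with the
# Levene/Haldane recurrence p(h+2)/p(h) = 4 homA homa / ((h+1)(h+2)),
# normalise, and sum configurations no more probable than observed.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  w <- numeric(length(hets))
  w[1] <- 1
  if (length(hets) > 1) for (i in 2:length(hets)) {
    h <- hets[i - 1]
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    w[i] <- w[i - 1] * 4 * hom_minor * hom_major / ((h + 1) * (h + 2))
  }
  p <- w / sum(w)
  p_obs <- p[match(n_Aa, hets)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

test_that("the exact HWE test agrees with the recurrence oracle", {
  expect_equal(hwe_test(20, 20, 20), hwe_oracle(20, 20, 20), tolerance = 1e-10)
  set.seed(31)
  for (i in 1:150) {
    n <- sample(3:200, 1)
    n_AA <- sample(0:n, 1)
    n_Aa <- sample(0:(n - n_AA), 1)
    n_aa <- n - n_AA - n_Aa
    expect_equal(hwe_test(n_AA, n_Aa, n_aa), hwe_oracle(n_AA, n_Aa, n_aa),
                 tolerance = 1e-9)
  }
})

test_that("HWE edge cases behave", {
  expect_equal(hwe_test(25, 50, 25), 1)          # most probable configuration
  expect_equal(hwe_test(0, 0, 100), 1)           # monomorphic
  expect_equal(hwe_test(100, 0, 0), 1)
  expect_error(hwe_test(-1, 5, 5), "non-negative")
  # gross heterozygote excess is detected by both flavours
  expect_lt(hwe_test(0, 100, 0), 1e-10)
  expect_lt(hwe_test(0, 100, 0, method = "chisq"), 1e-10)
})

test_that("genotyped-SNP filters apply the printed thresholds", {
  d <- filter_genotyped(0.979, 0.5, 0.3)
  expect_false(d$keep); expect_equal(d$reasons, "call_rate")
  d <- filter_genotyped(0.99, 5e-5, 0.3)
  expect_false(d$keep); expect_equal(d$reasons, "hwe")
  expect_true(filter_genotyped(1.0, 0.5, 0.3)$keep)
  expect_true(filter_genotyped(0.98, 1e-4, 0.005)$keep)  # boundaries keep
  d <- filter_genotyped(0.5, 1e-6, 0.001)
  expect_setequal(d$reasons, c("call_rate", "hwe", "maf"))
})

test_that("imputed-SNP filters follow the MAF-stratified Rsq rules", {
  expect_false(filter_imputed(0.02, 0.30)$keep)   # Rsq <= 0.3 is excluded
  expect_true(filter_imputed(0.02, 0.301)$keep)
  expect_true(filter_imputed(0.007, 0.50)$keep)   # 0.50 is not < 0.5
  expect_false(filter_imputed(0.007, 0.499)$keep)
  expect_true(filter_imputed(0.004, 0.99)$keep)
  expect_false(filter_imputed(0.004, 0.985)$keep)
  expect_true(filter_imputed(0.01, 0.5)$keep)     # endpoint in middle stratum
  expect_false(filter_imputed(0.01, 0.49)$keep)
})

test_that("keep is monotone in rsq and equivalent to empty reasons", {
  set.seed(17)
  for (i in 1:200) {
    maf <- runif(1, 0, 0.5)
    r1 <- runif(1); r2 <- runif(1)
    lo <- min(r1, r2); hi <- max(r1, r2)
    d_lo <- filter_imputed(maf, lo); d_hi <- filter_imputed(maf, hi)
    if (d_lo$keep) expect_true(d_hi$keep)
    for (d in list(d_lo, d_hi))
      expect_identical(d$keep, length(d$reasons) == 0L)
  }
})

test_that("study-level QC emits a complete report", {
  panel <- small_panel(n_variants = 12, seed = 10)
  design <- simulation_design("var0006", causal_or = 1.2, n_studies = 1,
                              cases_per_study = 150, controls_per_study = 150,
                              target_rsq = 0.9, seed = 12)
  s <- simulate_case_control(panel, design)[[1]]
  rep <- qc_study(s)
  expect_equal(nrow(rep), 12)
  expect_identical(rep$keep, rep$reasons == "")
})
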