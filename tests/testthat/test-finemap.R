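variant_table <- function(positions, chrom = "1") {
  data.frame(variant_id = sprintf("v%03d", seq_along(positions)),
             chrom = chrom, position = positions, stringsAsFactors = FALSE)
}

test_that("regions span the 500-kb window and clip at the chromosome start", {
  vt <- variant_table(c(200000, 750000, 1000000, 1250000, 1300001))
  r <- build_region("v003", vt)
  expect_equal(r$start, 750000L)
  expect_equal(r$end, 1250000L)
  expect_equal(r$end - r$start, 500000L)
  expect_false(r$truncated)
  expect_setequal(r$variants, c("v002", "v003", "v004"))
  expect_equal(r$n_snps, 3L)

  near <- build_region("v001", vt)
  expect_equal(near$start, 1L)
  expect_true(near$truncated)
  expect_error(build_region("nope", vt), "not found")
})

test_that("the region holds every variant inside the window", {
  set.seed(51)
  pos <- sort(sample.int(3e6, 4000))
  vt <- variant_table(pos)
  idx <- vt$variant_id[2000]
  r <- build_region(idx, vt)
  expect_equal(r$n_snps,
               sum(pos >= vt$position[2000] - 250000 &
                     pos <= vt$position[2000] + 250000))
})

test_that("top-SNP selection uses the deterministic tie rule", {
  m <- data.frame(variant_id = c("a", "b", "c"),
                  beta_meta = c(0.1, -0.3, 0.3),
                  p_meta = c(0.01, 0.001, 0.001),
                  position = c(10, 30, 20), converged = TRUE)
  # tie on p: larger |beta| wins; here equal |beta|, so smaller position
  expect_equal(find_top_snp(m), "c")
  m$beta_meta[2] <- -0.5
  expect_equal(find_top_snp(m), "b")
  expect_equal(find_top_snp(m[1, ]), "a")
  expect_error(find_top_snp(m[m$converged == FALSE, ]), "no converged")
})

test_that("regions sharing a top SNP collapse to one locus entry", {
  tops <- data.frame(locus = c("L1", "L1", "L2"),
                     index_snp = c("i1", "i2", "i3"),
                     top_snp = c("t1", "t1", "t3"))
  u <- unify_top_snps(tops)
  expect_equal(nrow(u), 2)
  expect_equal(u$n_regions[u$top_snp == "t1"], 2)
  expect_equal(u$index_snps[u$top_snp == "t1"], "i1,i2")
  # disjoint tops are the identity
  tops2 <- data.frame(index_snp = c("i1", "i2"), top_snp = c("t1", "t2"))
  expect_equal(nrow(unify_top_snps(tops2)), 2)
})

test_that("conditional scans use the per-region Bonferroni threshold", {
  panel <- small_panel(n_variants = 20, seed = 33)
  design <- simulation_design("var0010", causal_or = 1.5, n_studies = 2,
                              cases_per_study = 200, controls_per_study = 200,
                              seed = 35)
  studies <- simulate_case_control(panel, design)
  region <- build_region("var0010", studies[[1]]$variant_meta)
  cond <- conditional_scan(studies, region, "var0010")
  expect_equal(nrow(cond), region$n_snps - 1)
  expect_true(all(cond$alpha_region == 0.05 / region$n_snps))
  expect_equal(cond$significant[!cond$non_estimable],
               (cond$p_cond <= cond$alpha_region)[!cond$non_estimable])
})

test_that("variants collinear with the top SNP are flagged non-estimable", {
  panel <- small_panel(n_hap = 150, n_variants = 12, seed = 37)
  panel$haplotypes[, 4] <- panel$haplotypes[, 7]  # plant a perfect proxy
  design <- simulation_design("var0007", causal_or = 1.3, n_studies = 1,
                              cases_per_study = 150, controls_per_study = 150,
                              seed = 39)
  studies <- simulate_case_control(panel, design)
  region <- build_region("var0007", studies[[1]]$variant_meta)
  cond <- conditional_scan(studies, region, "var0007")
  expect_true(cond$non_estimable[cond$variant_id == "var0004"])
  expect_false(all(cond$non_estimable))
})

test_that("candidate sets reproduce a brute-force application of the rules", {
  for (rep in 1:8) {
    panel <- small_panel(n_hap = 100, n_variants = 25, seed = 600 + rep)
    causal <- "var0013"
    design <- simulation_design(causal, causal_or = 1.6, n_studies = 1,
                                cases_per_study = 150,
                                controls_per_study = 150, seed = 700 + rep)
    studies <- simulate_case_control(panel, design)
    region <- build_region(causal, studies[[1]]$variant_meta)
    meta <- meta_scan(run_region_scan(studies[[1]]))
    cs <- select_annotation_set(region, meta, panel)

    conv <- meta[meta$converged & meta$variant_id %in% region$variants, ]
    ord <- order(conv$p_meta, -abs(conv$beta_meta), conv$position)
    top <- conv$variant_id[ord[1]]
    top10 <- conv$variant_id[ord][1:min(10, nrow(conv))]
    h <- panel$haplotypes
    r2_with_index <- vapply(setdiff(top10, causal), function(w)
      r2_haplotypes(h[, causal], h[, w]), numeric(1))
    rule3 <- names(r2_with_index)[r2_with_index > 0.5]
    seeds <- unique(c(top, causal, rule3))
    rule4 <- setdiff(unique(unlist(lapply(seeds, function(v)
      Filter(function(w) abs(r2_haplotypes(h[, v], h[, w]) - 1) < 1e-12,
             setdiff(region$variants, v))))), seeds)

    expect_equal(cs$top_snp, top)
    expect_setequal(cs$rule3_members, rule3)
    expect_setequal(cs$rule4_members, rule4)
    expect_setequal(cs$all, unique(c(seeds, rule4)))
    expect_true(all(c(cs$top_snp, cs$index_snp) %in% cs$all))
  }
})

test_that("a degenerate region yields only the index SNP", {
  panel <- small_panel(n_hap = 100, n_variants = 25, seed = 61,
                       recombination_rate = 1e-3)
  causal <- "var0012"
  design <- simulation_design(causal, causal_or = 3, n_studies = 1,
                              cases_per_study = 400, controls_per_study = 400,
                              seed = 63)
  studies <- simulate_case_control(panel, design)
  region <- build_region(causal, studies[[1]]$variant_meta)
  meta <- meta_scan(run_region_scan(studies[[1]]))
  cs <- select_annotation_set(region, meta, panel)
  expect_true(causal %in% cs$all)
  if (cs$top_snp == causal && length(cs$rule3_members) == 0 &&
      length(cs$rule4_members) == 0)
    expect_equal(cs$all, causal)
})
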