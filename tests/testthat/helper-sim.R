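# Shared small-scale simulation fixtures, built in code at test time.

small_panel <- function(n_hap = 200, n_variants = 60, seed = 3,
                        recombination_rate = 1e-5, ...) {
  simulate_haplotype_panel(n_hap, n_variants, region_length = 5e5,
                           recombination_rate = recombination_rate,
                           seed = seed, ...)
}

# One quick case-control draw from a logistic population model with a
# binomial genotype -- independent of the haplotype-panel machinery, for
# tests that need a known allele frequency.
quick_cc <- function(n_case, n_ctrl, maf, or, prevalence = 0.1) {
  beta <- log(or)
  alpha <- uniroot(function(a) {
    g <- 0:2
    w <- dbinom(g, 2, maf)
    sum(w * plogis(a + beta * g)) - prevalence
  }, c(-20, 10))$root
  g_case <- integer(0); g_ctrl <- integer(0)
  while (length(g_case) < n_case || length(g_ctrl) < n_ctrl) {
    g <- rbinom(20000, 2, maf)
    y <- rbinom(20000, 1, plogis(alpha + beta * g))
    g_case <- c(g_case, g[y == 1])[seq_len(min(n_case, length(g_case) + sum(y == 1)))]
    g_ctrl <- c(g_ctrl, g[y == 0])[seq_len(min(n_ctrl, length(g_ctrl) + sum(y == 0)))]
  }
  list(phenotype = c(rep(1L, n_case), rep(0L, n_ctrl)),
       dosage = c(g_case, g_ctrl))
}

# A fully populated regulatory evidence profile (noncoding score 7).
full_evidence <- function(variant_id) {
  evidence_record(variant_id, histone_mark = TRUE, open_chromatin = TRUE,
                  protein_binding = TRUE, cancer_normal_differential = TRUE,
                  colorectal_evidence = TRUE, motif_altered = TRUE,
                  conserved = TRUE)
}

# Enumerate every constructible evidence record over the six +1 and two
# +0.5 components (binding_in_context is derived; dependent booleans are
# skipped when their preconditions fail).
enumerate_valid_records <- function(coding_class = "noncoding") {
  grid <- expand.grid(histone = c(FALSE, TRUE), open = c(FALSE, TRUE),
                      protein = c(FALSE, TRUE), diff = c(FALSE, TRUE),
                      crc = c(FALSE, TRUE), motif = c(FALSE, TRUE),
                      cons = c(FALSE, TRUE))
  records <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$diff && !g$histone) next
    if (g$crc && !(g$open || g$histone || g$protein)) next
    records[[length(records) + 1L]] <- evidence_record(
      sprintf("v%03d", i), histone_mark = g$histone, open_chromatin = g$open,
      protein_binding = g$protein, cancer_normal_differential = g$diff,
      colorectal_evidence = g$crc, motif_altered = g$motif,
      conserved = g$cons, coding_class = coding_class)
  }
  records
}
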