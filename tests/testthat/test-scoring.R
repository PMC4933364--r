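test_that("the noncoding score reaches at most 7 and is monotone", {
  records <- enumerate_valid_records()
  scores <- vapply(records, function(r) score_evidence(r)$score, numeric(1))
  expect_equal(max(scores), 7)
  expect_equal(min(scores), 0)
  expect_true(all(scores * 2 == round(scores * 2)))  # half-integer grid
  # monotonicity: turning any single false boolean on never lowers the score
  flip_fields <- c("histone_mark", "open_chromatin", "protein_binding",
                   "cancer_normal_differential", "colorectal_evidence",
                   "motif_altered", "conserved")
  for (r in records[seq(1, length(records), by = 3)]) {
    s0 <- score_evidence(r)$score
    for (f in flip_fields) {
      if (r[[f]]) next
      args <- r[setdiff(names(r), "binding_in_context")]
      args[[f]] <- TRUE
      r2 <- tryCatch(do.call(evidence_record, args), error = function(e) NULL)
      if (is.null(r2)) next  # flip violates a structural precondition
      expect_gte(score_evidence(r2)$score, s0)
    }
  }
})

test_that("PolyPhen classes override or fall back as published", {
  base <- list(variant_id = "v", histone_mark = TRUE, open_chromatin = TRUE,
               protein_binding = TRUE, colorectal_evidence = TRUE)
  poss <- do.call(evidence_record, c(base, coding_class = "possibly_damaging"))
  prob <- do.call(evidence_record, c(base, coding_class = "probably_damaging"))
  expect_equal(score_evidence(poss)$score, 8)
  expect_equal(score_evidence(prob)$score, 9)
  expect_equal(score_evidence(poss)$category, "strong")
  # benign/unknown coding variants score as non-coding regulatory variants
  for (cls in c("benign", "unknown")) {
    r <- do.call(evidence_record, c(base, coding_class = cls))
    expect_equal(score_evidence(r)$score,
                 score_evidence(do.call(evidence_record, base))$score)
  }
})

test_that("category edges partition all attainable scores", {
  expect_equal(categorize_score(3.5), "weak")
  expect_equal(categorize_score(4.0), "moderate")
  expect_equal(categorize_score(2.5), "none")
  attainable <- c(seq(0, 7, by = 0.5), 8, 9)
  cats <- categorize_score(attainable)
  expect_equal(unname(cats[attainable < 3]),
               rep("none", sum(attainable < 3)))
  expect_true(all(cats[attainable >= 3 & attainable <= 3.5] == "weak"))
  expect_true(all(cats[attainable >= 4 & attainable <= 4.5] == "moderate"))
  expect_true(all(cats[attainable >= 5] == "strong"))
})

test_that("an inconsistent binding-in-context flag is rejected", {
  expect_error(evidence_record("v", binding_in_context = TRUE),
               "protein_binding")
  expect_error(evidence_record("v", protein_binding = TRUE,
                               open_chromatin = TRUE,
                               binding_in_context = FALSE),
               "inconsistent")
})

test_that("the printed evidence row for rs3217827 scores 5 (strong)", {
  cand <- load_strong_candidates()
  rec <- encode_reported_evidence(cand[cand$variant_id == "rs3217827", ])[[1]]
  expect_false(rec$cancer_normal_differential)
  expect_true(rec$colorectal_evidence)
  s <- score_evidence(rec)
  expect_equal(s$score, 5)
  expect_equal(s$category, "strong")
})

test_that("gene context handles genic, intergenic and empty layouts", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = "1",
                      start = c(1000, 50000), end = c(5000, 60000),
                      strand = c("+", "-"))
  v <- list(variant_id = "x", chrom = "1", position = 3000)
  ctx <- assign_gene_context(v, genes)
  expect_equal(ctx$predicted_gene, "G1")
  expect_equal(ctx$location_class, "intronic")
  expect_equal(ctx$orientation, "within")
  ctx <- assign_gene_context(v, genes,
                             exons = data.frame(gene = "G1", start = 2500,
                                                end = 3500))
  expect_equal(ctx$location_class, "exonic")
  # 10 kb 5' of G1 on + strand
  ctx <- assign_gene_context(list(variant_id = "y", chrom = "1",
                                  position = 100), genes)
  expect_equal(ctx$predicted_gene, "G1")
  expect_equal(ctx$orientation, "upstream_5prime")
  # downstream of G2 end on - strand is 5'
  ctx <- assign_gene_context(list(variant_id = "z", chrom = "1",
                                  position = 61000), genes)
  expect_equal(ctx$predicted_gene, "G2")
  expect_equal(ctx$orientation, "upstream_5prime")
  none <- assign_gene_context(list(variant_id = "w", chrom = "9",
                                   position = 100), genes)
  expect_true(is.na(none$predicted_gene))
})

test_that("nearest-gene assignment matches a brute-force distance search", {
  set.seed(71)
  for (i in 1:50) {
    n_genes <- sample(2:6, 1)
    starts <- sort(sample.int(1e6, n_genes))
    genes <- data.frame(gene = sprintf("G%d", seq_len(n_genes)), chrom = "1",
                        start = starts,
                        end = starts + sample(1000:20000, n_genes),
                        strand = sample(c("+", "-"), n_genes, replace = TRUE))
    pos <- sample.int(1.1e6, 1)
    ctx <- assign_gene_context(list(variant_id = "v", chrom = "1",
                                    position = pos), genes)
    inside <- which(genes$start <= pos & pos <= genes$end)
    if (length(inside)) {
      expect_equal(ctx$orientation, "within")
    } else {
      d <- pmin(abs(pos - genes$start), abs(pos - genes$end))
      expect_equal(ctx$predicted_gene, genes$gene[which.min(d)])
      expect_equal(ctx$location_class, "intergenic")
    }
  }
})

test_that("the candidate-table summary tabulates deterministically", {
  empty <- score_candidate_table(NULL)
  expect_equal(empty$n_strong, 0L)
  one <- data.frame(variant_id = "v", locus = "L", is_index = FALSE,
                    location_class = "intronic", motif_altered = TRUE,
                    score = 5, category = "strong")
  s <- score_candidate_table(one)
  expect_equal(s$n_strong, 1L)
  expect_equal(s$n_loci_strong, 1L)
  expect_equal(s$n_strong_motif, 1L)
})
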