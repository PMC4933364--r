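test_that("planted records round-trip through the track bundle exactly", {
  panel <- small_panel(n_variants = 40, seed = 45)
  records <- enumerate_valid_records()
  set.seed(46)
  pick <- sample(seq_along(records), 25)
  planted <- list()
  for (i in seq_along(pick)) {
    v <- panel$variant_ids[i]
    r <- records[[pick[i]]]
    r$variant_id <- v
    planted[[v]] <- r
  }
  bundle <- simulate_annotation_tracks(panel, planted, withr::local_tempdir(),
                                       background_rate = 0, seed = 2)
  out <- evidence_from_tracks(panel, bundle)
  for (v in names(planted))
    expect_identical(out[[v]], planted[[v]])
  # background rate 0: every unplanted variant scores 0
  unplanted <- setdiff(panel$variant_ids, names(planted))
  scores <- vapply(out[unplanted], function(r) score_evidence(r)$score,
                   numeric(1))
  expect_true(all(scores == 0))
})

test_that("a full evidence profile recovers the maximum score of 7", {
  panel <- small_panel(n_variants = 10, seed = 47)
  v <- "var0004"
  bundle <- simulate_annotation_tracks(
    panel, setNames(list(full_evidence(v)), v), withr::local_tempdir(),
    background_rate = 0, seed = 3)
  rec <- evidence_from_tracks(panel, bundle)[[v]]
  expect_equal(score_evidence(rec)$score, 7)
  # an empty record stays empty
  v2 <- "var0006"
  bundle2 <- simulate_annotation_tracks(
    panel, setNames(list(evidence_record(v2)), v2), withr::local_tempdir(),
    background_rate = 0, seed = 3)
  expect_equal(score_evidence(evidence_from_tracks(panel, bundle2)[[v2]])$score, 0)
})

test_that("coding classes round-trip through the PolyPhen table", {
  panel <- small_panel(n_variants = 10, seed = 48)
  planted <- list(
    var0002 = evidence_record("var0002", open_chromatin = TRUE,
                              coding_class = "possibly_damaging"),
    var0005 = evidence_record("var0005", coding_class = "probably_damaging"))
  bundle <- simulate_annotation_tracks(panel, planted, withr::local_tempdir(),
                                       background_rate = 0, seed = 4)
  out <- evidence_from_tracks(panel, bundle)
  expect_equal(score_evidence(out$var0002)$score, 8)
  expect_equal(score_evidence(out$var0005)$score, 9)
})

test_that("the motif threshold is strictly greater than 5", {
  panel <- small_panel(n_variants = 6, seed = 49)
  dir <- withr::local_tempdir()
  simulate_annotation_tracks(panel, list(), dir, background_rate = 0, seed = 5)
  write.table(data.frame(variant_id = c("var0001", "var0002"),
                         ref_lod = c(0, 0), alt_lod = c(5.0, 5.01)),
              file.path(dir, "motif_lod.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  out <- evidence_from_tracks(panel, dir)
  expect_false(out$var0001$motif_altered)   # delta exactly 5 does not count
  expect_true(out$var0002$motif_altered)
  # sign of the change is irrelevant
  write.table(data.frame(variant_id = "var0003", ref_lod = 6, alt_lod = 0),
              file.path(dir, "motif_lod.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_true(evidence_from_tracks(panel, dir)$var0003$motif_altered)
})

test_that("unknown planted ids and malformed tracks fail loudly", {
  panel <- small_panel(n_variants = 6, seed = 50)
  expect_error(
    simulate_annotation_tracks(panel, list(nope = evidence_record("nope")),
                               withr::local_tempdir()),
    "not in panel")
  dir <- withr::local_tempdir()
  simulate_annotation_tracks(panel, list(), dir, seed = 6)
  writeLines(c("chr1\t10\tnot_a_number\tx"), file.path(dir, "conserved.bed"))
  expect_error(evidence_from_tracks(panel, dir), "malformed BED")
  # a missing track defaults to FALSE with a warning
  file.remove(file.path(dir, "conserved.bed"))
  expect_warning(out <- evidence_from_tracks(panel, dir), "missing track")
  expect_false(out$var0001$conserved)
})

test_that("background evidence appears at roughly the configured rate", {
  panel <- simulate_haplotype_panel(50, 400, region_length = 1e6, seed = 51)
  bundle <- simulate_annotation_tracks(panel, list(), withr::local_tempdir(),
                                       background_rate = 0.2, seed = 7)
  out <- evidence_from_tracks(panel, bundle)
  open_rate <- mean(vapply(out, `[[`, logical(1), "open_chromatin"))
  expect_gt(open_rate, 0.1); expect_lt(open_rate, 0.3)
})
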