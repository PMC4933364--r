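#' Published region-scan summary bundled with the package
#'
#' Summary of the association scans of the 31 fine-mapped 500-kb regions
#' around GWAS-identified colorectal-cancer index SNPs: locus, index SNP,
#' number of SNPs in the region, the top SNP (smallest meta-analysis P)
#' with its position, reference-panel r-squared with the index SNP, odds
#' ratio, confidence interval and P-values. Used as a worked example for
#' the bookkeeping operations ([bucket_r2()], [unify_top_snps()]).
#'
#' r-squared values reported only as below 0.2 appear in the file as the
#' literal string `<0.2`; [load_region_scan_summary()] represents them
#' numerically as 0.1 with a `r2_censored` flag (interval membership, not
#' a point value — 0.1 is used solely so that binning and maxima behave,
#' and no other value in the table falls below 0.2).
#'
#' @return data.frame with one row per (index SNP, region).
#' @export
load_region_scan_summary <- function() {
  path <- system.file("extdata", "reported_region_scan.tsv",
                      package = "finemapcrc", mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(r2_with_index = "character"))
  d$r2_censored <- d$r2_with_index == "<0.2"
  d$r2_numeric <- ifelse(d$r2_censored, 0.1, suppressWarnings(
    as.numeric(d$r2_with_index)))
  d
}

#' Per-top-SNP r-squared with the index SNP(s)
#'
#' Collapses the region-scan summary to the unique top SNPs. For loci with
#' several index SNPs the r-squared attributed to a top SNP is the maximum
#' over that locus's index SNPs (censored `<0.2` entries never dominate a
#' measured value).
#'
#' @param scan the [load_region_scan_summary()] table.
#' @return data.frame: `top_snp`, `r2_max`, `censored` (all contributing
#'   values were below 0.2), `n_regions`.
#' @export
top_snp_r2_summary <- function(scan = load_region_scan_summary()) {
  groups <- split(scan, scan$top_snp)
  out <- lapply(groups, function(d) {
    i <- which.max(d$r2_numeric)
    data.frame(top_snp = d$top_snp[1],
               r2_max = d$r2_numeric[i],
               censored = all(d$r2_censored),
               n_regions = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$top_snp, scan$top_snp)), , drop = FALSE]
}

#' Published strong functional candidates bundled with the package
#'
#' The 21 variants reported with strong functional evidence, with their
#' printed annotation columns: open-chromatin cell-line counts (and
#' whether a colorectal-cancer line is among them), histone-mark counts in
#' cancer/progenitor and normal ENCODE cell lines, histone marks in normal
#' colorectal tissues, bound proteins, altered binding motifs, and
#' conserved-element evidence.
#'
#' @return data.frame with one row per candidate variant.
#' @export
load_strong_candidates <- function() {
  path <- system.file("extdata", "reported_strong_candidates.tsv",
                      package = "finemapcrc", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(r2_with_index = "character"))
}

#' Encode printed annotation columns as evidence records
#'
#' Maps the published evidence columns onto [evidence_record()] booleans:
#' open chromatin iff any cell line shows it; histone mark iff any
#' cancer-line, normal-line or normal-colorectal-tissue source shows one;
#' protein binding iff any protein is listed; cancer-vs-normal
#' differential iff the cancer/progenitor and normal ENCODE *cell line*
#' histone columns disagree in overlap status (the tissue column reflects
#' a different assay programme and feeds the histone and colorectal
#' booleans instead); colorectal evidence iff any assay is tagged to a
#' colorectal cancer cell line or normal colon/rectal tissue; motif and
#' conservation directly. All candidates are non-coding, so
#' `coding_class = "noncoding"` throughout.
#'
#' @param candidates the [load_strong_candidates()] table (or a subset).
#' @return named list of `evidence_record` objects.
#' @export
encode_reported_evidence <- function(candidates = load_strong_candidates()) {
  records <- lapply(seq_len(nrow(candidates)), function(i) {
    d <- candidates[i, ]
    open <- d$n_open_chromatin_lines > 0
    hist_cancer <- d$n_histone_cancer_lines > 0
    hist_normal_cl <- d$n_histone_normal_lines > 0
    hist_tissue <- d$histone_normal_colorectal == 1
    histone <- hist_cancer || hist_normal_cl || hist_tissue
    protein <- !is.na(d$proteins_bound) && d$proteins_bound != "."
    evidence_record(
      variant_id = d$variant_id,
      histone_mark = histone,
      open_chromatin = open,
      protein_binding = protein,
      cancer_normal_differential = xor(hist_cancer, hist_normal_cl),
      colorectal_evidence = hist_tissue ||
        d$open_chromatin_crc_line == 1 || d$protein_binding_crc_line == 1,
      motif_altered = !is.na(d$altered_motifs) && d$altered_motifs != ".",
      conserved = d$conserved == 1,
      coding_class = "noncoding")
  })
  names(records) <- candidates$variant_id
  records
}

#' Score the published candidate table end to end
#'
#' Encodes the printed evidence columns, applies [score_evidence()] and
#' [categorize_score()], and returns the per-variant table expected by
#' [score_candidate_table()].
#'
#' @param candidates the [load_strong_candidates()] table.
#' @return data.frame: `variant_id`, `locus`, `is_index`,
#'   `location_class`, `motif_altered`, `score`, `category`.
#' @export
score_reported_candidates <- function(candidates = load_strong_candidates()) {
  records <- encode_reported_evidence(candidates)
  scores <- lapply(records, score_evidence)
  data.frame(
    variant_id = candidates$variant_id,
    locus = candidates$locus,
    is_index = candidates$r2_with_index == "index",
    location_class = candidates$location_class,
    motif_altered = vapply(records, `[[`, logical(1), "motif_altered"),
    score = vapply(scores, `[[`, numeric(1), "score"),
    category = vapply(scores, `[[`, character(1), "category"),
    stringsAsFactors = FALSE, row.names = NULL)
}
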