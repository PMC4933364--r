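#' Construct a per-variant regulatory evidence record
#'
#' Boolean summary of the regulatory annotations at one variant, as used by
#' the a-priori functional-evidence score. `binding_in_context` (protein
#' binding co-located with open chromatin or a histone mark) is derived
#' automatically when not supplied; supplying an inconsistent value is an
#' error, as is `colorectal_evidence` with no supporting assay or
#' `cancer_normal_differential` without any histone overlap.
#'
#' @param variant_id label.
#' @param histone_mark any histone enhancer/promoter modification overlap.
#' @param open_chromatin DNase-style open-chromatin overlap.
#' @param protein_binding any bound regulatory protein.
#' @param binding_in_context protein binding in the presence of open
#'   chromatin or a histone mark; derived if `NULL`.
#' @param cancer_normal_differential histone overlap status differs between
#'   cancer-tagged and normal-tagged sources.
#' @param colorectal_evidence any regulatory overlap in a colorectal cancer
#'   cell line or normal colon/rectal tissue.
#' @param motif_altered position-weight-matrix log-odds change > 5 between
#'   alleles.
#' @param conserved conserved-element overlap.
#' @param coding_class PolyPhen-style class; one of `noncoding`, `benign`,
#'   `unknown`, `possibly_damaging`, `probably_damaging`.
#' @return an `evidence_record`.
#' @export
evidence_record <- function(variant_id,
                            histone_mark = FALSE,
                            open_chromatin = FALSE,
                            protein_binding = FALSE,
                            binding_in_context = NULL,
                            cancer_normal_differential = FALSE,
                            colorectal_evidence = FALSE,
                            motif_altered = FALSE,
                            conserved = FALSE,
                            coding_class = "noncoding") {
  coding_class <- match.arg(coding_class,
                            c("noncoding", "benign", "unknown",
                              "possibly_damaging", "probably_damaging"))
  derived <- protein_binding && (open_chromatin || histone_mark)
  if (is.null(binding_in_context)) {
    binding_in_context <- derived
  } else {
    if (binding_in_context && !protein_binding)
      stop_invalid("binding_in_context requires protein_binding")
    if (binding_in_context != derived)
      stop_invalid(paste0(
        "binding_in_context (%s) inconsistent with point-overlap evidence ",
        "(protein %s, open chromatin %s, histone %s)"),
        binding_in_context, protein_binding, open_chromatin, histone_mark)
  }
  if (cancer_normal_differential && !histone_mark)
    stop_invalid("cancer_normal_differential requires some histone overlap")
  if (colorectal_evidence &&
      !(open_chromatin || histone_mark || protein_binding))
    stop_invalid("colorectal_evidence requires at least one regulatory assay")
  structure(
    list(variant_id = variant_id,
         histone_mark = isTRUE(histone_mark),
         open_chromatin = isTRUE(open_chromatin),
         protein_binding = isTRUE(protein_binding),
         binding_in_context = isTRUE(binding_in_context),
         cancer_normal_differential = isTRUE(cancer_normal_differential),
         colorectal_evidence = isTRUE(colorectal_evidence),
         motif_altered = isTRUE(motif_altered),
         conserved = isTRUE(conserved),
         coding_class = coding_class),
    class = "evidence_record")
}

evidence_booleans <- c("histone_mark", "open_chromatin", "protein_binding",
                       "binding_in_context", "cancer_normal_differential",
                       "colorectal_evidence", "motif_altered", "conserved")

#' The a-priori functional-evidence score of a variant
#'
#' Coding variants predicted possibly or probably damaging are assigned 8
#' or 9 respectively. All other variants (including benign/unknown coding
#' variants, which are scored as non-coding regulatory variants) receive
#' the sum: histone modification (+1), open chromatin (+1), protein
#' binding (+1), protein binding in the presence of open chromatin or
#' histone modification (+1), different histone patterns in cancerous vs
#' noncancerous sources (+1), regulatory evidence in a colorectal cancer
#' cell line or normal colon/rectal tissue (+1), altered binding motif
#' (+0.5), conserved region (+0.5) — a maximum of 7.
#'
#' @param record an [evidence_record()].
#' @return list with `variant_id`, `score` and `category`
#'   (see [categorize_score()]).
#' @export
score_evidence <- function(record) {
  stopifnot(inherits(record, "evidence_record"))
  if (record$binding_in_context && !record$protein_binding)
    stop_invalid("invalid record: binding_in_context without protein_binding")
  score <- switch(record$coding_class,
    possibly_damaging = 8,
    probably_damaging = 9,
    record$histone_mark + record$open_chromatin + record$protein_binding +
      record$binding_in_context + record$cancer_normal_differential +
      record$colorectal_evidence +
      0.5 * record$motif_altered + 0.5 * record$conserved)
  list(variant_id = record$variant_id, score = score,
       category = categorize_score(score))
}

#' Category of a functional-evidence score
#'
#' `none` below 3, `weak` for 3-3.5, `moderate` for 4-4.5, `strong` for 5
#' and above (which includes the 8/9 coding overrides). Scores are
#' half-integers, so the category bands partition the attainable range.
#'
#' @param score numeric score.
#' @return character scalar (or vector, vectorised over `score`).
#' @export
categorize_score <- function(score) {
  if (any(score < 0)) stop_invalid("scores are non-negative")
  ifelse(score >= 5, "strong",
         ifelse(score >= 4, "moderate",
                ifelse(score >= 3, "weak", "none")))
}

#' Predict the regulated gene by proximity and orientation
#'
#' A variant inside a gene is assigned that gene (`intronic` or `exonic`
#' by exon overlap, orientation `within`). An intergenic variant is
#' assigned the gene with the nearest transcript end, with orientation
#' recorded as 5' (upstream of the gene start) or 3' (downstream of the
#' end) relative to that gene's strand. With no gene on the chromosome an
#' explicit no-gene result is returned, not an error.
#'
#' @param variant list or one-row data.frame with `variant_id`, `chrom`,
#'   `position`.
#' @param gene_models data.frame with `gene`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param exons optional data.frame with `gene`, `start`, `end` for exonic
#'   classification; absent exons mean genic hits are called intronic.
#' @return list: `variant_id`, `location_class`, `predicted_gene`,
#'   `orientation` (`within`, `upstream_5prime`, `downstream_3prime`, or
#'   `NA` when no gene exists on the chromosome).
#' @export
assign_gene_context <- function(variant, gene_models, exons = NULL) {
  pos <- variant$position
  g <- gene_models[gene_models$chrom == variant$chrom, , drop = FALSE]
  if (nrow(g) == 0L)
    return(list(variant_id = variant$variant_id,
                location_class = "intergenic",
                predicted_gene = NA_character_, orientation = NA_character_))
  inside <- which(g$start <= pos & pos <= g$end)
  if (length(inside)) {
    gene <- g$gene[inside[1]]
    loc <- "intronic"
    if (!is.null(exons)) {
      e <- exons[exons$gene == gene & exons$start <= pos & pos <= exons$end, ]
      if (nrow(e)) loc <- "exonic"
    }
    return(list(variant_id = variant$variant_id, location_class = loc,
                predicted_gene = gene, orientation = "within"))
  }
  dist_to_end <- pmin(abs(pos - g$start), abs(pos - g$end))
  i <- order(dist_to_end, g$start)[1]
  before <- pos < g$start[i]
  plus <- g$strand[i] == "+"
  orientation <- if (before == plus) "upstream_5prime" else "downstream_3prime"
  list(variant_id = variant$variant_id, location_class = "intergenic",
       predicted_gene = g$gene[i], orientation = orientation)
}

#' Tabulate a scored candidate table
#'
#' Deterministic summary of a scored set: counts per category, and for the
#' strong candidates the locus count, genomic-location split, number with
#' motif alterations, and the loci in which the index SNP itself is a
#' strong candidate.
#'
#' @param scored data.frame with columns `variant_id`, `locus`,
#'   `is_index` (logical), `location_class`, `motif_altered` (logical),
#'   `score`, `category`.
#' @return list of summary counts.
#' @export
score_candidate_table <- function(scored) {
  empty <- list(
    n = 0L,
    by_category = c(none = 0L, weak = 0L, moderate = 0L, strong = 0L),
    n_strong = 0L, n_loci_strong = 0L,
    strong_by_location = integer(0), n_strong_motif = 0L,
    n_loci_index_strong = 0L, loci_index_strong = character(0))
  if (is.null(scored) || nrow(scored) == 0L) return(empty)
  by_cat <- empty$by_category
  tab <- table(scored$category)
  by_cat[names(tab)] <- as.integer(tab)
  strong <- scored[scored$category == "strong", , drop = FALSE]
  idx_loci <- sort(unique(strong$locus[strong$is_index]))
  list(
    n = nrow(scored),
    by_category = by_cat,
    n_strong = nrow(strong),
    n_loci_strong = length(unique(strong$locus)),
    strong_by_location = table(strong$location_class),
    n_strong_motif = sum(strong$motif_altered),
    n_loci_index_strong = length(idx_loci),
    loci_index_strong = idx_loci)
}
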