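#' Write a synthetic annotation track bundle
#'
#' Emits local BED/TSV evidence files (the stand-in for ENCODE/Roadmap
#' style tracks) such that reading them back with
#' [evidence_from_tracks()] reproduces each planted [evidence_record()]
#' exactly. Intervals are written with width 1 (covering exactly the
#' variant base, BED 0-based half-open at the file boundary) so planted
#' evidence never leaks onto neighbouring variants. Unplanted variants
#' receive independent background evidence per assay at a sparse rate.
#'
#' Bundle layout (all in `dir`): `open_chromatin.bed`,
#' `histone_marks.bed`, `protein_binding.bed`, `conserved.bed` with the
#' BED name field encoding `source|class|crc` (class `cancer`/`normal`;
#' `crc` 1 for colorectal cell line or normal colon/rectal tissue
#' sources), `motif_lod.tsv` (`variant_id`, `ref_lod`, `alt_lod`), and
#' `polyphen.tsv` (`variant_id`, `class`).
#'
#' @param panel a `haplotype_panel` providing variant positions.
#' @param planted named list of [evidence_record()]s; names are panel
#'   variant ids (unknown ids are an error).
#' @param dir output directory (created if needed).
#' @param background_rate per-assay probability that an unplanted variant
#'   receives that evidence (default 0).
#' @param seed integer seed for the background draws.
#' @return an `annotation_bundle` (list of file paths), invisibly usable
#'   by [evidence_from_tracks()].
#' @export
simulate_annotation_tracks <- function(panel, planted, dir,
                                       background_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (length(planted)) {
    stopifnot(!is.null(names(planted)),
              all(vapply(planted, inherits, logical(1), "evidence_record")))
    unknown <- setdiff(names(planted), panel$variant_ids)
    if (length(unknown))
      stop_invalid("planted variant id(s) not in panel: %s",
                   paste(unknown, collapse = ", "))
  }
  if (background_rate < 0 || background_rate > 1)
    stop_invalid("background_rate must be in [0, 1]")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  set.seed(seed)
  records <- planted
  for (v in setdiff(panel$variant_ids, names(planted))) {
    draw <- runif(5) < background_rate
    if (!any(draw)) next
    records[[v]] <- evidence_record(
      variant_id = v,
      open_chromatin = draw[1], histone_mark = draw[2],
      protein_binding = draw[3], motif_altered = draw[4],
      conserved = draw[5])
  }

  open_rows <- list(); hist_rows <- list(); prot_rows <- list()
  cons_rows <- list(); motif_rows <- list(); poly_rows <- list()
  add <- function(rows, v, source, class, crc) {
    pos <- panel$positions[match(v, panel$variant_ids)]
    c(rows, list(data.frame(pos = pos,
                            name = paste(source, class, crc, sep = "|"))))
  }
  for (v in names(records)) {
    r <- records[[v]]
    carrier <- if (!r$colorectal_evidence) "none"
               else if (r$open_chromatin) "open"
               else if (r$protein_binding) "protein"
               else "histone"
    if (r$open_chromatin) {
      open_rows <- add(open_rows, v, "syn_dnase_cell", "normal", 0)
      if (carrier == "open")
        open_rows <- add(open_rows, v, "syn_dnase_crc_line", "cancer", 1)
    }
    if (r$histone_mark) {
      normal_src <- if (carrier == "histone")
        c("syn_colon_mucosa", 1) else c("syn_normal_line", 0)
      if (r$cancer_normal_differential) {
        if (carrier == "histone")
          hist_rows <- add(hist_rows, v, normal_src[1], "normal", normal_src[2])
        else
          hist_rows <- add(hist_rows, v, "syn_cancer_line", "cancer", 0)
      } else {
        hist_rows <- add(hist_rows, v, "syn_cancer_line", "cancer", 0)
        hist_rows <- add(hist_rows, v, normal_src[1], "normal", normal_src[2])
      }
    }
    if (r$protein_binding) {
      if (carrier == "protein")
        prot_rows <- add(prot_rows, v, "syn_tf_crc_line", "cancer", 1)
      else
        prot_rows <- add(prot_rows, v, "syn_tf", "normal", 0)
    }
    if (r$conserved)
      cons_rows <- add(cons_rows, v, "phastcons", "normal", 0)
    if (r$motif_altered)
      motif_rows <- c(motif_rows, list(data.frame(
        variant_id = v, ref_lod = 0, alt_lod = 6)))
    if (r$coding_class != "noncoding")
      poly_rows <- c(poly_rows, list(data.frame(
        variant_id = v, class = r$coding_class)))
  }

  write_bed <- function(rows, file) {
    path <- file.path(dir, file)
    if (length(rows)) {
      d <- do.call(rbind, rows)
      gr <- GenomicRanges::GRanges(
        seqnames = panel$chrom,
        ranges = IRanges::IRanges(start = d$pos, end = d$pos),
        name = d$name)
      rtracklayer::export(gr, path, format = "BED")
    } else {
      file.create(path)
    }
    path
  }
  write_tsv <- function(rows, file, template) {
    path <- file.path(dir, file)
    d <- if (length(rows)) do.call(rbind, rows) else template
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  bundle <- list(
    dir = dir,
    open_chromatin = write_bed(open_rows, "open_chromatin.bed"),
    histone_marks = write_bed(hist_rows, "histone_marks.bed"),
    protein_binding = write_bed(prot_rows, "protein_binding.bed"),
    conserved = write_bed(cons_rows, "conserved.bed"),
    motif_lod = write_tsv(motif_rows, "motif_lod.tsv",
                          data.frame(variant_id = character(0),
                                     ref_lod = numeric(0),
                                     alt_lod = numeric(0))),
    polyphen = write_tsv(poly_rows, "polyphen.tsv",
                         data.frame(variant_id = character(0),
                                    class = character(0))))
  class(bundle) <- "annotation_bundle"
  invisible(bundle)
}

read_bundle_bed <- function(path) {
  if (is.null(path) || !file.exists(path)) {
    warning("missing track file ", path %||% "<NULL>",
            "; its evidence defaults to FALSE")
    return(GenomicRanges::GRanges())
  }
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  lines <- readLines(path)
  body <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 4 || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      stop_invalid("malformed BED line %d in %s: '%s'", i, path, lines[i])
  }
  rtracklayer::import(path, format = "BED")
}

#' Read per-variant evidence from a local annotation track bundle
#'
#' Each boolean is set by point-in-interval overlap of the 1-based variant
#' position against the BED tracks (0-based half-open on disk; the import
#' layer converts). `binding_in_context` is protein binding co-located
#' with open chromatin or a histone mark at the variant;
#' `cancer_normal_differential` is true iff histone overlap status differs
#' between any cancer-tagged and any normal-tagged source;
#' `colorectal_evidence` is any assay overlap from a source tagged as a
#' colorectal cancer cell line or normal colon/rectal tissue;
#' `motif_altered` is true iff the absolute position-weight-matrix
#' log-odds change between alleles exceeds 5 (strict). Variants absent
#' from the PolyPhen table are `noncoding`.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `position`, or a
#'   `haplotype_panel`.
#' @param bundle an `annotation_bundle` or the path of a bundle directory.
#' @return named list of [evidence_record()]s, one per variant.
#' @export
evidence_from_tracks <- function(variants, bundle) {
  if (inherits(variants, "haplotype_panel"))
    variants <- data.frame(variant_id = variants$variant_ids,
                           chrom = variants$chrom,
                           position = variants$positions,
                           stringsAsFactors = FALSE)
  if (is.character(bundle)) {
    bundle <- list(
      dir = bundle,
      open_chromatin = file.path(bundle, "open_chromatin.bed"),
      histone_marks = file.path(bundle, "histone_marks.bed"),
      protein_binding = file.path(bundle, "protein_binding.bed"),
      conserved = file.path(bundle, "conserved.bed"),
      motif_lod = file.path(bundle, "motif_lod.tsv"),
      polyphen = file.path(bundle, "polyphen.tsv"))
  }
  beds <- lapply(bundle[c("open_chromatin", "histone_marks",
                          "protein_binding", "conserved")], read_bundle_bed)
  motif <- if (file.exists(bundle$motif_lod))
    read.delim(bundle$motif_lod, stringsAsFactors = FALSE)
  else {
    warning("missing motif table; motif_altered defaults to FALSE")
    data.frame(variant_id = character(0), ref_lod = numeric(0),
               alt_lod = numeric(0))
  }
  polyphen <- if (file.exists(bundle$polyphen))
    read.delim(bundle$polyphen, stringsAsFactors = FALSE)
  else {
    warning("missing PolyPhen table; coding_class defaults to noncoding")
    data.frame(variant_id = character(0), class = character(0))
  }

  query <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$position,
                              end = variants$position))
  hit_info <- function(gr) {
    ov <- GenomicRanges::findOverlaps(query, gr)
    qh <- S4Vectors::queryHits(ov)
    meta <- if (length(gr)) {
      parts <- strsplit(as.character(gr$name %||% rep("", length(gr))), "\\|")
      data.frame(class = vapply(parts, function(p) p[2] %||% NA_character_,
                                character(1)),
                 crc = vapply(parts, function(p) identical(p[3], "1"),
                              logical(1)))
    } else data.frame(class = character(0), crc = logical(0))
    list(hits = qh, class = meta$class[S4Vectors::subjectHits(ov)],
         crc = meta$crc[S4Vectors::subjectHits(ov)])
  }
  open_h <- hit_info(beds$open_chromatin)
  hist_h <- hit_info(beds$histone_marks)
  prot_h <- hit_info(beds$protein_binding)
  cons_h <- hit_info(beds$conserved)

  records <- lapply(seq_len(nrow(variants)), function(i) {
    open_i <- open_h$hits == i
    hist_i <- hist_h$hits == i
    prot_i <- prot_h$hits == i
    open <- any(open_i)
    histone <- any(hist_i)
    protein <- any(prot_i)
    cancer_hist <- any(hist_i & hist_h$class == "cancer")
    normal_hist <- any(hist_i & hist_h$class == "normal")
    crc_any <- any(open_i & open_h$crc) || any(hist_i & hist_h$crc) ||
      any(prot_i & prot_h$crc)
    vid <- variants$variant_id[i]
    m <- motif[motif$variant_id == vid, , drop = FALSE]
    motif_alt <- nrow(m) > 0 &&
      any(abs(m$alt_lod - m$ref_lod) > 5)
    pp <- polyphen$class[polyphen$variant_id == vid]
    evidence_record(
      variant_id = vid,
      histone_mark = histone,
      open_chromatin = open,
      protein_binding = protein,
      cancer_normal_differential = xor(cancer_hist, normal_hist),
      colorectal_evidence = crc_any,
      motif_altered = motif_alt,
      conserved = any(cons_h$hits == i),
      coding_class = if (length(pp)) pp[1] else "noncoding")
  })
  names(records) <- variants$variant_id
  records
}
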