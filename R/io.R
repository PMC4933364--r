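#' Write a study's genotypes as VCF with GT and DS fields
#'
#' One row per variant with hard genotype calls (`GT`, rounded dosage) and
#' the expected alternate-allele count (`DS`); the per-variant imputation
#' quality and source flag travel in the INFO column (`RSQ`, `SRC`).
#'
#' @param study a `study_dataset`.
#' @param path output `.vcf` path (uncompressed).
#' @return the path, invisibly.
#' @export
write_study_vcf <- function(study, path) {
  stopifnot(inherits(study, "study_dataset"))
  vm <- study$variant_meta
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=finemapcrc_%s", study$study_id),
    "##INFO=<ID=RSQ,Number=1,Type=Float,Description=\"Imputation quality (squared dosage/genotype correlation)\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"genotyped or imputed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", study$subject_ids), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(vm)), function(j) {
    ds <- study$dosages[, j]
    gt <- gt_codes[pmin(pmax(round(ds), 0), 2) + 1L]
    info <- sprintf("RSQ=%.4f;SRC=%s",
                    if (is.na(vm$rsq[j])) 0 else vm$rsq[j], vm$source[j])
    paste(c(vm$chrom[j], vm$position[j], vm$variant_id[j], "A", "G", ".",
            "PASS", info, "GT:DS", sprintf("%s:%.3f", gt, ds)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an allele-dosage matrix back from a VCF
#'
#' Parses with `vcfR` and extracts the `DS` FORMAT field (subjects x
#' variants) along with the `RSQ`/`SRC` INFO keys.
#'
#' @param path a VCF path.
#' @param rsq_key INFO key holding the imputation quality (default
#'   `"RSQ"`).
#' @return list with `dosages` (subjects x variants matrix) and
#'   `variant_meta` (`variant_id`, `chrom`, `position`, `rsq`, `source`).
#' @export
read_dosage_vcf <- function(path, rsq_key = "RSQ") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  info_field <- function(key) {
    m <- regmatches(fix[, "INFO"] %||% character(0),
                    regexpr(paste0(key, "=[^;]+"), fix[, "INFO"]))
    sub(paste0(key, "="), "", m)
  }
  rsq <- suppressWarnings(as.numeric(vcfR::extract.info(v, rsq_key)))
  src <- vcfR::extract.info(v, "SRC")
  list(dosages = t(ds),
       variant_meta = data.frame(
         variant_id = unname(fix[, "ID"]),
         chrom = unname(fix[, "CHROM"]),
         position = as.integer(fix[, "POS"]),
         rsq = rsq,
         source = if (is.null(src)) NA_character_ else unname(src),
         stringsAsFactors = FALSE))
}

#' Write phenotype/covariate tables for a list of studies
#'
#' @param studies list of `study_dataset`s.
#' @param path output TSV path (columns `study_id`, `subject_id`,
#'   `status`, `age`, `sex`, `pc1`..`pc3`).
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(studies, path) {
  rows <- lapply(studies, function(s) {
    data.frame(study_id = s$study_id, subject_id = s$subject_ids,
               status = s$phenotype, s$covariates,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' @param path TSV written by [write_phenotypes()].
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
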