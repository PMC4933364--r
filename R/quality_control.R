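#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the
#' probability of each possible heterozygote count is computed from the
#' conditional (hypergeometric-type) distribution under HWE, and the
#' two-sided P-value is the summed probability of all configurations no
#' more probable than the observed one. Monomorphic input returns 1.
#' A chi-square flavour (1 df, no continuity correction) is provided for
#' speed on large tables.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return two-sided P-value in `(0, 1]`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop_invalid("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop_invalid("genotype counts must be integers")
  n <- sum(counts)
  if (n == 0) stop_invalid("total genotype count must be > 0")
  n_a <- 2 * n_aa + n_Aa   # minor-ish allele count (label-free below)
  n_A <- 2 * n_AA + n_Aa
  if (n_A == 0 || n_a == 0) return(1)

  if (method == "chisq") {
    p <- n_A / (2 * n)
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - expected)^2 / expected)
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  }

  n_minor <- min(n_A, n_a)
  ## possible heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  log_prob <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    ## P(h | n, n_minor) = n! / (hom_major! h! hom_minor!) * 2^h *
    ##                     n_minor! n_major! / (2n)!
    lgamma(n + 1) - lgamma(hom_major + 1) - lgamma(h + 1) -
      lgamma(hom_minor + 1) + h * log(2) +
      lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  obs <- n_Aa
  p_obs <- prob[match(obs, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

qc_decision <- function(reasons) {
  structure(list(keep = length(reasons) == 0L, reasons = reasons),
            class = "qc_decision")
}

#' @exportS3Method base::print
print.qc_decision <- function(x, ...) {
  cat(if (x$keep) "<qc_decision> keep\n"
      else sprintf("<qc_decision> drop (%s)\n", paste(x$reasons, collapse = ", ")))
  invisible(x)
}

#' QC filter for directly genotyped SNPs
#'
#' Drops a genotyped SNP iff its call rate is below `call_rate_min`
#' (default 98%), its Hardy-Weinberg P-value in controls is below
#' `hwe_alpha` (default 1e-4), or its MAF is below `maf_min`. The MAF
#' cutoff for genotyped SNPs is a required, surfaced parameter (default
#' 0.005, mirroring the lowest imputation-quality stratum) because no
#' single community convention exists.
#'
#' @param call_rate fraction of non-missing genotypes, in `[0, 1]`.
#' @param hwe_p_controls HWE P-value computed in controls.
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @param call_rate_min,hwe_alpha,maf_min thresholds.
#' @return a `qc_decision` with `keep` and the violated-rule `reasons`
#'   (`keep` is `TRUE` iff `reasons` is empty).
#' @export
filter_genotyped <- function(call_rate, hwe_p_controls, maf,
                             call_rate_min = 0.98, hwe_alpha = 1e-4,
                             maf_min = 0.005) {
  if (call_rate < 0 || call_rate > 1) stop_invalid("call_rate must be in [0, 1]")
  if (hwe_p_controls < 0 || hwe_p_controls > 1)
    stop_invalid("hwe_p_controls must be in [0, 1]")
  if (maf < 0 || maf > 0.5) stop_invalid("maf must be in [0, 0.5]")
  reasons <- character()
  if (call_rate < call_rate_min) reasons <- c(reasons, "call_rate")
  if (hwe_p_controls < hwe_alpha) reasons <- c(reasons, "hwe")
  if (maf < maf_min) reasons <- c(reasons, "maf")
  qc_decision(reasons)
}

#' MAF-stratified imputation-quality filter
#'
#' Implements the published Rsq exclusions with the comparator directions
#' exactly as printed: for MAF > 0.01 drop iff Rsq <= 0.3 (non-strict); for
#' MAF in \[0.005, 0.01\] drop iff Rsq < 0.5; for MAF < 0.005 drop iff
#' Rsq < 0.99. The printed strata leave the endpoint MAF = 0.01 in the
#' middle stratum, which is how the boundaries are resolved here
#' (no gaps, no overlaps).
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @param rsq imputation quality in `[0, 1]`.
#' @return a `qc_decision`.
#' @export
filter_imputed <- function(maf, rsq) {
  if (maf < 0 || maf > 0.5) stop_invalid("maf must be in [0, 0.5]")
  if (rsq < 0 || rsq > 1) stop_invalid("rsq must be in [0, 1]")
  reasons <- character()
  if (maf > 0.01) {
    if (rsq <= 0.3) reasons <- "rsq_common"
  } else if (maf >= 0.005) {
    if (rsq < 0.5) reasons <- "rsq_lowfreq"
  } else {
    if (rsq < 0.99) reasons <- "rsq_rare"
  }
  qc_decision(reasons)
}

#' Run variant QC over a study and emit a report table
#'
#' Applies [filter_genotyped()] or [filter_imputed()] per variant according
#' to its source flag. HWE is computed in controls from (rounded) dosages
#' for genotyped variants. Call rate for simulated data is 1 unless a
#' missingness matrix is supplied upstream.
#'
#' @param study a `study_dataset`.
#' @param maf_min MAF cutoff for genotyped SNPs.
#' @param hwe_method passed to [hwe_test()]; the chi-square flavour is the
#'   default here for speed on thousands of variants.
#' @return data.frame: `variant_id`, `maf`, `rsq`, `call_rate`, `hwe_p`,
#'   `keep`, `reasons` (comma-separated rule ids, empty when kept).
#' @export
qc_study <- function(study, maf_min = 0.005,
                     hwe_method = c("chisq", "exact")) {
  stopifnot(inherits(study, "study_dataset"))
  hwe_method <- match.arg(hwe_method)
  vm <- study$variant_meta
  ctrl <- study$phenotype == 0
  out <- vm[, c("variant_id", "maf", "rsq")]
  out$call_rate <- 1
  out$hwe_p <- NA_real_
  out$keep <- NA
  out$reasons <- ""
  for (j in seq_len(nrow(vm))) {
    if (vm$source[j] == "genotyped") {
      g <- round(study$dosages[ctrl, j])
      hwe_p <- hwe_test(sum(g == 0), sum(g == 1), sum(g == 2),
                        method = hwe_method)
      dec <- filter_genotyped(call_rate = 1, hwe_p_controls = hwe_p,
                              maf = vm$maf[j], maf_min = maf_min)
      out$hwe_p[j] <- hwe_p
    } else {
      dec <- filter_imputed(vm$maf[j], vm$rsq[j])
    }
    out$keep[j] <- dec$keep
    out$reasons[j] <- paste(dec$reasons, collapse = ",")
  }
  out
}
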