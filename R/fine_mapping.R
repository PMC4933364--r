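#' Build a 500-kb fine-mapping region around an index SNP
#'
#' The region spans 250 kb upstream and downstream of the index position
#' (1-based inclusive coordinates) and carries every QC-passing variant of
#' the supplied table falling in that window on the index chromosome.
#' Regions running off the chromosome start are clipped at 1 and flagged
#' `truncated` rather than erroring.
#'
#' @param index_id id of the index SNP; must be present in `variants`.
#' @param variants data.frame with `variant_id`, `chrom`, `position`
#'   (genome-ordered or not; the region keeps position order).
#' @param flank flank size in bp (default 250,000 on each side).
#' @param chrom_length optional chromosome length for right-end clipping.
#' @return a `region` object: `index_snp`, `chrom`, `start`, `end`,
#'   `variants` (ordered ids), `n_snps`, `truncated`.
#' @export
build_region <- function(index_id, variants, flank = 250000L,
                         chrom_length = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "chrom", "position") %in% names(variants)))
  i <- match(index_id, variants$variant_id)
  if (is.na(i)) stop_invalid("index SNP '%s' not found in variant list", index_id)
  pos <- variants$position[i]
  chrom <- variants$chrom[i]
  start <- pos - flank
  end <- pos + flank
  truncated <- FALSE
  if (start < 1) { start <- 1L; truncated <- TRUE }
  if (!is.null(chrom_length) && end > chrom_length) {
    end <- chrom_length; truncated <- TRUE
  }
  in_window <- variants$chrom == chrom &
    variants$position >= start & variants$position <= end
  ids <- variants$variant_id[in_window][order(variants$position[in_window])]
  structure(
    list(index_snp = index_id, chrom = chrom,
         start = as.integer(start), end = as.integer(end),
         variants = ids, n_snps = length(ids), truncated = truncated),
    class = "region")
}

#' @exportS3Method base::print
print.region <- function(x, ...) {
  cat(sprintf("<region> index %s, chr%s:%d-%d (%s), %d SNPs\n",
              x$index_snp, x$chrom, x$start, x$end,
              if (x$truncated) "truncated" else "full 500-kb", x$n_snps))
  invisible(x)
}

#' Identify the top SNP (smallest meta-analysis P) of a region
#'
#' Only converged results are ranked. Ties on P are broken
#' deterministically: larger `|beta_meta|` first, then smaller position.
#'
#' @param meta_results a [meta_scan()] table restricted to the region.
#' @return the winning `variant_id`.
#' @export
find_top_snp <- function(meta_results) {
  d <- meta_results[meta_results$converged & is.finite(meta_results$p_meta), ]
  if (nrow(d) == 0L) stop_invalid("no converged results to rank")
  ord <- order(d$p_meta, -abs(d$beta_meta), d$position)
  d$variant_id[ord[1]]
}

#' Collapse overlapping regions that share a top SNP
#'
#' Regions around index SNPs of the same locus often overlap; when two
#' regions elect the same top SNP they describe one signal. Returns the
#' unique top SNPs with all their index SNPs attached.
#'
#' @param region_tops data.frame with columns `index_snp`, `top_snp` and
#'   optionally `locus`.
#' @return data.frame with one row per unique top SNP: `top_snp`,
#'   `n_regions`, `index_snps` (comma-joined), and `locus` when supplied.
#' @export
unify_top_snps <- function(region_tops) {
  stopifnot(is.data.frame(region_tops),
            all(c("index_snp", "top_snp") %in% names(region_tops)))
  groups <- split(region_tops, region_tops$top_snp)
  out <- lapply(groups, function(d) {
    row <- data.frame(top_snp = d$top_snp[1],
                      n_regions = nrow(d),
                      index_snps = paste(unique(d$index_snp), collapse = ","),
                      stringsAsFactors = FALSE)
    if ("locus" %in% names(d))
      row$locus <- paste(unique(d$locus), collapse = ",")
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$top_snp, region_tops$top_snp)), , drop = FALSE]
}

#' Conditional independence scan of a region
#'
#' Re-tests every non-top variant with the top SNP's dosage added as a
#' covariate (two variants per model), per study, then combines studies by
#' fixed-effects meta-analysis. The per-region significance threshold is
#' the Bonferroni level `alpha / n_snps` of that region. Variants collinear
#' with the top SNP in every study are flagged `non_estimable`, never
#' silently dropped.
#'
#' @param studies list of `study_dataset` objects.
#' @param region a [build_region()] region (needs >= 2 variants).
#' @param top_id the top SNP to condition on.
#' @param alpha family-wise level before Bonferroni division (default
#'   0.05).
#' @param covariates_fn optional function(study) returning the covariate
#'   matrix; defaults to the stored study covariates.
#' @return data.frame: `variant_id`, `beta_cond`, `se_cond`, `p_cond`,
#'   `k`, `alpha_region`, `significant`, `non_estimable`, `position`.
#' @export
conditional_scan <- function(studies, region, top_id, alpha = 0.05,
                             covariates_fn = NULL) {
  stopifnot(inherits(region, "region"))
  if (!top_id %in% region$variants)
    stop_invalid("top SNP '%s' is not in the region", top_id)
  if (region$n_snps < 2)
    stop_invalid("conditional scan needs a region with >= 2 variants")
  others <- setdiff(region$variants, top_id)
  alpha_region <- alpha / region$n_snps

  per_study <- lapply(studies, function(study) {
    vm <- study$variant_meta
    jt <- match(top_id, vm$variant_id)
    base_cov <- if (is.null(covariates_fn)) study$covariates
                else covariates_fn(study)
    top_dos <- study$dosages[, jt]
    lapply(setNames(others, others), function(v) {
      jv <- match(v, vm$variant_id)
      dv <- study$dosages[, jv]
      if (sd(dv) == 0 || sd(top_dos) == 0 ||
          abs(cor(dv, top_dos)) > 1 - 1e-10) {
        return(data.frame(beta = NA_real_, se = NA_real_,
                          converged = FALSE, collinear = TRUE))
      }
      fit <- fit_logistic_dosage(study$phenotype, dv,
                                 covariates = cbind(base_cov, top = top_dos),
                                 variant_id = v, study_id = study$study_id)
      data.frame(beta = fit$beta, se = fit$se,
                 converged = fit$converged, collinear = FALSE)
    })
  })

  rows <- lapply(others, function(v) {
    units <- do.call(rbind, lapply(per_study, `[[`, v))
    usable <- units$converged
    pos <- studies[[1]]$variant_meta$position[
      match(v, studies[[1]]$variant_meta$variant_id)]
    if (!any(usable)) {
      return(data.frame(variant_id = v, beta_cond = NA_real_,
                        se_cond = NA_real_, p_cond = NA_real_, k = 0L,
                        alpha_region = alpha_region, significant = FALSE,
                        non_estimable = TRUE, position = pos,
                        stringsAsFactors = FALSE))
    }
    m <- ivw_fixed(units$beta, units$se, converged = usable, variant_id = v)
    data.frame(variant_id = v, beta_cond = m$beta_meta,
               se_cond = m$se_meta, p_cond = m$p_meta, k = m$k,
               alpha_region = alpha_region,
               significant = m$p_meta <= alpha_region,
               non_estimable = FALSE, position = pos,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the annotation candidate set of a region
#'
#' Implements the four a-priori selection rules plus the conditional rule:
#' (1) the top SNP (smallest meta P in the region); (2) the index SNP —
#' always annotated, flagged when absent from the scan (e.g. removed by
#' QC); (3) among the 10 variants with the smallest P-values, those with
#' reference-panel r-squared > `r2_threshold` with the index SNP; (4) any
#' variant completely correlated (r-squared = 1) with a member of rules
#' 1-3; plus any variant with conditional `P <= conditional_p` and its
#' perfect proxies. The r-squared = 1 relation is an equivalence on a
#' fixed panel, so a single proxy-closure pass is complete.
#'
#' @param region a `region`.
#' @param meta_results [meta_scan()] rows for the region.
#' @param panel reference `haplotype_panel` for LD.
#' @param conditional_results optional [conditional_scan()] table.
#' @param top_k rule-3 pool size (default 10).
#' @param r2_threshold rule-3 LD threshold (default 0.5).
#' @param conditional_p conditional-annotation threshold (default 5e-5).
#' @return a `candidate_set`: `region_id`, `top_snp`, `index_snp`,
#'   `index_in_scan`, per-rule member vectors, `members` (data.frame of
#'   variant/rule pairs) and the union `all`.
#' @export
select_annotation_set <- function(region, meta_results, panel,
                                  conditional_results = NULL,
                                  top_k = 10L, r2_threshold = 0.5,
                                  conditional_p = 5e-5) {
  stopifnot(inherits(region, "region"), nrow(meta_results) > 0)
  conv <- meta_results[meta_results$converged &
                         meta_results$variant_id %in% region$variants, ]
  top <- find_top_snp(conv)
  index <- region$index_snp
  index_in_scan <- index %in% conv$variant_id

  ord <- order(conv$p_meta, -abs(conv$beta_meta), conv$position)
  top10 <- conv$variant_id[ord][seq_len(min(top_k, nrow(conv)))]

  rule3 <- character()
  index_polymorphic <- index %in% panel$variant_ids &&
    length(unique(panel$haplotypes[, index])) > 1
  if (index_polymorphic) {
    r2 <- panel_r2(panel, index,
                   candidates = setdiff(intersect(top10, panel$variant_ids),
                                        index))
    rule3 <- names(r2)[!is.na(r2) & r2 > r2_threshold]
  }

  seed_set <- unique(c(top, index, rule3))
  proxy_candidates <- intersect(region$variants, panel$variant_ids)
  rule4 <- unique(unlist(lapply(
    intersect(seed_set, panel$variant_ids), function(v) {
      if (length(unique(panel$haplotypes[, v])) < 2) return(character())
      perfect_proxies(v, panel, candidates = proxy_candidates)
    })))
  rule4 <- setdiff(rule4, seed_set)

  cond_members <- character()
  if (!is.null(conditional_results) && nrow(conditional_results)) {
    hits <- conditional_results$variant_id[
      !conditional_results$non_estimable &
        is.finite(conditional_results$p_cond) &
        conditional_results$p_cond <= conditional_p]
    cond_proxies <- unique(unlist(lapply(
      intersect(hits, panel$variant_ids), function(v) {
        if (length(unique(panel$haplotypes[, v])) < 2) return(character())
        perfect_proxies(v, panel, candidates = proxy_candidates)
      })))
    cond_members <- unique(c(hits, cond_proxies))
  }

  members <- rbind(
    data.frame(variant_id = top, rule = "top_snp"),
    data.frame(variant_id = index, rule = "index_snp"),
    if (length(rule3)) data.frame(variant_id = rule3, rule = "top10_r2"),
    if (length(rule4)) data.frame(variant_id = rule4, rule = "perfect_proxy"),
    if (length(cond_members))
      data.frame(variant_id = cond_members, rule = "conditional"))
  structure(
    list(region_id = region$index_snp, top_snp = top, index_snp = index,
         index_in_scan = index_in_scan,
         rule3_members = rule3, rule4_members = rule4,
         conditional_members = cond_members,
         members = members,
         all = unique(members$variant_id)),
    class = "candidate_set")
}

#' @exportS3Method base::print
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> region %s: top %s, index %s%s, %d candidates\n",
              x$region_id, x$top_snp, x$index_snp,
              if (x$index_in_scan) "" else " (absent from scan)",
              length(x$all)))
  invisible(x)
}
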