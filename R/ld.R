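#' Haplotype-based linkage-disequilibrium r-squared
#'
#' Computes r-squared between two loci from phased binary haplotype vectors
#' by direct haplotype-frequency counting:
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#' No EM step is needed because the panel is phased by construction.
#'
#' @param h_a,h_b 0/1 vectors of equal length (>= 4), one entry per
#'   haplotype.
#' @return r-squared in `[0, 1]`.
#' @export
r2_haplotypes <- function(h_a, h_b) {
  if (length(h_a) != length(h_b))
    stop_invalid("haplotype vectors differ in length (%d vs %d)",
                 length(h_a), length(h_b))
  if (length(h_a) < 4)
    stop_invalid("need at least 4 haplotypes, got %d", length(h_a))
  if (!all(h_a %in% c(0, 1)) || !all(h_b %in% c(0, 1)))
    stop_invalid("haplotype vectors must be 0/1")
  p_a <- mean(h_a)
  p_b <- mean(h_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1))
    stop_invalid("LD is undefined for a monomorphic locus")
  p_ab <- mean(h_a == 1 & h_b == 1)
  d <- p_ab - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

#' Pairwise r-squared against one panel variant
#'
#' @param panel a [simulate_haplotype_panel()] panel.
#' @param v variant id in the panel (must be polymorphic).
#' @param candidates variant ids to compare against; defaults to all other
#'   polymorphic variants.
#' @return named numeric vector of r-squared values.
#' @export
panel_r2 <- function(panel, v, candidates = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!v %in% panel$variant_ids) stop_invalid("unknown variant id '%s'", v)
  hv <- panel$haplotypes[, v]
  if (length(unique(hv)) < 2)
    stop_invalid("LD is undefined: '%s' is monomorphic in the panel", v)
  if (is.null(candidates)) candidates <- setdiff(panel$variant_ids, v)
  missing <- setdiff(candidates, panel$variant_ids)
  if (length(missing))
    stop_invalid("unknown candidate variant id(s): %s",
                 paste(missing, collapse = ", "))
  vapply(candidates, function(w) {
    hw <- panel$haplotypes[, w]
    if (length(unique(hw)) < 2) return(NA_real_)
    r2_haplotypes(hv, hw)
  }, numeric(1))
}

#' Perfect proxies (r-squared exactly 1) of a variant in a reference panel
#'
#' A candidate is a perfect proxy iff its haplotype column equals the query
#' column or its bitwise complement (allele relabelling leaves r-squared
#' unchanged). The query variant itself is never returned.
#'
#' @inheritParams panel_r2
#' @return character vector of proxy variant ids (possibly empty).
#' @export
perfect_proxies <- function(v, panel, candidates = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!v %in% panel$variant_ids) stop_invalid("unknown variant id '%s'", v)
  hv <- panel$haplotypes[, v]
  if (length(unique(hv)) < 2)
    stop_invalid("LD is undefined: '%s' is monomorphic in the panel", v)
  if (is.null(candidates)) candidates <- panel$variant_ids
  candidates <- setdiff(candidates, v)
  hits <- vapply(candidates, function(w) {
    hw <- panel$haplotypes[, w]
    all(hw == hv) || all(hw == 1L - hv)
  }, logical(1))
  candidates[hits]
}

#' Bucket r-squared values into the conventional reporting bins
#'
#' Bins are left-closed, right-open except the top bin which is `[0.8, 1]`:
#' `<0.2`, `[0.2, 0.4)`, `[0.4, 0.6)`, `[0.6, 0.8)`, `>=0.8`.
#'
#' @param values numeric r-squared values in `[0, 1]`.
#' @param edges internal bin edges (ascending).
#' @return named integer vector of counts, summing to `length(values)`.
#' @export
bucket_r2 <- function(values, edges = c(0.2, 0.4, 0.6, 0.8)) {
  if (length(values) && (any(values < 0) || any(values > 1)))
    stop_invalid("r-squared values must lie in [0, 1]")
  n_bin <- length(edges) + 1L
  counts <- tabulate(findInterval(values, edges) + 1L, nbins = n_bin)
  names(counts) <- c(sprintf("<%.1f", edges[1]),
                     sprintf("%.1f-%.1f", edges[-length(edges)], edges[-1]),
                     sprintf(">=%.1f", edges[length(edges)]))
  counts
}
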