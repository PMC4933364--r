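#' Simulate a phased reference haplotype panel with block-like LD
#'
#' Generates a panel of phased binary haplotypes by a founder-mosaic model:
#' each haplotype copies from a small pool of founder haplotypes, switching
#' founders between adjacent variants with a per-bp crossover probability.
#' This produces the block-like decay of pairwise r-squared with physical
#' distance that fine-mapping candidate-selection rules rely on, while
#' remaining cheap and exactly reproducible under a seed. It stands in for a
#' phased reference panel such as 1000 Genomes European haplotypes.
#'
#' @param n_hap number of haplotypes (rows), at least 4.
#' @param n_variants number of variants (columns), at least 2.
#' @param region_length length of the simulated region in bp; variant
#'   positions are drawn uniformly (without replacement) in
#'   `[1, region_length]`.
#' @param recombination_rate per-bp probability that a haplotype switches to
#'   a random founder between adjacent base pairs. The default `1e-5` gives
#'   a handful of crossover events across a 500-kb region per haplotype,
#'   i.e. a few LD blocks.
#' @param maf_floor minimum minor allele frequency enforced per variant
#'   (realised in the panel, not just in the founder pool). Columns that
#'   cannot reach the floor after repeated redraws are flagged monomorphic
#'   when `allow_monomorphic = TRUE`, otherwise an error is raised.
#' @param n_founders size of the founder pool. With `n_founders = 2` and
#'   `recombination_rate = 0` every polymorphic variant pair is in complete
#'   LD (r-squared 1), a useful degenerate check.
#' @param allow_monomorphic keep (and flag) monomorphic variants instead of
#'   erroring.
#' @param chrom chromosome label used when the panel is written to VCF/BED.
#' @param seed integer seed; identical seeds give bit-identical panels.
#'
#' @return An object of class `haplotype_panel`: a list with `haplotypes`
#'   (0/1 integer matrix, `n_hap` x `n_variants`), `positions` (strictly
#'   increasing 1-based bp), `variant_ids`, `alleles` (data.frame with
#'   `ref`, `alt`), `chrom`, and logical `monomorphic`.
#' @export
simulate_haplotype_panel <- function(n_hap, n_variants,
                                     region_length = 5e5,
                                     recombination_rate = 1e-5,
                                     maf_floor = 0.01,
                                     n_founders = 20,
                                     allow_monomorphic = FALSE,
                                     chrom = "1",
                                     seed = 1L) {
  if (n_hap < 4 || n_variants < 2)
    stop_invalid("n_hap must be >= 4 and n_variants >= 2 (got %s, %s)",
                 n_hap, n_variants)
  if (region_length < n_variants)
    stop_invalid("region_length (%s) must be >= n_variants (%s)",
                 region_length, n_variants)
  if (recombination_rate < 0 || recombination_rate > 1)
    stop_invalid("recombination_rate must be in [0, 1]")
  if (n_founders < 2) stop_invalid("n_founders must be >= 2")

  set.seed(seed)
  positions <- sort(sample.int(region_length, n_variants))

  ## mosaic paths: founder index copied by each haplotype at each variant
  path <- matrix(0L, n_hap, n_variants)
  path[, 1] <- sample.int(n_founders, n_hap, replace = TRUE)
  if (n_variants > 1) {
    gaps <- diff(positions)
    p_switch <- 1 - (1 - recombination_rate)^gaps
    for (j in 2:n_variants) {
      switch_now <- runif(n_hap) < p_switch[j - 1]
      path[, j] <- ifelse(switch_now,
                          sample.int(n_founders, n_hap, replace = TRUE),
                          path[, j - 1])
    }
  }

  ## founder alleles per variant, redrawn until the realised MAF clears the
  ## floor (paths stay fixed, so LD structure is untouched)
  haplotypes <- matrix(0L, n_hap, n_variants)
  monomorphic <- logical(n_variants)
  for (j in seq_len(n_variants)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      p <- runif(1, min = max(maf_floor, 0.05), max = 0.5)
      founder_alleles <- rbinom(n_founders, 1L, p)
      col <- founder_alleles[path[, j]]
      f <- mean(col)
      maf <- min(f, 1 - f)
      if (maf >= maf_floor) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      if (!allow_monomorphic)
        stop_invalid("variant %d could not reach maf_floor %.3g", j, maf_floor)
      monomorphic[j] <- TRUE
      col <- rep(0L, n_hap)
    }
    haplotypes[, j] <- col
  }

  variant_ids <- sprintf("var%04d", seq_len(n_variants))
  colnames(haplotypes) <- variant_ids
  structure(
    list(haplotypes = haplotypes,
         positions = positions,
         variant_ids = variant_ids,
         alleles = data.frame(ref = rep("A", n_variants),
                              alt = rep("G", n_variants)),
         chrom = chrom,
         monomorphic = monomorphic),
    class = "haplotype_panel")
}

#' Alternate-allele frequency of each panel variant
#'
#' @param panel a `haplotype_panel`.
#' @return named numeric vector of alternate-allele frequencies.
#' @export
panel_freq <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  colMeans(panel$haplotypes)
}

#' Minor allele frequency of each panel variant
#'
#' @param panel a `haplotype_panel`.
#' @return named numeric vector of MAFs (in `[0, 0.5]`).
#' @export
panel_maf <- function(panel) {
  f <- panel_freq(panel)
  pmin(f, 1 - f)
}

#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d variants on chr%s, span %d-%d bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$chrom,
              min(x$positions), max(x$positions)))
  cat(sprintf("  MAF range %.3f-%.3f; %d monomorphic\n",
              min(panel_maf(x)), max(panel_maf(x)), sum(x$monomorphic)))
  invisible(x)
}
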