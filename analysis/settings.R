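# Shared settings for the numbered analysis drivers.
#
# One synthetic consortium: 3 case-control studies over a 600-kb synthetic
# chromosome segment with a planted causal variant (per-allele OR 1.5)
# that also carries a full strong-evidence annotation profile. Scales are
# desk-sized so the whole chain re-runs in about a minute.

library(finemapcrc)

settings <- list(
  seed          = 4242L,
  results_dir   = "results",
  n_hap         = 200L,
  n_variants    = 100L,
  region_length = 600000L,
  recomb_rate   = 1e-5,
  maf_floor     = 0.05,
  n_founders    = 12L,
  n_studies     = 3L,
  cases         = 300L,
  controls      = 300L,
  causal_or     = 1.5,
  prevalence    = 0.1,
  target_rsq    = 0.95,
  flank         = 250000L,
  background    = 0.02
)

build_panel <- function(s = settings) {
  simulate_haplotype_panel(s$n_hap, s$n_variants,
                           region_length = s$region_length,
                           recombination_rate = s$recomb_rate,
                           maf_floor = s$maf_floor,
                           n_founders = s$n_founders, seed = s$seed)
}

causal_variant <- function(panel, s = settings) {
  panel$variant_ids[which.min(abs(panel$positions - s$region_length / 2))]
}

# Rebuild study_dataset objects from the stage files written by
# 01_simulate_cohort.R, so later drivers consume the on-disk interface.
load_studies_from_files <- function(sim_dir) {
  pheno <- read_phenotypes(file.path(sim_dir, "phenotypes.tsv"))
  lapply(split(pheno, pheno$study_id), function(ph) {
    vcf <- read_dosage_vcf(file.path(sim_dir, paste0(ph$study_id[1], ".vcf")))
    stopifnot(identical(rownames(vcf$dosages), ph$subject_id))
    vm <- vcf$variant_meta
    freq <- colMeans(vcf$dosages) / 2
    vm$maf <- pmin(freq, 1 - freq)
    structure(
      list(study_id = ph$study_id[1], stratum = "crc",
           phenotype = ph$status,
           dosages = vcf$dosages,
           covariates = as.matrix(ph[, c("age", "sex", "pc1", "pc2", "pc3")]),
           subject_ids = ph$subject_id,
           variant_meta = vm[, c("variant_id", "chrom", "position", "maf",
                                 "rsq", "source")]),
      class = "study_dataset")
  })
}
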