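#!/usr/bin/env Rscript
# Variant quality control: the genotyped-SNP exclusions (call rate, HWE in
# controls, MAF) and the MAF-stratified imputation Rsq filter, applied per
# study to the simulated VCFs. Writes results/qc_report.tsv and the list
# of variants kept in every study.

source("analysis/settings.R")
sim_dir <- file.path(settings$results_dir, "sim")
studies <- load_studies_from_files(sim_dir)

reports <- lapply(studies, function(s) {
  r <- qc_study(s)
  r$study_id <- s$study_id
  r
})
qc_all <- do.call(rbind, reports)
rownames(qc_all) <- NULL
write.table(qc_all, file.path(settings$results_dir, "qc_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

kept <- Reduce(intersect, lapply(reports, function(r) r$variant_id[r$keep]))
writeLines(kept, file.path(settings$results_dir, "variants_kept.txt"))

dropped <- qc_all[!qc_all$keep, ]
cat(sprintf("QC: %d variants in, %d kept in all %d studies\n",
            length(unique(qc_all$variant_id)), length(kept), length(studies)))
if (nrow(dropped)) {
  cat("exclusion reasons:\n")
  print(table(dropped$reasons))
} else cat("no exclusions at this simulated imputation quality\n")
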