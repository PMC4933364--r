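#!/usr/bin/env Rscript
# Fine-mapping of the single synthetic region: build the 500-kb window
# around the index SNP (the planted causal variant), identify the top SNP,
# run the conditional independence scan at the per-region Bonferroni
# threshold, and assemble the annotation candidate set by the a-priori
# selection rules. Writes results/regions.tsv, results/conditional.tsv and
# results/candidates.tsv.

source("analysis/settings.R")
sim_dir <- file.path(settings$results_dir, "sim")
studies <- load_studies_from_files(sim_dir)
kept <- readLines(file.path(settings$results_dir, "variants_kept.txt"))
meta_tsv <- read.delim(file.path(settings$results_dir, "meta.tsv"))
meta <- data.frame(variant_id = meta_tsv$SNP, chrom = as.character(meta_tsv$CHR),
                   position = meta_tsv$POS, beta_meta = meta_tsv$BETA,
                   se_meta = meta_tsv$SE, p_meta = meta_tsv$P,
                   k = meta_tsv$K, converged = meta_tsv$K > 0)

panel <- build_panel()
index <- causal_variant(panel)

variants_tbl <- studies[[1]]$variant_meta[
  studies[[1]]$variant_meta$variant_id %in% kept, ]
region <- build_region(index, variants_tbl, flank = settings$flank)
print(region)

meta_region <- meta[meta$variant_id %in% region$variants, ]
top <- find_top_snp(meta_region)
cat(sprintf("top SNP: %s; index SNP: %s; r2(top, index) = %.3f\n", top, index,
            if (top == index) 1 else panel_r2(panel, index, top)))

cond <- conditional_scan(studies, region, top)
write.table(cond, file.path(settings$results_dir, "conditional.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("conditional scan: %d variants at alpha = 0.05/%d = %.2e; %d significant\n",
            nrow(cond), region$n_snps, unique(cond$alpha_region),
            sum(cond$significant, na.rm = TRUE)))

cand <- select_annotation_set(region, meta_region, panel,
                              conditional_results = cond)
write.table(cand$members, file.path(settings$results_dir, "candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(index_snp = region$index_snp, chrom = region$chrom,
                       start = region$start, end = region$end,
                       n_snps = region$n_snps, truncated = region$truncated,
                       top_snp = top),
            file.path(settings$results_dir, "regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("candidate set: %s\n", paste(cand$all, collapse = ", ")))
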