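#' Configuration for the end-to-end fine-mapping pipeline
#'
#' Collects every knob of the chain simulate -> qc -> associate -> meta ->
#' fine-map -> annotate -> score -> power, with defaults sized for a
#' desk-scale demonstration (3 studies, one 500-kb region, a planted
#' causal variant carrying a full strong-evidence profile). All
#' thresholds surface here rather than being hard-coded in stages.
#'
#' @param out_dir output directory for stage files and the manifest.
#' @param seed master seed; every stage derives from it.
#' @param n_studies,cases_per_study,controls_per_study study design.
#' @param causal_or,baseline_prevalence,target_rsq disease model and
#'   imputation accuracy.
#' @param n_hap,n_variants,region_length,recombination_rate,maf_floor,n_founders
#'   reference-panel parameters.
#' @param flank region flank in bp.
#' @param maf_min genotyped-SNP MAF cutoff.
#' @param top_k,r2_threshold,conditional_p candidate-selection rules.
#' @param background_rate sparse background annotation rate.
#' @param power_mafs,power_ors power-curve grid.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("finemap_run_"),
                            seed = 1L,
                            n_studies = 3L,
                            cases_per_study = 400L,
                            controls_per_study = 400L,
                            causal_or = 1.5,
                            baseline_prevalence = 0.1,
                            target_rsq = 0.95,
                            n_hap = 200L,
                            n_variants = 120L,
                            region_length = 600000L,
                            recombination_rate = 1e-5,
                            maf_floor = 0.05,
                            n_founders = 12L,
                            flank = 250000L,
                            maf_min = 0.005,
                            top_k = 10L,
                            r2_threshold = 0.5,
                            conditional_p = 5e-5,
                            background_rate = 0.02,
                            power_mafs = c(0.01, 0.05, 0.2),
                            power_ors = c(1.1, 1.2, 1.3, 1.5)) {
  cfg <- as.list(environment())
  stopifnot(cfg$flank > 0, cfg$top_k >= 1,
            cfg$r2_threshold >= 0, cfg$r2_threshold <= 1,
            cfg$conditional_p > 0, cfg$conditional_p < 1,
            cfg$background_rate >= 0, cfg$background_rate <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their [pipeline_config()] defaults;
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] n_in=%d n_out=%d", stage, n_in, n_out))
}

#' Run the full fine-mapping pipeline on synthetic data
#'
#' Executes the stage chain in order, writing each stage's output files
#' under `config$out_dir` and returning a manifest of per-stage variant
#' counts, output paths and md5 checksums. The run is fully deterministic
#' under a fixed config and seed (re-running yields byte-identical stage
#' files). The causal variant is the panel variant nearest the region
#' midpoint, doubles as the index SNP of the single fine-mapped region,
#' and carries a planted full strong-evidence annotation profile.
#'
#' @param config a [pipeline_config()], or the path of a YAML file for
#'   [read_pipeline_config()].
#' @return the manifest (list), invisibly; also written as
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  manifest <- list(config = unclass(config)[setdiff(names(config), "out_dir")],
                   stages = list())

  ## -- simulate ------------------------------------------------------------
  panel <- simulate_haplotype_panel(
    n_hap = config$n_hap, n_variants = config$n_variants,
    region_length = config$region_length,
    recombination_rate = config$recombination_rate,
    maf_floor = config$maf_floor, n_founders = config$n_founders,
    seed = config$seed)
  causal <- panel$variant_ids[
    which.min(abs(panel$positions - config$region_length / 2))]
  design <- simulation_design(
    causal_variant_id = causal, causal_or = config$causal_or,
    n_studies = config$n_studies,
    cases_per_study = config$cases_per_study,
    controls_per_study = config$controls_per_study,
    baseline_prevalence = config$baseline_prevalence,
    target_rsq = config$target_rsq, seed = config$seed + 1L)
  studies <- simulate_case_control(panel, design)
  planted <- setNames(list(evidence_record(
    variant_id = causal, histone_mark = TRUE, open_chromatin = TRUE,
    protein_binding = TRUE, cancer_normal_differential = TRUE,
    colorectal_evidence = TRUE, motif_altered = TRUE, conserved = TRUE)),
    causal)
  tracks_dir <- file.path(out, "tracks")
  bundle <- simulate_annotation_tracks(panel, planted, tracks_dir,
                                       background_rate = config$background_rate,
                                       seed = config$seed + 2L)
  paths$vcf <- vapply(studies, function(s) {
    p <- file.path(out, sprintf("%s.vcf", s$study_id))
    write_study_vcf(s, p)
    p
  }, character(1))
  paths$phenotypes <- write_phenotypes(studies,
                                       file.path(out, "phenotypes.tsv"))
  manifest$stages$simulate <- list(
    n_variants = config$n_variants,
    n_subjects = sum(vapply(studies, function(s) length(s$phenotype),
                            numeric(1))),
    causal_variant = causal)
  stage_log("simulate", config$n_variants, config$n_variants)

  ## -- qc ------------------------------------------------------------------
  qc_reports <- lapply(studies, qc_study, maf_min = config$maf_min)
  qc_all <- do.call(rbind, Map(function(r, s) {
    r$study_id <- s$study_id
    r
  }, qc_reports, studies))
  paths$qc <- file.path(out, "qc_report.tsv")
  write.table(qc_all, paths$qc, sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- Reduce(intersect, lapply(qc_reports,
                                   function(r) r$variant_id[r$keep]))
  manifest$stages$qc <- list(n_in = config$n_variants, n_out = length(kept))
  stage_log("qc", config$n_variants, length(kept))
  if (length(kept) < 2) stop_invalid("pipeline halted at qc: <2 variants kept")

  ## -- association ---------------------------------------------------------
  scans <- lapply(studies, run_region_scan, variant_ids = kept)
  paths$assoc <- file.path(out, "association.tsv")
  write_assoc_tsv(do.call(rbind, scans), paths$assoc)
  manifest$stages$association <- list(n_in = length(kept),
                                      n_out = length(kept))
  stage_log("association", length(kept), length(kept))

  ## -- meta ----------------------------------------------------------------
  meta <- meta_scan(scans)
  meta_out <- meta
  meta_out$beta <- meta$beta_meta
  meta_out$se <- meta$se_meta
  meta_out$p <- meta$p_meta
  paths$meta <- file.path(out, "meta.tsv")
  write_assoc_tsv(meta_out, paths$meta)
  manifest$stages$meta <- list(n_in = length(kept), n_out = nrow(meta))
  stage_log("meta", length(kept), nrow(meta))

  ## -- fine-mapping --------------------------------------------------------
  variants_tbl <- studies[[1]]$variant_meta[
    studies[[1]]$variant_meta$variant_id %in% kept, ]
  region <- build_region(causal, variants_tbl, flank = config$flank)
  meta_region <- meta[meta$variant_id %in% region$variants, ]
  top <- find_top_snp(meta_region[meta_region$converged, ])
  cond <- conditional_scan(studies, region, top)
  cand <- select_annotation_set(region, meta_region, panel,
                                conditional_results = cond,
                                top_k = config$top_k,
                                r2_threshold = config$r2_threshold,
                                conditional_p = config$conditional_p)
  paths$region <- file.path(out, "regions.tsv")
  write.table(data.frame(index_snp = region$index_snp, chrom = region$chrom,
                         start = region$start, end = region$end,
                         n_snps = region$n_snps,
                         truncated = region$truncated,
                         top_snp = top),
              paths$region, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$conditional <- file.path(out, "conditional.tsv")
  write.table(cond, paths$conditional, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$candidates <- file.path(out, "candidates.tsv")
  write.table(cand$members, paths$candidates, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$finemap <- list(
    n_in = nrow(meta_region), n_out = length(cand$all),
    region_span = region$end - region$start + 1L,
    top_snp = top, index_snp = region$index_snp,
    n_conditional_significant = sum(cond$significant, na.rm = TRUE))
  stage_log("finemap", nrow(meta_region), length(cand$all))

  ## -- annotate & score ----------------------------------------------------
  cand_variants <- studies[[1]]$variant_meta[
    match(cand$all, studies[[1]]$variant_meta$variant_id), ]
  records <- evidence_from_tracks(cand_variants, bundle)
  scores <- lapply(records, score_evidence)
  ## one synthetic gene spanning the central 100 kb anchors gene-context calls
  gene_models <- data.frame(
    gene = "SYNG1", chrom = panel$chrom,
    start = as.integer(config$region_length / 2 - 50000L),
    end = as.integer(config$region_length / 2 + 50000L), strand = "+")
  contexts <- lapply(seq_len(nrow(cand_variants)), function(i)
    assign_gene_context(cand_variants[i, ], gene_models))
  scored <- data.frame(
    variant_id = cand$all,
    locus = region$index_snp,
    is_index = cand$all == region$index_snp,
    location_class = vapply(contexts, `[[`, character(1), "location_class"),
    motif_altered = vapply(records, `[[`, logical(1), "motif_altered"),
    score = vapply(scores, `[[`, numeric(1), "score"),
    category = vapply(scores, `[[`, character(1), "category"),
    stringsAsFactors = FALSE, row.names = NULL)
  paths$scores <- file.path(out, "functional_scores.tsv")
  write.table(scored, paths$scores, sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary <- score_candidate_table(scored)
  manifest$stages$score <- list(
    n_in = length(cand$all), n_out = nrow(scored),
    n_strong = summary$n_strong,
    causal_in_candidates = causal %in% cand$all,
    causal_category = scored$category[match(causal, scored$variant_id)])
  stage_log("score", length(cand$all), nrow(scored))

  ## -- power ---------------------------------------------------------------
  pc <- power_curve(sum(design$cases_per_study),
                    sum(design$controls_per_study),
                    config$power_mafs, config$power_ors)
  paths$power <- file.path(out, "power_curve.tsv")
  write.table(pc, paths$power, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$power <- list(n_in = nrow(pc), n_out = nrow(pc))
  stage_log("power", nrow(pc), nrow(pc))

  ## -- manifest ------------------------------------------------------------
  all_files <- c(unlist(paths, use.names = FALSE),
                 unlist(bundle[setdiff(names(bundle), "dir")],
                        use.names = FALSE))
  manifest$files <- data.frame(
    path = sub(paste0("^", out, "/?"), "", all_files),
    md5 = unname(md5sum(all_files)), stringsAsFactors = FALSE)
  manifest$files <- manifest$files[order(manifest$files$path), ]
  rownames(manifest$files) <- NULL
  yaml::write_yaml(
    c(manifest["stages"],
      list(files = setNames(as.list(manifest$files$md5),
                            manifest$files$path))),
    file.path(out, "manifest.yaml"))
  invisible(manifest)
}
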