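#' Describe a multi-study case-control simulation
#'
#' Collects the knobs of the retrospective case-control simulator. Defaults
#' emulate the consortium design the workflow targets: 14 studies totalling
#' 11,900 cases and 14,311 controls (uniform split, remainders on the first
#' studies), a per-allele odds ratio in the 1.1-1.3 range typical of common
#' colorectal-cancer risk variants, covariates age ~ Normal(64.2, 9),
#' sex ~ Bernoulli(0.5) and three standard-normal principal components with
#' mild effects, and imputation-style dosage error.
#'
#' @param causal_variant_id id of the causal variant in the panel.
#' @param causal_or per-allele odds ratio (> 0); 1 gives a null simulation.
#' @param n_studies number of independent studies.
#' @param cases_per_study,controls_per_study per-study counts, recycled to
#'   `n_studies`.
#' @param baseline_prevalence disease probability for a subject with zero
#'   alternate alleles and covariates at their means.
#' @param covariate_effects named log-odds per unit of each covariate
#'   (names among `age`, `sex`, `pc1`, `pc2`, `pc3`).
#' @param target_rsq imputation accuracy (squared dosage/genotype
#'   correlation) applied to every variant; 1 keeps hard genotypes.
#' @param strata per-study stratum labels (`"crc"` or `"adenoma"`),
#'   recycled; strata are analysed separately and only combined at the
#'   meta-analysis stage.
#' @param seed integer seed.
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(causal_variant_id,
                              causal_or = 1.2,
                              n_studies = 14L,
                              cases_per_study = NULL,
                              controls_per_study = NULL,
                              baseline_prevalence = 0.1,
                              covariate_effects = c(age = 0.01, sex = 0.15,
                                                    pc1 = 0.10, pc2 = 0, pc3 = 0),
                              target_rsq = 1,
                              strata = "crc",
                              seed = 1L) {
  if (causal_or <= 0) stop_invalid("causal_or must be > 0")
  if (target_rsq < 0 || target_rsq > 1)
    stop_invalid("target_rsq must be in [0, 1]")
  if (n_studies < 1) stop_invalid("n_studies must be >= 1")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop_invalid("baseline_prevalence must be in (0, 1)")
  if (is.null(cases_per_study))
    cases_per_study <- split_evenly(11900L, n_studies)
  if (is.null(controls_per_study))
    controls_per_study <- split_evenly(14311L, n_studies)
  cases_per_study <- rep_len(as.integer(cases_per_study), n_studies)
  controls_per_study <- rep_len(as.integer(controls_per_study), n_studies)
  if (any(cases_per_study < 1) || any(controls_per_study < 1))
    stop_invalid("per-study case and control counts must be >= 1")
  strata <- rep_len(match.arg(strata, c("crc", "adenoma"), several.ok = TRUE),
                    n_studies)
  structure(
    list(causal_variant_id = causal_variant_id,
         causal_or = causal_or,
         n_studies = as.integer(n_studies),
         cases_per_study = cases_per_study,
         controls_per_study = controls_per_study,
         baseline_prevalence = baseline_prevalence,
         covariate_effects = covariate_effects,
         target_rsq = target_rsq,
         strata = strata,
         seed = as.integer(seed)),
    class = "simulation_design")
}

split_evenly <- function(total, k) {
  base <- total %/% k
  out <- rep(base, k)
  extra <- total - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  as.integer(out)
}

covariate_names <- c("age", "sex", "pc1", "pc2", "pc3")

draw_covariates <- function(n) {
  cbind(age = rnorm(n, 64.2, 9),
        sex = rbinom(n, 1, 0.5),
        pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n))
}

## Solve the logistic intercept so that E[P(case)] over the population model
## equals the requested prevalence (Monte-Carlo expectation, fixed draws).
solve_intercept <- function(beta, causal_freq, gamma, prevalence, n_mc = 20000L) {
  g <- rbinom(n_mc, 2, causal_freq)
  cov <- draw_covariates(n_mc)
  cov_centred <- sweep(cov, 2, c(64.2, 0.5, 0, 0, 0))
  eta0 <- beta * g + drop(cov_centred %*% gamma[covariate_names])
  f <- function(alpha) mean(plogis(alpha + eta0)) - prevalence
  uniroot(f, c(-30, 10), tol = 1e-8)$root
}

#' Simulate multi-study retrospective case-control genotype data
#'
#' Subjects are generated under the population model: two haplotypes drawn
#' with replacement from the reference panel give the genotype; disease
#' status follows `logit(P) = alpha + log(causal_or) * g + covariates`, with
#' the intercept tuned so the population prevalence matches the design.
#' Cases and controls are then accumulated by rejection sampling until the
#' requested per-study counts are met (cost grows as `1/prevalence`; an
#' explicit sampling-exhaustion error is raised if the draw budget runs
#' out). When `design$target_rsq < 1`, hard genotypes are degraded to
#' imputation-style dosages with [degrade_to_dosage()].
#'
#' @param panel a [simulate_haplotype_panel()] panel containing the causal
#'   variant.
#' @param design a [simulation_design()].
#' @param max_draws population-draw budget per study before the
#'   sampling-exhaustion error fires; the default (500 draws per requested
#'   subject) accommodates prevalences down to roughly 0.4\% at balanced
#'   case/control counts.
#' @return list of `study_dataset` objects (one per study), each with
#'   `study_id`, `stratum`, `phenotype` (0/1), `dosages` (subjects x
#'   variants, values in `[0, 2]`), `covariates`, `subject_ids`, and
#'   `variant_meta` (id, position, maf, rsq, source).
#' @export
simulate_case_control <- function(panel, design, max_draws = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(design, "simulation_design"))
  cv <- design$causal_variant_id
  if (!cv %in% panel$variant_ids)
    stop_invalid("causal variant '%s' not present in the panel", cv)

  set.seed(design$seed)
  n_hap <- nrow(panel$haplotypes)
  causal_col <- match(cv, panel$variant_ids)
  causal_freq <- mean(panel$haplotypes[, causal_col])
  beta <- log(design$causal_or)
  gamma <- setNames(numeric(5), covariate_names)
  eff <- design$covariate_effects
  gamma[intersect(names(eff), covariate_names)] <-
    eff[intersect(names(eff), covariate_names)]
  alpha <- solve_intercept(beta, causal_freq, gamma,
                           design$baseline_prevalence)

  studies <- vector("list", design$n_studies)
  for (s in seq_len(design$n_studies)) {
    n_case <- design$cases_per_study[s]
    n_ctrl <- design$controls_per_study[s]
    budget <- max_draws %||% ceiling(500 * (n_case + n_ctrl))
    drawn <- 0L
    case_rows <- list(); ctrl_rows <- list()
    n_case_acc <- 0L; n_ctrl_acc <- 0L
    while (n_case_acc < n_case || n_ctrl_acc < n_ctrl) {
      if (drawn >= budget)
        stop_invalid(paste0(
          "sampling exhausted for study %d after %d draws ",
          "(prevalence %.3g too low for the requested %d cases)"),
          s, drawn, design$baseline_prevalence, n_case)
      batch <- min(max(2L * (n_case + n_ctrl), 1000L), budget - drawn)
      drawn <- drawn + batch
      h1 <- sample.int(n_hap, batch, replace = TRUE)
      h2 <- sample.int(n_hap, batch, replace = TRUE)
      g <- panel$haplotypes[h1, causal_col] + panel$haplotypes[h2, causal_col]
      cov <- draw_covariates(batch)
      cov_centred <- sweep(cov, 2, c(64.2, 0.5, 0, 0, 0))
      p <- plogis(alpha + beta * g + drop(cov_centred %*% gamma))
      status <- rbinom(batch, 1, p)
      keep_case <- which(status == 1)[seq_len(min(sum(status == 1),
                                                  n_case - n_case_acc))]
      keep_ctrl <- which(status == 0)[seq_len(min(sum(status == 0),
                                                  n_ctrl - n_ctrl_acc))]
      if (length(keep_case)) {
        case_rows[[length(case_rows) + 1L]] <-
          list(h1 = h1[keep_case], h2 = h2[keep_case],
               cov = cov[keep_case, , drop = FALSE])
        n_case_acc <- n_case_acc + length(keep_case)
      }
      if (length(keep_ctrl)) {
        ctrl_rows[[length(ctrl_rows) + 1L]] <-
          list(h1 = h1[keep_ctrl], h2 = h2[keep_ctrl],
               cov = cov[keep_ctrl, , drop = FALSE])
        n_ctrl_acc <- n_ctrl_acc + length(keep_ctrl)
      }
    }
    h1 <- c(unlist(lapply(case_rows, `[[`, "h1")),
            unlist(lapply(ctrl_rows, `[[`, "h1")))
    h2 <- c(unlist(lapply(case_rows, `[[`, "h2")),
            unlist(lapply(ctrl_rows, `[[`, "h2")))
    covariates <- rbind(do.call(rbind, lapply(case_rows, `[[`, "cov")),
                        do.call(rbind, lapply(ctrl_rows, `[[`, "cov")))
    phenotype <- c(rep(1L, n_case), rep(0L, n_ctrl))
    genotypes <- panel$haplotypes[h1, , drop = FALSE] +
      panel$haplotypes[h2, , drop = FALSE]
    study_id <- sprintf("study%02d", s)
    subject_ids <- sprintf("%s_S%05d", study_id, seq_len(n_case + n_ctrl))
    rownames(genotypes) <- subject_ids
    rownames(covariates) <- subject_ids

    maf <- pmin(colMeans(genotypes) / 2, 1 - colMeans(genotypes) / 2)
    if (design$target_rsq < 1) {
      deg <- degrade_to_dosage(genotypes, design$target_rsq,
                               seed = design$seed + 1000L + s,
                               allele_freq = panel_freq(panel))
      dosages <- deg$dosages
      rsq <- deg$rsq
      source <- rep("imputed", ncol(genotypes))
    } else {
      dosages <- genotypes
      rsq <- rep(1, ncol(genotypes))
      source <- rep("genotyped", ncol(genotypes))
    }
    studies[[s]] <- structure(
      list(study_id = study_id,
           stratum = design$strata[s],
           phenotype = phenotype,
           dosages = dosages,
           covariates = covariates,
           subject_ids = subject_ids,
           variant_meta = data.frame(
             variant_id = panel$variant_ids,
             chrom = panel$chrom,
             position = panel$positions,
             maf = unname(maf),
             rsq = unname(rsq),
             source = source,
             stringsAsFactors = FALSE)),
      class = "study_dataset")
  }
  studies
}

#' @exportS3Method base::print
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %s (%s): %d cases / %d controls, %d variants\n",
              x$study_id, x$stratum, sum(x$phenotype == 1),
              sum(x$phenotype == 0), ncol(x$dosages)))
  invisible(x)
}

#' Degrade hard genotypes to imputation-style dosages
#'
#' Mimics posterior-mean shrinkage of genotype imputation:
#' `dosage = s * g + (1 - s) * 2p + jitter`, clipped to `[0, 2]`, where `p`
#' is the panel allele frequency. The raw signal fraction `s^2` and the
#' jitter variance are tied so the pre-clipping squared correlation with the
#' true genotype equals a trial value, and that trial value is solved
#' numerically (uniroot on the clipped empirical correlation, with common
#' random numbers) so the *returned* matrix attains the target Rsq.
#'
#' @param genotypes integer matrix in `{0, 1, 2}` (subjects x variants).
#' @param target_rsq target squared dosage/genotype correlation in `[0, 1]`.
#' @param seed integer seed.
#' @param allele_freq optional per-variant alternate-allele frequencies
#'   (defaults to the empirical column frequencies).
#' @return list with `dosages` (same shape, values in `[0, 2]`) and `rsq`
#'   (per-variant empirical squared correlation; `NA` for monomorphic
#'   columns).
#' @export
degrade_to_dosage <- function(genotypes, target_rsq, seed = 1L,
                              allele_freq = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0L, 1L, 2L)))
    stop_invalid("genotypes must contain only 0, 1, 2")
  if (length(target_rsq) != 1 || is.na(target_rsq) ||
      target_rsq < 0 || target_rsq > 1)
    stop_invalid("target_rsq must be a single value in [0, 1]")
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (is.null(allele_freq)) allele_freq <- colMeans(genotypes) / 2
  if (target_rsq == 1) {
    rsq <- rep(1, m)
    rsq[apply(genotypes, 2, sd) == 0] <- NA_real_
    return(list(dosages = genotypes, rsq = rsq))
  }

  set.seed(seed)
  dosages <- matrix(0, n, m, dimnames = dimnames(genotypes))
  rsq <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    p <- allele_freq[j]
    sg <- sd(g)
    eps <- rnorm(n)
    if (sg == 0) {
      dosages[, j] <- pmin(pmax(2 * p + 0.05 * eps, 0), 2)
      next
    }
    make <- function(r_raw) {
      s <- sqrt(r_raw)
      sig_e <- sg * sqrt(1 - r_raw)
      d <- s * g + (1 - s) * 2 * p + sig_e * eps
      ## clipping to [0, 2] biases the mean upward for low-frequency
      ## alleles; re-centre on the genotype mean, then re-clip (the
      ## residual shift is second order after three passes)
      for (it in 1:3) {
        d <- pmin(pmax(d, 0), 2)
        d <- d + (mean(g) - mean(d))
      }
      pmin(pmax(d, 0), 2)
    }
    clipped_r2 <- function(r_raw) {
      d <- make(r_raw)
      if (sd(d) == 0) return(0)
      cor(d, g)^2
    }
    r_raw <- if (target_rsq <= 0) 0 else {
      f <- function(r) clipped_r2(r) - target_rsq
      f_t <- f(target_rsq)
      if (abs(f_t) < 1e-4) target_rsq
      else {
        interval <- if (f_t > 0) c(1e-6, target_rsq) else c(target_rsq, 1)
        tryCatch(uniroot(f, interval, tol = 1e-5)$root,
                 error = function(e) target_rsq)
      }
    }
    d <- make(r_raw)
    dosages[, j] <- d
    rsq[j] <- if (sd(d) > 0) cor(d, g)^2 else 0
  }
  list(dosages = dosages, rsq = rsq)
}
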