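#' Log-additive logistic association of case status on allele dosage
#'
#' Unconditional logistic regression of a 0/1 phenotype on the expected
#' alternate-allele count (dosage in `[0, 2]`), optionally adjusted for
#' covariates. Fitting is maximum likelihood by iteratively reweighted
#' least squares (`stats::glm.fit`, at most `max_iter` iterations,
#' deviance tolerance `tol`). Inference is Wald: the standard error comes
#' from the observed information, the P-value from the two-sided normal
#' tail, and the 95\% CI is `exp(beta +/- 1.96 se)`. Separation or a
#' constant dosage is reported as `converged = FALSE` with a diagnostic,
#' never as a silent estimate.
#'
#' @param phenotype 0/1 vector with at least one case and one control.
#' @param dosage numeric vector in `[0, 2]`, same length.
#' @param covariates optional numeric matrix (rows aligned with
#'   `phenotype`).
#' @param variant_id,study_id labels carried into the result row.
#' @param max_iter,tol IRLS controls; `|beta| > 15` on the dosage
#'   coefficient is flagged as separation.
#' @return one-row data.frame: `variant_id`, `study_id`, `beta`, `se`,
#'   `p`, `or`, `ci_lower`, `ci_upper`, `n_cases`, `n_controls`,
#'   `converged`, `note`.
#' @export
fit_logistic_dosage <- function(phenotype, dosage, covariates = NULL,
                                variant_id = NA_character_,
                                study_id = NA_character_,
                                max_iter = 50L, tol = 1e-8) {
  phenotype <- as.numeric(phenotype)
  if (!all(phenotype %in% c(0, 1)))
    stop_invalid("phenotype must be binary 0/1")
  n <- length(phenotype)
  if (length(dosage) != n)
    stop_invalid("dosage length (%d) does not match phenotype length (%d)",
                 length(dosage), n)
  if (any(dosage < -1e-9) || any(dosage > 2 + 1e-9))
    stop_invalid("dosage values must lie in [0, 2]")
  n_cases <- sum(phenotype == 1)
  n_controls <- sum(phenotype == 0)
  if (n_cases == 0 || n_controls == 0)
    stop_invalid("need at least one case and one control (got %d / %d)",
                 n_cases, n_controls)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop_invalid("covariate rows (%d) do not align with phenotype (%d)",
                   nrow(covariates), n)
  }

  row <- data.frame(variant_id = variant_id, study_id = study_id,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                    n_cases = n_cases, n_controls = n_controls,
                    converged = FALSE, note = "", stringsAsFactors = FALSE)
  if (sd(dosage) == 0) {
    row$note <- "constant_dosage"
    return(row)
  }

  x <- cbind(`(Intercept)` = 1, dosage = dosage, covariates)
  fit <- suppressWarnings(
    glm.fit(x, phenotype, family = binomial(),
            control = glm.control(epsilon = tol, maxit = max_iter)))
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    row$note <- "collinear"
    return(row)
  }
  ## observed-information covariance from the final weighted QR
  qr_r <- qr.R(fit$qr)
  covmat <- chol2inv(qr_r)
  pivot <- fit$qr$pivot
  ses <- numeric(length(coefs))
  ses[pivot] <- sqrt(diag(covmat))
  beta <- unname(coefs["dosage"])
  se <- ses[which(colnames(x) == "dosage")]

  row$beta <- beta
  row$se <- se
  row$p <- 2 * pnorm(-abs(beta / se))
  row$or <- exp(beta)
  row$ci_lower <- exp(beta - 1.96 * se)
  row$ci_upper <- exp(beta + 1.96 * se)
  if (!fit$converged) {
    row$note <- "no_convergence"
  } else if (abs(beta) > 15) {
    row$note <- "separation"
  } else if (!is.finite(se) || se <= 0) {
    row$note <- "unstable_se"
  } else {
    row$converged <- TRUE
  }
  row
}

#' Association scan of a study over a region
#'
#' Fits [fit_logistic_dosage()] for every region variant present in the
#' study after QC, adjusting for the study covariates. Non-converged
#' variants are retained in the output with `converged = FALSE` so that
#' downstream ranking can exclude them without losing bookkeeping.
#'
#' @param study a `study_dataset`.
#' @param variant_ids variants to scan; defaults to all study variants.
#'   Scanning an empty set returns a zero-row table with a warning.
#' @param covariates covariate matrix; defaults to the study covariates.
#'   Pass `NULL` explicitly for an unadjusted scan.
#' @return data.frame with one row per scanned variant, plus `chrom` and
#'   `position` columns for downstream region logic.
#' @export
run_region_scan <- function(study, variant_ids = NULL,
                            covariates = study$covariates) {
  stopifnot(inherits(study, "study_dataset"))
  vm <- study$variant_meta
  if (is.null(variant_ids)) variant_ids <- vm$variant_id
  missing <- setdiff(variant_ids, vm$variant_id)
  if (length(missing))
    stop_invalid("variants not present in study %s: %s", study$study_id,
                 paste(head(missing, 5), collapse = ", "))
  if (length(variant_ids) == 0L) {
    warning("empty region scan for study ", study$study_id)
    return(cbind(fit_logistic_dosage(c(0, 1), c(0, 1))[0, ],
                 chrom = character(0), position = integer(0)))
  }
  rows <- lapply(variant_ids, function(v) {
    j <- match(v, vm$variant_id)
    res <- fit_logistic_dosage(study$phenotype, study$dosages[, j],
                               covariates = covariates,
                               variant_id = v, study_id = study$study_id)
    res$chrom <- vm$chrom[j]
    res$position <- vm$position[j]
    res
  })
  do.call(rbind, rows)
}

#' Write an association (or meta-analysis) table as TSV
#'
#' Column layout (`CHR, POS, SNP, BETA, SE, P, ...`) is chosen to be
#' directly loadable by LocusZoom-style plotting tools.
#'
#' @param results a scan or meta table with `variant_id`, `chrom`,
#'   `position`, `beta`, `se`, `p` columns.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_assoc_tsv <- function(results, path) {
  out <- data.frame(CHR = results$chrom, POS = results$position,
                    SNP = results$variant_id,
                    BETA = results$beta, SE = results$se, P = results$p)
  for (extra in intersect(c("n_cases", "n_controls", "q", "p_het", "k"),
                          names(results)))
    out[[toupper(extra)]] <- results[[extra]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
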