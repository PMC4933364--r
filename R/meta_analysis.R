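#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Combines per-unit estimates with weights `w_i = 1/se_i^2`:
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = 1/sqrt(sum(w))`, Wald
#' P-value, plus Cochran's Q heterogeneity against a chi-square with
#' `k - 1` degrees of freedom. Units flagged non-converged (when a
#' `converged` vector is supplied) are excluded and `k` reflects the
#' exclusion; heterogeneity for `k < 2` is reported as `q = 0`,
#' `p_het = 1` with `degenerate = TRUE`.
#'
#' @param beta,se numeric vectors of per-unit log-OR estimates and their
#'   standard errors (all `se > 0`).
#' @param converged optional logical vector; `FALSE` units are dropped.
#' @param variant_id label carried into the result.
#' @return one-row data.frame: `variant_id`, `beta_meta`, `se_meta`,
#'   `p_meta`, `or`, `ci_lower`, `ci_upper`, `q`, `p_het`, `k`,
#'   `degenerate`.
#' @export
ivw_fixed <- function(beta, se, converged = NULL,
                      variant_id = NA_character_) {
  if (length(beta) != length(se))
    stop_invalid("beta and se differ in length")
  keep <- is.finite(beta) & is.finite(se)
  if (!is.null(converged)) keep <- keep & converged
  beta <- beta[keep]; se <- se[keep]
  if (length(beta) == 0L)
    stop_invalid("no usable units to meta-analyse (k = 0 after exclusions)")
  if (any(se <= 0)) stop_invalid("all standard errors must be > 0")
  k <- length(beta)
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  het <- cochran_q(beta, se)
  data.frame(variant_id = variant_id,
             beta_meta = beta_meta, se_meta = se_meta,
             p_meta = 2 * pnorm(-abs(beta_meta / se_meta)),
             or = exp(beta_meta),
             ci_lower = exp(beta_meta - 1.96 * se_meta),
             ci_upper = exp(beta_meta + 1.96 * se_meta),
             q = het$q, p_het = het$p_het, k = k,
             degenerate = het$degenerate,
             stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i (beta_i - beta_meta)^2)` with `w_i = 1/se_i^2`, referred to
#' a chi-square distribution with `k - 1` degrees of freedom. With fewer
#' than two units the statistic is degenerate: `q = 0`, `p_het = 1`.
#'
#' @inheritParams ivw_fixed
#' @return list with `q`, `p_het`, `df`, `degenerate`.
#' @export
cochran_q <- function(beta, se) {
  if (length(beta) != length(se))
    stop_invalid("beta and se differ in length")
  k <- length(beta)
  if (k < 2)
    return(list(q = 0, p_het = 1, df = 0L, degenerate = TRUE))
  if (any(se <= 0)) stop_invalid("all standard errors must be > 0")
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - beta_meta)^2)
  list(q = q, p_het = pchisq(q, df = k - 1, lower.tail = FALSE),
       df = k - 1L, degenerate = FALSE)
}

#' Meta-analyse per-study association scans variant by variant
#'
#' Groups one or more [run_region_scan()] tables by variant and applies
#' [ivw_fixed()]. Studies (and strata: CRC vs adenoma units enter as
#' separate rows of `scans`, never pooled at subject level) contribute one
#' unit each; non-converged rows are excluded per variant.
#'
#' @param scans a data.frame of stacked per-study scan rows, or a list of
#'   such data.frames.
#' @return data.frame with one row per variant (carrying `chrom` and
#'   `position` through), ordered by position.
#' @export
meta_scan <- function(scans) {
  if (is.list(scans) && !is.data.frame(scans))
    scans <- do.call(rbind, scans)
  stopifnot(is.data.frame(scans), nrow(scans) > 0)
  out <- lapply(split(scans, scans$variant_id), function(d) {
    if (!any(d$converged)) {
      res <- ivw_fixed(0, 1, variant_id = d$variant_id[1])
      res[, c("beta_meta", "se_meta", "p_meta", "or",
              "ci_lower", "ci_upper")] <- NA_real_
      res$k <- 0L
      res$converged <- FALSE
    } else {
      res <- ivw_fixed(d$beta, d$se, converged = d$converged,
                       variant_id = d$variant_id[1])
      res$converged <- TRUE
    }
    if ("chrom" %in% names(d)) res$chrom <- d$chrom[1]
    if ("position" %in% names(d)) res$position <- d$position[1]
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if ("position" %in% names(out)) out <- out[order(out$position), ]
  rownames(out) <- NULL
  out
}
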