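#' Analytic power of the per-allele (log-additive) case-control test
#'
#' Normal-approximation power for the two-sided Wald test of the per-allele
#' log odds ratio. The variance of the estimate is evaluated under the
#' alternative's allele frequencies: with control frequency `p0 = maf` the
#' case frequency is `p1 = OR p0 / (1 - p0 + OR p0)`, and
#' `Var(beta) = 1/(2 n_cases p1 (1 - p1)) + 1/(2 n_controls p0 (1 - p0))`.
#' At `or_alt = 1` the power equals the nominal level (both rejection
#' tails are counted).
#'
#' @param n_cases,n_controls sample sizes.
#' @param maf control-population allele frequency in `(0, 0.5]`.
#' @param or_alt per-allele odds ratio under the alternative (> 0).
#' @param alpha two-sided significance level in `(0, 1)`.
#' @return rejection probability in `(0, 1)`.
#' @export
power_trend <- function(n_cases, n_controls, maf, or_alt, alpha = 0.05) {
  if (n_cases < 1 || n_controls < 1)
    stop_invalid("sample sizes must be >= 1")
  if (maf <= 0 || maf > 0.5)
    stop_invalid("maf must be in (0, 0.5]")
  if (or_alt <= 0) stop_invalid("or_alt must be > 0")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  p0 <- maf
  p1 <- or_alt * p0 / (1 - p0 + or_alt * p0)
  v <- 1 / (2 * n_cases * p1 * (1 - p1)) +
    1 / (2 * n_controls * p0 * (1 - p0))
  delta <- log(or_alt) / sqrt(v)
  z <- qnorm(1 - alpha / 2)
  pnorm(-z + delta) + pnorm(-z - delta)
}

#' Minimum detectable per-allele odds ratio
#'
#' Solves `power_trend(..., or_alt) = power` for `or_alt > 1` by
#' root-finding on the log-OR scale (tolerance 1e-6 on power at the
#' returned OR is verified; a non-bracketing search interval raises an
#' explicit error).
#'
#' @inheritParams power_trend
#' @param power target power in `(0, 1)`.
#' @param or_max upper bracket for the search.
#' @return the smallest per-allele OR (> 1) detectable at the target
#'   power.
#' @export
min_detectable_or <- function(n_cases, n_controls, maf, alpha = 0.05,
                              power = 0.8, or_max = 20) {
  if (power <= 0 || power >= 1) stop_invalid("power must be in (0, 1)")
  f <- function(log_or)
    power_trend(n_cases, n_controls, maf, exp(log_or), alpha) - power
  lo <- 1e-8
  if (f(log(or_max)) < 0 || f(lo) > 0)
    stop_invalid(paste0(
      "search interval (1, %.3g] does not bracket the target power %.3g; ",
      "increase or_max or lower the target"), or_max, power)
  root <- uniroot(f, c(lo, log(or_max)), tol = 1e-10)$root
  exp(root)
}

#' Power-curve table over a grid of allele frequencies and odds ratios
#'
#' @inheritParams power_trend
#' @param mafs,ors grids to cross.
#' @return data.frame: `maf`, `or`, `power`.
#' @export
power_curve <- function(n_cases, n_controls, mafs, ors, alpha = 0.05) {
  grid <- expand.grid(maf = mafs, or = ors)
  grid$power <- mapply(function(m, o)
    power_trend(n_cases, n_controls, m, o, alpha), grid$maf, grid$or)
  grid
}
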