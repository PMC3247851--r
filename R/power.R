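#' Risk-allele frequency in cases under a log-additive model
#'
#' Converts a population (control) risk-allele frequency and a per-allele
#' odds ratio into the expected allele frequency among case chromosomes:
#' p' = OR * p / (1 + p * (OR - 1)).
#'
#' @param p_risk Risk-allele frequency in controls / the population.
#' @param odds_ratio Per-allele odds ratio (> 0).
#' @return The case allele frequency.
#' @export
case_allele_frequency <- function(p_risk, odds_ratio) {
  stopifnot(all(p_risk > 0 & p_risk < 1), all(odds_ratio > 0))
  odds_ratio * p_risk / (1 + p_risk * (odds_ratio - 1))
}

#' Approximate power of an allelic case-control test
#'
#' Normal approximation to the two-sided allelic (trend-type) test
#' comparing allele frequencies between cases and controls, evaluated on
#' effective chromosome counts 2 * N* per group. When the effective sample
#' sizes come from a pooling plan this gives pool-adjusted power; with the
#' raw sample sizes it gives conventional individual-genotyping power.
#' Under the rare-disease approximation control frequencies are taken
#' equal to population frequencies.
#'
#' @param ess_case,ess_control Effective sample sizes (individuals).
#' @param p_risk Risk-allele frequency in controls.
#' @param odds_ratio Per-allele odds ratio under a log-additive model.
#' @param alpha Two-sided significance level (default 0.05).
#' @return The approximate power, a number in (0, 1).
#' @examples
#' power_case_control(300, 1000, p_risk = 0.29, odds_ratio = 1.32)
#' @export
power_case_control <- function(ess_case, ess_control, p_risk, odds_ratio,
                               alpha = 0.05) {
  stopifnot(ess_case > 0, ess_control > 0, alpha > 0, alpha < 1)
  n1 <- 2 * ess_case
  n0 <- 2 * ess_control
  p1 <- case_allele_frequency(p_risk, odds_ratio)
  p0 <- p_risk
  d <- p1 - p0
  pbar <- (n1 * p1 + n0 * p0) / (n1 + n0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((d - z * se0) / se1) + stats::pnorm((-d - z * se0) / se1)
}

#' Minimum detectable odds ratio at a target power
#'
#' Smallest per-allele odds ratio above 1 whose approximate power
#' ([power_case_control()]) reaches the target, located by bisection on
#' log(OR). Strictly decreasing in both effective sample sizes.
#'
#' @inheritParams power_case_control
#' @param target_power Power to reach, in (alpha, 1).
#' @param tol Bisection tolerance on log(OR) (default 1e-4).
#' @return The minimum detectable odds ratio.
#' @examples
#' minimum_detectable_or(300, 1000, p_risk = 0.29, target_power = 0.8)
#' @export
minimum_detectable_or <- function(ess_case, ess_control, p_risk,
                                  target_power = 0.8, alpha = 0.05,
                                  tol = 1e-4) {
  stopifnot(target_power > alpha, target_power < 1)
  f <- function(log_or) {
    power_case_control(ess_case, ess_control, p_risk, exp(log_or), alpha) -
      target_power
  }
  lo <- 0
  hi <- log(1000)
  if (f(hi) < 0) {
    stop("target power unreachable even at odds ratio 1000")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Power over a grid of odds ratios
#'
#' @inheritParams power_case_control
#' @param odds_ratios Vector of odds ratios to evaluate.
#' @return A data frame with columns `or` and `power`.
#' @export
power_curve <- function(ess_case, ess_control, p_risk,
                        odds_ratios = seq(1, 2, by = 0.01), alpha = 0.05) {
  data.frame(or = odds_ratios,
             power = vapply(odds_ratios, function(or)
               power_case_control(ess_case, ess_control, p_risk, or, alpha),
               numeric(1)))
}
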