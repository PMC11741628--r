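# Population impact of a protective genotype and of the iKIR score.

#' Convert an odds ratio to a relative risk
#'
#' Uses the standard prevalence-based adjustment
#' `RR = OR / ((1 - p0) + p0 * OR)` with `p0` the disease risk among
#' genotype-negative individuals (approximated by the population
#' prevalence for a rare disease and a common genotype).
#'
#' @param or Odds ratio (> 0).
#' @param p0 Baseline (genotype-negative) risk in (0, 1).
#' @return Relative risk.
#' @export
or_to_rr <- function(or, p0) {
  stopifnot(or > 0, p0 > 0, p0 < 1)
  or / ((1 - p0) + p0 * or)
}

#' Fraction of cases prevented by a protective genotype
#'
#' Counterfactual prevented fraction `PF = f (1 - RR)`: the proportion of
#' cases averted in the population, relative to a population in which the
#' genotype is absent, for carriage frequency `f` and relative risk `RR`.
#' Supply a stratum-specific OR plus the disease prevalence to evaluate an
#' all-high-score or all-low-score scenario.
#'
#' @param f Genotype carriage frequency in [0, 1].
#' @param rr Relative risk (> 0); alternatively give `or` and `prevalence`
#'   and the RR is derived via [or_to_rr()].
#' @param or,prevalence Optional odds-ratio route.
#' @return Prevented fraction (in [0, 1] for RR < 1; negative, with a
#'   warning, when RR > 1 — an excess, not a prevention).
#' @examples
#' prevented_fraction(0.3, rr = 0.05)  # 0.285
#' @export
prevented_fraction <- function(f, rr = NULL, or = NULL, prevalence = NULL) {
  stopifnot(f >= 0, f <= 1)
  if (is.null(rr)) {
    stopifnot(!is.null(or), !is.null(prevalence))
    rr <- or_to_rr(or, prevalence)
  }
  stopifnot(rr > 0)
  pf <- f * (1 - rr)
  if (rr > 1) warning("RR > 1: returning a negative prevented fraction (excess)")
  pf
}

#' Relative increase in prevented fraction between score scenarios
#'
#' `100 (pf_low - pf_high) / pf_high`: by how many percent more cases are
#' prevented if the whole population had a low rather than a high iKIR
#' score. Scale-invariant in its inputs, so it can be evaluated directly
#' on prevented-case percentages.
#'
#' @param pf_low Prevented fraction under the all-low-score scenario.
#' @param pf_high Prevented fraction under the all-high-score scenario
#'   (> 0).
#' @return Percent increase.
#' @examples
#' relative_increase(31.6, 21.6)  # 46.3
#' @export
relative_increase <- function(pf_low, pf_high) {
  stopifnot(pf_high > 0)
  100 * (pf_low - pf_high) / pf_high
}

#' Normalized iKIR-score odds ratio within genotype carriers
#'
#' Rescales the iKIR score to [0, 1] by its attainable range under the
#' weight table (so the OR is comparable with presence/absence variants),
#' restricts the cohort to genotype-positive individuals and fits
#' `status ~ score_norm + sex`. The OR for the rescaled score equals the
#' raw-score OR raised to the power of the range (reparameterisation
#' identity).
#'
#' @param cohort Scored cohort.
#' @param genotype Genotype label defining the sub-cohort.
#' @param weights Weight table (sets the attainable range).
#' @param include_kir3dl2 Score setting.
#' @return One-row data.frame with `or`, `ci_low`, `ci_high`, `p_value`
#'   (on the OR scale) and attributes `range`, `n`.
#' @export
normalized_score_or <- function(cohort, genotype, weights = ikir_weights(),
                                include_kir3dl2 = FALSE) {
  if (!"ikir_score" %in% names(cohort))
    cohort <- score_cohort(cohort, weights = weights,
                           include_kir3dl2 = include_kir3dl2)
  sub <- cohort[genotype_carriage(cohort, genotype), ]
  if (!any(sub$status == 1) || !any(sub$status == 0))
    stop("genotype-positive sub-cohort needs both cases and controls")
  rng <- max_attainable_score(weights, include_kir3dl2)
  if (stats::var(sub$ikir_score) == 0)
    stop("degenerate (constant) iKIR score in sub-cohort")
  res <- fit_logistic(sub$status,
                      data.frame(score_norm = sub$ikir_score / rng,
                                 sex = as.integer(sub$sex == "M")))
  row <- res[res$term == "score_norm", ]
  out <- data.frame(or = exp(row$ln_or), ci_low = exp(row$ci_low),
                    ci_high = exp(row$ci_high), p_value = row$p_value)
  attr(out, "range") <- rng
  attr(out, "n") <- nrow(sub)
  out
}
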