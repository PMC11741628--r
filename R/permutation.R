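# Score-permutation tests: single-genotype stratification tests and the
# frequency-weighted multi-genotype statistic with an empirical null built
# by permuting iKIR scores across individuals.

#' Frequency-weighted mean iKIR-effect statistic
#'
#' The test statistic of the multi-genotype permutation test: the weighted
#' mean of the per-genotype iKIR effect, ln[OR] in the high-score stratum
#' minus ln[OR] in the low-score stratum, weighted by the genotype's
#' carriage frequency. For protective genotypes whose protection is
#' weakened by iKIRs the statistic is positive.
#'
#' @param ln_or_high,ln_or_low Per-genotype stratum estimates.
#' @param weights Positive weights (carriage frequencies); invariant to
#'   rescaling.
#' @return The scalar statistic; genotypes with an NA stratum estimate are
#'   dropped (with a message).
#' @export
weighted_delta_stat <- function(ln_or_high, ln_or_low, weights) {
  stopifnot(length(ln_or_high) == length(ln_or_low),
            length(weights) == length(ln_or_high))
  if (any(weights <= 0)) stop("weights must be > 0")
  delta <- ln_or_high - ln_or_low
  keep <- is.finite(delta)
  if (!all(keep)) {
    message(sum(!keep), " genotype(s) dropped: stratum estimate inestimable")
    if (!any(keep)) return(NA_real_)
  }
  sum(weights[keep] * delta[keep]) / sum(weights[keep])
}

#' Permute iKIR scores across individuals
#'
#' Each permutation shuffles the cohort's score vector, preserving its
#' multiset (and leaving every other column untouched).
#'
#' @param scores Numeric score vector.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return A `length(scores) x n_perm` matrix, one permutation per column.
#' @export
permute_scores <- function(scores, n_perm, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  n <- length(scores)
  vapply(seq_len(n_perm), function(b) scores[sample.int(n)], numeric(n))
}

#' Score-permutation test of iKIR modification
#'
#' Tests whether the difference between the high- and low-score stratum
#' effects of one or more genotypes is larger than expected by chance. The
#' null distribution is built by permuting the iKIR score across
#' individuals (genotypes, status and sex stay fixed) and recomputing the
#' statistic; the empirical p-value uses the add-one rule
#' `p = (n_as_extreme + 1) / (n_perm + 1)` and therefore never returns 0.
#'
#' The default statistic is [weighted_delta_stat()] over sex-adjusted
#' stratified logistic fits, with carriage frequencies in the analysed
#' cohort as weights; a single genotype reduces to its own
#' high-minus-low difference. Permutations in which a stratum estimate
#' does not exist for any genotype are dropped; the test aborts if more
#' than `max_inestimable` of permutations are lost this way.
#'
#' @param cohort Scored cohort data.frame.
#' @param genotypes Character vector of genotype labels.
#' @param threshold iKIR score threshold.
#' @param n_perm Number of permutations (default 1e5).
#' @param direction `"greater"` (one-sided, the a-priori direction for
#'   protective genotypes: statistic > 0) or `"two-sided"` (appropriate
#'   for the detrimental-genotype test, where no direction is predicted).
#' @param seed Integer seed.
#' @param statistic Optional custom statistic: a `function(strata_high)`
#'   mapping a logical high-stratum indicator to a number. When supplied,
#'   permutations are evaluated by calling it directly.
#' @param weights Optional per-genotype weights; default carriage
#'   frequency in `cohort`.
#' @param phase Carriage phase mode.
#' @param max_inestimable Abort threshold for the dropped-permutation
#'   fraction.
#' @param chunk Permutations processed per block (memory control).
#' @return An object of class `ikir_perm`: `observed_stat`, `n_perm`
#'   (valid permutations), `n_as_extreme`, `p_value`, `direction`, `seed`,
#'   and `per_genotype` (observed delta, weight and marginal add-one p per
#'   genotype).
#' @export
permutation_test <- function(cohort, genotypes, threshold = 1.75,
                             n_perm = 1e5, direction = c("greater", "two-sided"),
                             seed = 1L, statistic = NULL, weights = NULL,
                             phase = "either", max_inestimable = 0.2,
                             chunk = 500L) {
  direction <- match.arg(direction)
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)
  if (!"ikir_score" %in% names(cohort)) cohort <- score_cohort(cohort)
  n <- nrow(cohort)
  score <- cohort$ikir_score
  obs_high <- score > threshold
  set.seed(seed)

  if (!is.null(statistic)) {
    obs <- statistic(obs_high)
    perm_stats <- vapply(seq_len(n_perm), function(b)
      statistic(score[sample.int(n)] > threshold), 0)
    return(.perm_result(obs, perm_stats, direction, seed, n_perm,
                        per_genotype = NULL))
  }

  carr <- carriage_matrix(cohort, genotypes, phase)
  g <- matrix(as.integer(carr), n)
  sex <- as.integer(cohort$sex == "M")
  status <- as.integer(cohort$status)
  if (is.null(weights)) weights <- colMeans(carr)
  if (any(weights <= 0))
    stop("genotype(s) absent from cohort: ",
         paste(genotypes[weights <= 0], collapse = ", "))

  obs_fit <- lapply(seq_along(genotypes), function(j)
    batch_stratum_lnor(g[, j], sex, status, matrix(obs_high, n, 1)))
  d_obs <- vapply(obs_fit, function(f) f$high[1] - f$low[1], 0)
  obs <- weighted_delta_stat(d_obs, rep(0, length(d_obs)), weights)
  if (is.na(obs))
    stop("observed statistic inestimable for every genotype")

  perm_delta <- matrix(NA_real_, length(genotypes), n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    Shigh <- vapply(seq_len(b), function(i) score[sample.int(n)] > threshold,
                    logical(n))
    for (j in seq_along(genotypes)) {
      f <- batch_stratum_lnor(g[, j], sex, status, Shigh)
      perm_delta[j, done + seq_len(b)] <- f$high - f$low
    }
    done <- done + b
  }
  wsum <- colSums(matrix(weights * is.finite(perm_delta),
                         length(genotypes), n_perm))
  pd <- perm_delta; pd[!is.finite(pd)] <- 0
  perm_stats <- colSums(weights * pd) / wsum
  valid <- is.finite(perm_stats)
  if (mean(!valid) > max_inestimable)
    stop(sprintf("statistic inestimable in %.0f%% of permutations",
                 100 * mean(!valid)))
  per_genotype <- data.frame(
    genotype = genotypes, delta_obs = d_obs, weight = weights,
    p_value = vapply(seq_along(genotypes), function(j) {
      pj <- perm_delta[j, ]; ok <- is.finite(pj)
      extreme <- if (direction == "greater") pj[ok] >= d_obs[j]
                 else abs(pj[ok]) >= abs(d_obs[j])
      (sum(extreme) + 1) / (sum(ok) + 1)
    }, 0), row.names = NULL, stringsAsFactors = FALSE)
  .perm_result(obs, perm_stats[valid], direction, seed, n_perm, per_genotype)
}

.perm_result <- function(obs, perm_stats, direction, seed, n_perm_requested,
                         per_genotype) {
  extreme <- if (direction == "greater") perm_stats >= obs
             else abs(perm_stats) >= abs(obs)
  n_valid <- length(perm_stats)
  structure(list(
    observed_stat = obs, n_perm = n_valid, n_as_extreme = sum(extreme),
    p_value = (sum(extreme) + 1) / (n_valid + 1),
    direction = direction, seed = seed,
    n_perm_requested = n_perm_requested,
    per_genotype = per_genotype,
    null_stats = perm_stats), class = "ikir_perm")
}

#' @export
print.ikir_perm <- function(x, ...) {
  cat("Score-permutation test (", x$direction, ")\n", sep = "")
  cat(sprintf("  observed statistic = %.4f\n", x$observed_stat))
  cat(sprintf("  p = %.3g  (%d of %d permutations as extreme, add-one rule)\n",
              x$p_value, x$n_as_extreme, x$n_perm))
  if (!is.null(x$per_genotype)) {
    cat("  per-genotype high-minus-low differences:\n")
    print(x$per_genotype, row.names = FALSE)
  }
  invisible(x)
}
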