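# Score-permutation machinery.

test_that("weighted delta statistic is a weighted mean with scale-invariant weights", {
  # identical strata estimates -> 0
  expect_equal(weighted_delta_stat(c(-1, -2), c(-1, -2), c(1, 2)), 0)
  # single published genotype difference: -3.12 - (-4.58) = 1.46
  expect_equal(weighted_delta_stat(-3.12, -4.58, 5), 1.46)
  # plain arithmetic mean for equal weights
  expect_equal(weighted_delta_stat(c(1, 3), c(0, 0), c(1, 1)), 2)
  # rescaling weights changes nothing
  expect_equal(weighted_delta_stat(c(1, 3), c(0, 0), c(0.2, 0.6)),
               weighted_delta_stat(c(1, 3), c(0, 0), c(2, 6)))
  expect_message(s <- weighted_delta_stat(c(1, NA), c(0, 0), c(1, 1)), "dropped")
  expect_equal(s, 1)
  expect_error(weighted_delta_stat(1, 0, 0), "weights")
})

test_that("score permutations preserve the multiset and differ by seed", {
  sc <- c(0, 1, 1.75, 2.5, 3.25)
  pm <- permute_scores(sc, 20, seed = 1)
  expect_equal(dim(pm), c(5, 20))
  for (b in 1:20) expect_equal(sort(pm[, b]), sort(sc))
  expect_false(identical(permute_scores(sc, 20, seed = 1),
                         permute_scores(sc, 20, seed = 2)))
  expect_error(permute_scores(sc, 0), "n_perm")
})

test_that("permutation p-values respect the add-one floor and determinism", {
  coh <- score_cohort(generate_cohort(null_config(n_cases = 200,
                                                  n_controls = 200, seed = 6)))
  # a statistic maximal only at the observed assignment is never matched
  # by a permutation: p hits the add-one floor 1/(n_perm+1)
  obs_high <- coh$ikir_score > 1.75
  res <- permutation_test(coh, "DQB1*03:01", n_perm = 99, seed = 2,
                          statistic = function(high) -sum(xor(high, obs_high)))
  expect_equal(res$p_value, 1 / 100)
  expect_equal(res$n_as_extreme, 0)
  r1 <- permutation_test(coh, "DQB1*03:01", n_perm = 200, seed = 3)
  r2 <- permutation_test(coh, "DQB1*03:01", n_perm = 200, seed = 3)
  expect_equal(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
})

test_that("sampled permutation p agrees with exhaustive enumeration on a toy cohort", {
  # 8 individuals, distinct scores; statistic = difference in mean case
  # fraction between strata, computable for every permutation
  toy <- toy_cohort()
  toy$ikir_score <- c(3, 2.5, 2, 1.9, 1.5, 1, 0.5, 0)
  stat <- function(high) mean(toy$status[high]) - mean(toy$status[!high])
  # exhaustive oracle over all 8! index permutations
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  all_p <- perms(1:8)
  obs <- stat(toy$ikir_score > 1.75)
  null_stats <- vapply(all_p, function(idx) stat(toy$ikir_score[idx] > 1.75), 0)
  p_exact <- mean(null_stats >= obs - 1e-12)
  res <- permutation_test(toy, "unused", n_perm = 4000, seed = 9, statistic = stat)
  # sampled add-one p within 3 binomial SEs of the exact enumeration value
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-3)
})

test_that("multi-genotype test weights by carriage frequency and reports
           per-genotype results", {
  coh <- generate_cohort(cohort_config(n_cases = 800, n_controls = 800,
                                       interaction_beta = 0.9, seed = 12))
  res <- permutation_test(coh, PROT_SET, n_perm = 300, seed = 4)
  expect_equal(nrow(res$per_genotype), 4)
  expect_equal(res$per_genotype$weight,
               unname(colMeans(carriage_matrix(coh, PROT_SET))))
  # observed statistic equals the weighted mean of per-genotype deltas
  expect_equal(res$observed_stat,
               with(res$per_genotype, sum(weight * delta_obs) / sum(weight)))
  # generated interaction is detected
  expect_lt(res$p_value, 0.05)
})

test_that("permutation refits agree with stats::glm on the observed data", {
  coh <- generate_cohort(cohort_config(n_cases = 500, n_controls = 500, seed = 14))
  res <- permutation_test(coh, "DQB1*03:01", n_perm = 50, seed = 1)
  se <- stratified_effect(coh, "DQB1*03:01")
  expect_equal(res$per_genotype$delta_obs, se$high$ln_or - se$low$ln_or,
               tolerance = 1e-6)
})
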