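# Crude and model-based association estimates.

test_that("crude ln[OR] reproduces published whole-cohort rows at 2 dp", {
  counts <- utils::read.delim(system.file("extdata", "published_strata_counts.tsv",
                                          package = "ikirmod"))
  whole <- counts[counts$group == "whole", ]
  est <- vapply(seq_len(nrow(whole)), function(i)
    crude_ln_or(whole$n_gpos_case[i], whole$n_gpos_ctrl[i],
                whole$n_gneg_case[i], whole$n_gneg_ctrl[i]), 0)
  # published estimates are sex-adjusted; the crude 2x2 value lands on the
  # printed number at 2 dp for these rows and within 0.01 for the rest
  exact <- whole$genotype %in% c("DQA1*01:02-DQB1*06:02", "DQB1*03:01",
                                 "DQA1*01:02")
  expect_equal(round(est[exact], 2), whole$published_lnor[exact])
  expect_true(all(abs(est - whole$published_lnor) < 0.02))
  # each published row analyses the same reduced cohort
  expect_true(all(rowSums(whole[, 4:7]) == 5420))
})

test_that("crude ln[OR] handles symmetry and zero cells", {
  expect_equal(crude_ln_or(10, 10, 10, 10), 0)
  expect_error(crude_ln_or(0, 5, 5, 5), "zero cell")
  expect_equal(crude_ln_or(0, 5, 5, 5, continuity = "haldane"),
               log((0.5 * 5.5) / (5.5 * 5.5)))
})

test_that("single-predictor logistic coefficient equals the crude ln[OR]", {
  tabs <- list(c(26, 729, 2984, 1681), c(361, 777, 2649, 1633),
               c(12, 85, 2998, 2325))
  for (cells in tabs) {
    status <- rep(c(1, 0, 1, 0), cells)
    g <- rep(c(1, 1, 0, 0), cells)
    fit <- fit_logistic(status, data.frame(genotype = g))
    expect_equal(fit$ln_or[fit$term == "genotype"],
                 crude_ln_or(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-8)
  }
})

test_that("an uninformative predictor has a near-zero coefficient and
           separation raises a diagnostic", {
  status <- rep(c(1, 0), each = 50)
  flat <- rep(c(0, 1), 50)
  fit <- fit_logistic(status, data.frame(x = flat))
  expect_lt(abs(fit$ln_or[fit$term == "x"]), 1e-8)
  expect_error(suppressWarnings(fit_logistic(status, data.frame(x = status))),
               "separation")
})

test_that("stratified effects follow the generative interaction direction
           and skip sparse genotypes", {
  cfg <- cohort_config(n_cases = 1500, n_controls = 1500,
                       interaction_beta = 0.9, seed = 17)
  coh <- generate_cohort(cfg)
  res <- stratified_effect(coh, "DQA1*01:02-DQB1*06:02")
  expect_lt(res$low$ln_or, res$high$ln_or)  # stronger protection in low stratum
  expect_true(res$whole$ci_low <= res$whole$ln_or &
                res$whole$ln_or <= res$whole$ci_high)
  # four-cell counts sum to the analysed size in every stratum
  strat <- stratify(coh$ikir_score, 1.75)
  expect_equal(sum(attr(res$high, "n_by_cell")), sum(strat == "high"))
  expect_equal(sum(attr(res$low, "n_by_cell")), sum(strat == "low"))
  expect_equal(sum(attr(res$whole, "n_by_cell")), nrow(coh))

  # a genotype carried by < 10 cases is skipped with a reason
  rare <- coh[1:40, ]
  expect_message(out <- stratified_effect(rare, "DQA1*01:02-DQB1*06:02"),
                 "skipped")
  expect_s3_class(out, "ikir_skipped")
})

test_that("interaction model recovers the generative coefficient and reports AIC", {
  cfg <- cohort_config(n_cases = 2000, n_controls = 2000,
                       interaction_beta = 0.9, seed = 23)
  coh <- generate_cohort(cfg)
  res <- interaction_model(coh, "DQA1*01:02-DQB1*06:02")
  expect_gt(res$ln_or, 0)          # positive interaction: protection weakened
  expect_lt(res$p_value, 0.05)
  expect_true(res$ci_low < 0.9 & 0.9 < res$ci_high)
  # AIC = 2k - 2 logLik by definition
  expect_equal(attr(res, "aic"), 2 * 5 - 2 * attr(res, "loglik"))
  # stratified coding also runs
  res2 <- interaction_model(coh, "DQA1*01:02-DQB1*06:02", score_mode = "stratified")
  expect_gt(res2$ln_or, 0)
})

test_that("resampling power is calibrated at null and non-decreasing in s", {
  # subcohorts much smaller than the base cohort, so the base cohort's own
  # sampling noise does not dominate the resampled interaction estimates
  cfg0 <- null_config(n_cases = 1000, n_controls = 1000, seed = 3)
  coh0 <- generate_cohort(cfg0)
  pw0 <- power_by_resampling(coh0, "DQA1*01:02-DQB1*06:02",
                             sample_sizes = 200, n_boot = 100, seed = 7)
  expect_lt(pw0$power, 0.16)  # near-nominal type-I at the null

  cfg1 <- cohort_config(n_cases = 1200, n_controls = 1200,
                        interaction_beta = 0.9, seed = 3)
  coh1 <- generate_cohort(cfg1)
  pw1 <- power_by_resampling(coh1, "DQA1*01:02-DQB1*06:02",
                             sample_sizes = c(200, 2000), n_boot = 60, seed = 7)
  expect_gte(pw1$power[2] + 0.1, pw1$power[1])  # monotone within MC error
})
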