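# Synthetic cohort and trio generation, and cohort/trio file round-trips.

test_that("cohort generation honours quotas, determinism and the all-control edge", {
  cfg <- cohort_config(n_cases = 0, n_controls = 10, seed = 4)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 10)
  expect_true(all(coh$status == 0))

  cfg2 <- cohort_config(n_cases = 40, n_controls = 60, seed = 8)
  c1 <- generate_cohort(cfg2)
  c2 <- generate_cohort(cfg2)
  expect_identical(c1, c2)
  expect_equal(sum(c1$status), 40)
  expect_equal(nrow(c1), 100)
  # different seed gives a different cohort
  c3 <- generate_cohort(cohort_config(n_cases = 40, n_controls = 60, seed = 9))
  expect_false(identical(c1$kir_genes, c3$kir_genes))
})

test_that("config validation rejects unattainable labels and bad probabilities", {
  expect_error(cohort_config(effect_lnors = c("DQB1*99:99" = -1)),
               "unattainable")
  expect_error(cohort_config(interaction_genotypes = "DQB1*03:01",
                             effect_lnors = c("DQA1*01:02-DQB1*06:02" = -2)),
               "interaction_genotypes")
  expect_error(cohort_config(sex_ratio = 1.4))
})

test_that("crude ln[OR] of a generated genotype recovers the generative value", {
  # single effect, no interaction, no LD: crude estimate within +-0.3 of -2
  cfg <- cohort_config(n_cases = 5000, n_controls = 5000,
                       effect_lnors = c("DQA1*01:02-DQB1*06:02" = -2),
                       interaction_beta = 0, sex_lnor = 0, seed = 21)
  coh <- generate_cohort(cfg)
  carr <- genotype_carriage(coh, "DQA1*01:02-DQB1*06:02")
  est <- crude_ln_or(sum(carr & coh$status == 1), sum(carr & coh$status == 0),
                     sum(!carr & coh$status == 1), sum(!carr & coh$status == 0))
  expect_lt(abs(est - (-2)), 0.3)
})

test_that("KIR carriage is independent of HLA when ld_links is empty, and
           linked when odds multipliers are set", {
  cfg <- null_config(n_cases = 2000, n_controls = 2000, seed = 31)
  coh <- generate_cohort(cfg)
  kir2dl2 <- grepl("KIR2DL2", coh$kir_genes)
  dq6 <- genotype_carriage(coh, "DQA1*01:02-DQB1*06:02")
  p <- stats::chisq.test(table(kir2dl2, dq6))$p.value
  expect_gt(p, 0.001)
  # LD link: B*57:01 enriched in DQ6 carriers
  ld <- data.frame(class1_allele = "B*57:01",
                   class2_genotype = "DQA1*01:02-DQB1*06:02",
                   odds_multiplier = 8)
  cfg_ld <- null_config(n_cases = 2000, n_controls = 2000, seed = 31,
                        ld_links = ld)
  coh_ld <- generate_cohort(cfg_ld)
  b57 <- genotype_carriage(coh_ld, "B*57:01")
  dq6_ld <- genotype_carriage(coh_ld, "DQA1*01:02-DQB1*06:02")
  expect_gt(mean(b57[dq6_ld]), mean(b57[!dq6_ld]))
})

test_that("trios are Mendelian, deterministic, and null-calibrated", {
  cfg <- null_config(seed = 13)
  tr <- generate_trios(cfg, 3)
  expect_equal(nrow(tr), 3)
  # child haplotypes are a union of one haplotype from each parent
  expect_true(all(tr$child_hap1 == ifelse(tr$father_transmitted == 1,
                                          tr$father_hap1, tr$father_hap2)))
  expect_true(all(tr$child_hap2 == ifelse(tr$mother_transmitted == 1,
                                          tr$mother_hap1, tr$mother_hap2)))
  expect_identical(generate_trios(cfg, 3), tr)

  # null model: transmission proportion ~ Binomial(n, 0.5)
  tr_null <- generate_trios(null_config(seed = 41), 400)
  tc <- transmission_counts(tr_null, "DQA1*01:02-DQB1*06:02")
  bt <- stats::binom.test(sum(tc$T), sum(tc$T) + sum(tc$NT), 0.5)
  expect_gt(bt$p.value, 0.001)
})

test_that("cohort files round-trip and malformed rows name their line", {
  coh <- generate_cohort(cohort_config(n_cases = 5, n_controls = 5, seed = 2))
  coh$ikir_score <- NULL; coh$ikir_stratum <- NULL
  path <- tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back, coh, ignore_attr = TRUE)

  # empty cohort -> header-only file
  write_cohort(coh[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_cohort(path)), 0L)

  # three alleles in one locus cell -> parse error with line number
  lines <- readLines(write_cohort(coh, path))
  bad <- sub("A\\*", "A*01:01;A*", lines[3])
  writeLines(c(lines[1:2], bad, lines[4:length(lines)]), path)
  expect_error(read_cohort(path), "line 3")

  # wrong field count
  writeLines(c(lines[1], "only\tthree\tfields"), path)
  expect_error(read_cohort(path), "line 2")
})

test_that("trio PED files round-trip transmissions", {
  tr <- generate_trios(null_config(seed = 5), 20)
  path <- tempfile(fileext = ".ped")
  write_trios(tr, path)
  back <- read_trios(path)
  expect_equal(nrow(back), 20)
  for (g in c("DQA1*01:02-DQB1*06:02", "DQB1*03:01")) {
    expect_equal(transmission_counts(back, g), transmission_counts(tr, g),
                 ignore_attr = TRUE)
  }
})
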