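# Driver screen, effective number of tests and Bonferroni arithmetic.

test_that("pair count and Bonferroni cutoffs match direct arithmetic", {
  expect_equal(n_pairs(21696), 235347360)
  expect_equal(n_pairs(2), 1)
  expect_equal(signif(adjusted_threshold(0.05, 3692), 3), 1.35e-5)
  expect_equal(signif(adjusted_threshold(0.05, 21696), 2), 2.3e-6)
  expect_equal(adjusted_threshold(0.05, 1), 0.05)
})

test_that("genotype enumeration is canonical, deduplicated and filtered", {
  coh <- toy_cohort()
  gen <- enumerate_genotypes(coh, min_carriers = 1)
  expect_false(any(duplicated(gen$label)))
  # canonical labels are sorted, so allele order cannot create duplicates
  lab <- strsplit(gen$label[gen$size > 1], "-", fixed = TRUE)
  expect_true(all(vapply(lab, function(a) identical(a, sort(a)), FALSE)))
  # carriage counts match direct evaluation
  for (i in sample(nrow(gen), 10)) {
    expect_equal(gen$n_carriers[i],
                 sum(genotype_carriage(coh, gen$label[i])),
                 info = gen$label[i])
  }
  # min_carriers filter
  gen5 <- enumerate_genotypes(coh, min_carriers = 5)
  expect_true(all(gen5$n_carriers >= 5))
})

test_that("Meff limits: independence gives m, rank-1 gives 1, hand case gives 2", {
  set.seed(1)
  # identity correlation (orthogonal balanced columns)
  M <- matrix(0, 8, 3)
  M[, 1] <- rep(c(0, 1), 4); M[, 2] <- rep(c(0, 0, 1, 1), 2)
  M[, 3] <- rep(c(0, 1, 1, 0), 2)
  expect_equal(as.numeric(effective_tests(M)), 3, tolerance = 1e-8)
  # all columns identical: rank 1
  M1 <- matrix(rep(rbinom(50, 1, 0.4), 3), 50)
  expect_equal(as.numeric(effective_tests(M1)), 1, tolerance = 1e-8)
  # duplicated pair + independent column: eigenvalues (2, 1, 0) -> Meff = 2
  x <- rep(c(0, 1), 25); y <- rep(c(0, 0, 1, 1), length.out = 50)
  expect_equal(as.numeric(effective_tests(cbind(x, x, y))), 2, tolerance = 1e-8)
  # constant column dropped with warning
  expect_warning(effective_tests(cbind(x, y, rep(1, 50))), "constant")
})

test_that("Meff is invariant to duplicating an existing column", {
  set.seed(7)
  M <- matrix(rbinom(300, 1, 0.5), 100, 3)
  m0 <- as.numeric(effective_tests(M))
  m1 <- as.numeric(effective_tests(cbind(M, M[, 2])))
  expect_equal(m0, m1, tolerance = 1e-6)
})

# simulated screen scenario: one causal protective genotype, an LD
# passenger, independent noise
simulate_screen <- function(n = 1500, n_noise = 30, r_flip = 0.025,
                            beta = -1.2, seed = 1) {
  set.seed(seed)
  causal <- rbinom(n, 1, 0.3)
  flip <- rbinom(n, 1, r_flip) == 1
  passenger <- ifelse(flip, 1 - causal, causal)  # r ~ 0.95
  noise <- matrix(rbinom(n * n_noise, 1, 0.3), n)
  sex <- rbinom(n, 1, 0.5)
  eta <- beta * causal + 0.1 * sex
  status <- rbinom(n, 1, plogis(eta))
  M <- cbind(causal = causal, passenger = passenger, noise)
  colnames(M) <- c("causal", "passenger", paste0("g", seq_len(n_noise)))
  list(status = status, sex = sex, M = M)
}

test_that("screen calls the causal genotype and rejects the LD passenger", {
  sim <- simulate_screen(seed = 3)
  calls <- pairwise_driver_screen(sim$status, sim$sex, sim$M)
  expect_true(calls$is_driver[calls$label == "causal"])
  expect_false(calls$is_driver[calls$label == "passenger"])
  # a driver never records a failing partner
  expect_true(is.na(calls$failing_partner[calls$label == "causal"]))
  expect_false(is.na(calls$failing_partner[calls$label == "passenger"]))
})

test_that("driver status is order-invariant and unaffected by adding
           independent null genotypes", {
  sim <- simulate_screen(n = 1000, n_noise = 10, seed = 5)
  calls <- pairwise_driver_screen(sim$status, sim$sex, sim$M)
  perm <- sample(ncol(sim$M))
  calls_p <- pairwise_driver_screen(sim$status, sim$sex, sim$M[, perm])
  expect_equal(calls$is_driver[match(calls_p$label, calls$label)],
               calls_p$is_driver)
  # subset consistency: extra independent, outcome-unrelated genotype
  set.seed(99)
  extra <- cbind(sim$M, g_extra = rbinom(length(sim$status), 1, 0.4))
  calls_e <- pairwise_driver_screen(sim$status, sim$sex, extra)
  expect_equal(calls_e$is_driver[match(calls$label, calls_e$label)],
               calls$is_driver)
})

test_that("a sign-flipping genotype is excluded by the criterion", {
  # confounder construction: x protective only through its overlap with z
  set.seed(11)
  n <- 4000
  z <- rbinom(n, 1, 0.4)
  x <- ifelse(rbinom(n, 1, 0.85) == 1, z, rbinom(n, 1, 0.4))
  status <- rbinom(n, 1, plogis(-1.5 * z + 0.8 * (x & !z)))
  sex <- rbinom(n, 1, 0.5)
  M <- cbind(z = z, x = x)
  calls <- pairwise_driver_screen(status, sex, M)
  expect_false(calls$is_driver[calls$label == "x"])
})
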