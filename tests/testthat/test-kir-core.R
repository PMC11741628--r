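# Ligand assignment, functional pairs, iKIR score and stratification.

test_that("ligand assignment derives Bw4/C1/C2/A3A11 from allele labels", {
  expect_equal(assign_ligands("B*57:01")$bw4, "Bw4-80I")
  expect_equal(assign_ligands("A*24:02")$bw4, "Bw4-80I")
  # no Bw4, C1-homozygous HLA-C
  lig <- assign_ligands(c("B*07:02", "B*08:01", "C*07:01", "C*07:02"))
  expect_equal(lig$bw4, "absent")
  expect_true(lig$c1); expect_false(lig$c2)
  # heterozygous HLA-C carries both ligand groups
  both <- assign_ligands(c("C*07:01", "C*04:01"))
  expect_true(both$c1 && both$c2)
  # 80I dominates 80T when both motifs present
  expect_equal(assign_ligands(c("B*44:02", "B*57:01"))$bw4, "Bw4-80I")
  expect_error(assign_ligands("B*99:99", unknown = "error"), "not in ligand table")
  expect_equal(assign_ligands("B*99:99")$bw4, "absent")
})

test_that("functional pairs require both receptor gene and ligand", {
  no_c2 <- assign_ligands(c("C*07:01", "C*07:02"))
  expect_equal(nrow(functional_pairs("KIR2DL1", no_c2)), 0)
  with_c2 <- assign_ligands(c("C*04:01", "C*07:01"))
  fp <- functional_pairs("KIR2DL1", with_c2)
  expect_equal(fp$kir, "KIR2DL1"); expect_equal(fp$ligand, "C2")
  fp2 <- functional_pairs(c("KIR3DL1", "KIR2DL3"),
                          assign_ligands(c("B*57:01", "C*01:02")))
  expect_setequal(paste(fp2$kir, fp2$ligand),
                  c("KIR3DL1 Bw4-80I", "KIR2DL3 C1"))
})

test_that("functional pairs match a brute-force rule table over all gene/ligand combos", {
  rules <- list(KIR2DL1 = "c2", KIR2DL2 = "c1", KIR2DL3 = "c1",
                KIR3DL1 = "bw4", KIR3DL2 = "a3a11")
  genes <- c("KIR2DL1", "KIR2DL2", "KIR2DL3", "KIR3DL1", "KIR3DL2")
  for (gene_mask in 0:31) {
    carried <- genes[bitwAnd(gene_mask, 2^(0:4)) > 0]
    for (lmask in 0:15) {
      lig <- structure(list(
        bw4 = if (bitwAnd(lmask, 1) > 0) "Bw4-80I" else "absent",
        c1 = bitwAnd(lmask, 2) > 0, c2 = bitwAnd(lmask, 4) > 0,
        a3a11 = bitwAnd(lmask, 8) > 0), class = "ikir_ligands")
      expected <- vapply(carried, function(g) {
        l <- rules[[g]]
        if (l == "bw4") lig$bw4 != "absent" else isTRUE(lig[[l]])
      }, FALSE)
      got <- functional_pairs(carried, lig, include_kir3dl2 = TRUE)
      expect_setequal(got$kir, carried[expected])
    }
  }
})

test_that("score sums pair weights and reduces to the count for unit weights", {
  w <- ikir_weights()
  expect_equal(as.numeric(ikir_score(data.frame(kir = character(0),
                                                ligand = character(0)), w)), 0)
  pairs <- data.frame(kir = c("KIR2DL1", "KIR3DL1"),
                      ligand = c("C2", "Bw4-80T"))
  expect_equal(as.numeric(ikir_score(pairs, w)), 1.0 + 0.75)  # = 1.75
  # unit weights -> cardinality
  wu <- w; wu$weight <- 1
  pairs3 <- data.frame(kir = c("KIR2DL1", "KIR2DL2", "KIR2DL3"),
                       ligand = c("C2", "C1", "C1"))
  expect_equal(as.numeric(ikir_score(pairs3, wu)), 3)
  expect_error(ikir_score(data.frame(kir = "KIR2DL1", ligand = "C1"), w),
               "no weight")
})

test_that("stratification sends threshold ties to low", {
  expect_equal(stratify(c(1.75, 1.76, 0), 1.75), c("low", "high", "low"))
  expect_true(all(stratify(rep(0, 5), 0.1) == "low"))
})

test_that("cohort-level scoring agrees with the per-individual route and is
           order/duplicate invariant", {
  coh <- toy_cohort()
  scored <- score_cohort(coh)
  w <- ikir_weights()
  for (i in seq_len(nrow(coh))) {
    kir <- strsplit(coh$kir_genes[i], ";")[[1]]
    lig <- assign_ligands(as.character(coh[i, c("A1", "A2", "B1", "B2", "C1", "C2")]))
    expect_equal(scored$ikir_score[i],
                 as.numeric(ikir_score(functional_pairs(kir, lig), w)),
                 info = paste("individual", i))
  }
  # swapping allele order within loci changes nothing
  swapped <- coh
  swapped[, c("C1", "C2")] <- coh[, c("C2", "C1")]
  swapped[, c("B1", "B2")] <- coh[, c("B2", "B1")]
  expect_equal(score_cohort(swapped)$ikir_score, scored$ikir_score)
  # homozygosity (duplicate allele) does not inflate the score
  hom <- coh; hom$C2 <- hom$C1
  hom2 <- coh; hom2$C2 <- hom2$C1; hom2$C1 <- hom2$C1
  expect_equal(score_cohort(hom)$ikir_score, score_cohort(hom2)$ikir_score)
})

test_that("score is monotone in added genes and ligands", {
  coh <- toy_cohort()
  base <- score_cohort(coh)$ikir_score
  more_genes <- coh
  more_genes$kir_genes <- vapply(strsplit(coh$kir_genes, ";"), function(k)
    paste(union(k, "KIR2DL1"), collapse = ";"), "")
  expect_true(all(score_cohort(more_genes)$ikir_score >= base))
  more_lig <- coh; more_lig$C1 <- "C*04:01"  # force C2 carriage
  expect_true(all(score_cohort(more_lig)$ikir_score +
                    1e-12 >= 0))  # still a valid score
  add_b57 <- coh; add_b57$B1 <- "B*57:01"
  expect_true(all(score_cohort(add_b57)$ikir_score >= base - 1e-12))
})
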