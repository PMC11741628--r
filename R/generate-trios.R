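# Synthetic family trios with an affected child.

#' Generate synthetic family trios
#'
#' Parents' phased class II haplotypes and class I alleles are drawn from
#' the population pools in the config. Each child inherits one gamete per
#' parent (no recombination within the HLA region: the class II haplotype
#' and one class I allele per locus travel together); KIR genes, which lie
#' on a different chromosome, are drawn from the population frequencies.
#' The child's disease status follows the same logistic model as
#' [generate_cohort()] and gamete choices plus child-specific covariates
#' are resampled until the child is affected, which is what induces
#' transmission distortion at disease-associated haplotypes.
#'
#' @param config A [cohort_config()].
#' @param n_families Number of trios (>= 1).
#' @param baseline Marginal disease probability the intercept is solved
#'   for (default 0.01, a rare-disease regime: with common diseases the
#'   affected-child ascertainment compresses transmission distortion
#'   because probability ratios, not odds ratios, drive it).
#' @return A data.frame of class `ikir_trios`, one row per family, holding
#'   both parents' phased haplotypes, the index (1 or 2) of each parent's
#'   transmitted haplotype, and the affected child's genotype columns
#'   (`child_hap1` paternal, `child_hap2` maternal) and iKIR score.
#' @examples
#' tr <- generate_trios(cohort_config(seed = 3), n_families = 5)
#' nrow(tr)
#' @export
generate_trios <- function(config, n_families, baseline = 0.01) {
  stopifnot(inherits(config, "cohort_config"), n_families >= 1,
            baseline > 0, baseline < 1)
  set.seed(config$seed)
  base <- .sim_batch(config, 5000L)
  beta0 <- stats::uniroot(function(b0) mean(stats::plogis(b0 + base$.eta)) - baseline,
                          interval = c(-40, 40), tol = 1e-10)$root

  nh <- length(config$class2_haplotypes)
  hnames <- names(config$class2_haplotypes)
  nfam <- as.integer(n_families)
  draw2 <- function(freqs, n) matrix(sample(names(freqs), 2L * n, replace = TRUE,
                                            prob = freqs), n, 2)
  fa_hap <- matrix(hnames[sample.int(nh, 2L * nfam, replace = TRUE,
                                     prob = config$class2_haplotypes)], nfam, 2)
  mo_hap <- matrix(hnames[sample.int(nh, 2L * nfam, replace = TRUE,
                                     prob = config$class2_haplotypes)], nfam, 2)
  fa_A <- draw2(config$class1_freqs$A, nfam); mo_A <- draw2(config$class1_freqs$A, nfam)
  fa_B <- draw2(config$class1_freqs$B, nfam); mo_B <- draw2(config$class1_freqs$B, nfam)
  fa_C <- draw2(config$class1_freqs$C, nfam); mo_C <- draw2(config$class1_freqs$C, nfam)

  kirnames <- names(config$kir_gene_freqs)
  out <- data.frame(
    family_id = sprintf("F%04d", seq_len(nfam)),
    father_hap1 = fa_hap[, 1], father_hap2 = fa_hap[, 2],
    father_transmitted = NA_integer_,
    mother_hap1 = mo_hap[, 1], mother_hap2 = mo_hap[, 2],
    mother_transmitted = NA_integer_,
    child_sex = NA_character_, child_kir_genes = NA_character_,
    child_A1 = NA_character_, child_A2 = NA_character_,
    child_B1 = NA_character_, child_B2 = NA_character_,
    child_C1 = NA_character_, child_C2 = NA_character_,
    child_hap1 = NA_character_, child_hap2 = NA_character_,
    child_ikir_score = NA_real_, stringsAsFactors = FALSE)

  # candidate children for all unfinished families in one vectorised batch;
  # repeat until every family has an affected child
  # batch grows geometrically so strongly protected families (tiny
  # acceptance probability) still finish
  m <- as.integer(min(256L, max(16L, ceiling(2 / baseline))))
  unfinished <- seq_len(nfam)
  guard <- 0L
  while (length(unfinished)) {
    guard <- guard + 1L
    if (guard > 60L) stop("trio rejection sampling failed; check config")
    if (guard > 1L) m <- min(8192L, m * 2L)
    fidx <- rep(unfinished, each = m)
    nr <- length(fidx)
    ftv <- sample.int(2L, nr, replace = TRUE)
    mtv <- sample.int(2L, nr, replace = TRUE)
    kirdraw <- matrix(stats::runif(nr * length(kirnames)), nr) <
      matrix(config$kir_gene_freqs, nr, length(kirnames), byrow = TRUE)
    colnames(kirdraw) <- kirnames
    sexv <- ifelse(stats::runif(nr) < config$sex_ratio, "F", "M")
    hap1 <- fa_hap[cbind(fidx, ftv)]; hap2 <- mo_hap[cbind(fidx, mtv)]
    h1 <- do.call(rbind, strsplit(hap1, "~", fixed = TRUE))
    h2 <- do.call(rbind, strsplit(hap2, "~", fixed = TRUE))
    class1 <- cbind(fa_A[cbind(fidx, ftv)], mo_A[cbind(fidx, mtv)],
                    fa_B[cbind(fidx, ftv)], mo_B[cbind(fidx, mtv)],
                    fa_C[cbind(fidx, ftv)], mo_C[cbind(fidx, mtv)])
    allele_cols <- cbind(class1, h1, h2)
    score <- .score_parts(kirdraw[, IKIR_GENES, drop = FALSE], class1,
                          config$weights, ligand_table(),
                          config$include_kir3dl2)
    carr_of <- function(label) {
      alleles <- parse_genotype_label(label)
      ok <- rep(TRUE, nr)
      for (a in alleles) ok <- ok & (rowSums(allele_cols == a) > 0)
      ok
    }
    eta <- rep(0, nr)
    for (gl in names(config$effect_lnors)) {
      carr <- carr_of(gl)
      eta <- eta + config$effect_lnors[[gl]] * carr
      if (gl %in% config$interaction_genotypes)
        eta <- eta + config$interaction_beta * score * carr
    }
    eta <- eta + config$sex_lnor * (sexv == "M")
    hit <- stats::runif(nr) < stats::plogis(beta0 + eta)
    first <- tapply(seq_len(nr)[hit], fidx[hit], min)
    for (k in seq_along(first)) {
      f <- as.integer(names(first)[k]); i <- first[[k]]
      out$father_transmitted[f] <- ftv[i]
      out$mother_transmitted[f] <- mtv[i]
      out$child_sex[f] <- sexv[i]
      out$child_kir_genes[f] <- paste(kirnames[kirdraw[i, ]], collapse = ";")
      out$child_A1[f] <- class1[i, 1]; out$child_A2[f] <- class1[i, 2]
      out$child_B1[f] <- class1[i, 3]; out$child_B2[f] <- class1[i, 4]
      out$child_C1[f] <- class1[i, 5]; out$child_C2[f] <- class1[i, 6]
      out$child_hap1[f] <- hap1[i]; out$child_hap2[f] <- hap2[i]
      out$child_ikir_score[f] <- score[i]
    }
    unfinished <- which(is.na(out$father_transmitted))
  }
  class(out) <- c("ikir_trios", "data.frame")
  out
}

# Cohort-shaped frame for the affected children (used for carriage weights)
trios_child_frame <- function(trios) {
  split2 <- function(s, i) vapply(strsplit(s, "~", fixed = TRUE), `[`, "", i)
  data.frame(
    id = trios$family_id, status = 1L, sex = trios$child_sex,
    kir_genes = trios$child_kir_genes,
    A1 = trios$child_A1, A2 = trios$child_A2,
    B1 = trios$child_B1, B2 = trios$child_B2,
    C1 = trios$child_C1, C2 = trios$child_C2,
    DRB1_1 = split2(trios$child_hap1, 1), DRB1_2 = split2(trios$child_hap2, 1),
    DQA1_1 = split2(trios$child_hap1, 2), DQA1_2 = split2(trios$child_hap2, 2),
    DQB1_1 = split2(trios$child_hap1, 3), DQB1_2 = split2(trios$child_hap2, 3),
    hap1 = trios$child_hap1, hap2 = trios$child_hap2,
    stringsAsFactors = FALSE)
}
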