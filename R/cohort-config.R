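#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model a synthetic case-control cohort is drawn
#' from: a class II haplotype pool (two independent draws per individual,
#' phase kept explicit), per-locus HLA class I allele frequencies, KIR gene
#' carriage frequencies (KIR and HLA lie on different chromosomes, so KIR
#' genes are drawn independently of HLA unless `ld_links` says otherwise),
#' and a logistic disease model
#' \deqn{logit P(case) = \beta_0 + \sum_g \beta_g G_g +
#'   \beta_{int} \cdot score \cdot G_{prot} + \beta_{sex} \cdot male}
#' where \eqn{G_g} are dominant genotype-carriage indicators and
#' \eqn{score} is the individual's iKIR score computed from the generated
#' KIR and class I genes. The intercept \eqn{\beta_0} is solved numerically
#' so the marginal case probability matches `n_cases / (n_cases +
#' n_controls)`, and case/control quotas are then filled by rejection
#' sampling (case-control, not prospective, sampling).
#'
#' Defaults emulate European-typical gene frequencies and mid-range
#' published class II effect sizes, with a protective DQ6-like genotype
#' whose protection is weakened by the iKIR score at rate
#' `interaction_beta` (default 0.9 ln-odds per score unit).
#'
#' @param n_cases,n_controls Cohort composition.
#' @param class2_haplotypes Named numeric: class II haplotype pool
#'   (names are `~`-joined DRB1/DQA1/DQB1 allele strings) with sampling
#'   frequencies; renormalised to sum to 1.
#' @param class1_freqs List with named numeric elements `A`, `B`, `C`:
#'   allele frequencies per class I locus.
#' @param kir_gene_freqs Named numeric: carriage probability per KIR gene.
#' @param effect_lnors Named numeric: ln-odds of case status per carried
#'   genotype label (dominant coding). Every label must be attainable from
#'   the configured haplotype pool.
#' @param interaction_beta ln-odds per unit iKIR score per carried
#'   interaction genotype.
#' @param interaction_genotypes Labels the interaction applies to; default
#'   the DQ6-like protective genotype.
#' @param ld_links Data.frame with columns `class1_allele`,
#'   `class2_genotype`, `odds_multiplier` (> 0): for carriers of the class
#'   II genotype the sampling odds of the class I allele are multiplied,
#'   injecting class I / class II linkage at the genotype level.
#' @param sex_ratio Probability of being female.
#' @param sex_lnor ln-odds for males relative to females.
#' @param threshold,weights,include_kir3dl2 iKIR score settings used inside
#'   the generative model.
#' @param seed Integer seed; generation is reproducible for a fixed config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 1000, n_controls = 1000,
                          class2_haplotypes = default_class2_haplotypes(),
                          class1_freqs = default_class1_freqs(),
                          kir_gene_freqs = default_kir_freqs(),
                          effect_lnors = default_effect_lnors(),
                          interaction_beta = 0.9,
                          interaction_genotypes = "DQA1*01:02-DQB1*06:02",
                          ld_links = NULL,
                          sex_ratio = 0.5, sex_lnor = 0.1,
                          threshold = 1.75,
                          weights = ikir_weights(),
                          include_kir3dl2 = FALSE,
                          seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_cases + n_controls > 0)
  stopifnot(all(class2_haplotypes >= 0), sum(class2_haplotypes) > 0)
  stopifnot(all(unlist(class1_freqs) >= 0))
  stopifnot(all(kir_gene_freqs >= 0 & kir_gene_freqs <= 1))
  stopifnot(sex_ratio >= 0, sex_ratio <= 1)
  if (anyDuplicated(names(effect_lnors)))
    stop("configuration error: duplicate genotype labels in effect_lnors")
  class2_haplotypes <- class2_haplotypes / sum(class2_haplotypes)
  class1_freqs <- lapply(class1_freqs, function(f) f / sum(f))
  cfg <- structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    class2_haplotypes = class2_haplotypes, class1_freqs = class1_freqs,
    kir_gene_freqs = kir_gene_freqs, effect_lnors = effect_lnors,
    interaction_beta = interaction_beta,
    interaction_genotypes = interaction_genotypes,
    ld_links = ld_links, sex_ratio = sex_ratio, sex_lnor = sex_lnor,
    threshold = threshold, weights = weights,
    include_kir3dl2 = include_kir3dl2, seed = as.integer(seed)),
    class = "cohort_config")
  # every effect label must be realisable from the haplotype pool
  probs <- induced_carriage_probs(cfg)
  dead <- names(probs)[probs <= 0]
  if (length(dead))
    stop("configuration error: genotype label(s) unattainable from the ",
         "haplotype pool: ", paste(dead, collapse = ", "))
  if (length(interaction_genotypes) &&
      !all(interaction_genotypes %in% names(effect_lnors)))
    stop("configuration error: interaction_genotypes must be labels of effect_lnors")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration:",
      x$n_cases, "cases /", x$n_controls, "controls\n")
  cat("  genotype effects (lnOR):\n")
  for (g in names(x$effect_lnors))
    cat(sprintf("    %-35s % .2f\n", g, x$effect_lnors[[g]]))
  cat("  interaction beta:", x$interaction_beta, "on",
      paste(x$interaction_genotypes, collapse = ", "), "\n")
  cat("  score threshold:", x$threshold,
      "| weights:", attr(x$weights, "id"), "| seed:", x$seed, "\n")
  invisible(x)
}

#' @rdname cohort_config
#' @export
default_class2_haplotypes <- function() {
  c("DRB1*15:01~DQA1*01:02~DQB1*06:02" = 0.13,
    "DRB1*03:01~DQA1*05:01~DQB1*02:01" = 0.12,
    "DRB1*04:01~DQA1*03:01~DQB1*03:02" = 0.07,
    "DRB1*07:01~DQA1*02:01~DQB1*02:02" = 0.11,
    "DRB1*01:01~DQA1*01:01~DQB1*05:01" = 0.09,
    "DRB1*11:01~DQA1*05:05~DQB1*03:01" = 0.08,
    "DRB1*13:01~DQA1*01:03~DQB1*06:03" = 0.06,
    "DRB1*13:02~DQA1*01:02~DQB1*06:04" = 0.03,
    "DRB1*08:01~DQA1*04:01~DQB1*04:02" = 0.03,
    "DRB1*12:01~DQA1*05:05~DQB1*03:01" = 0.03,
    "DRB1*14:01~DQA1*01:04~DQB1*05:03" = 0.03,
    "DRB1*09:01~DQA1*03:02~DQB1*03:03" = 0.02,
    "DRB1*10:01~DQA1*01:05~DQB1*05:01" = 0.02,
    "DRB1*04:04~DQA1*03:01~DQB1*03:02" = 0.03,
    "DRB1*16:01~DQA1*01:02~DQB1*05:02" = 0.02,
    "DRB1*07:01~DQA1*02:01~DQB1*03:03" = 0.03,
    "DRB1*11:04~DQA1*05:05~DQB1*03:01" = 0.04,
    "DRB1*13:03~DQA1*05:05~DQB1*03:01" = 0.02,
    "DRB1*04:02~DQA1*03:01~DQB1*03:02" = 0.02,
    "DRB1*15:02~DQA1*01:03~DQB1*06:01" = 0.02)
}

#' @rdname cohort_config
#' @export
default_class1_freqs <- function() {
  list(
    A = c("A*01:01" = 0.16, "A*02:01" = 0.27, "A*03:01" = 0.13,
          "A*11:01" = 0.06, "A*24:02" = 0.09, "A*23:01" = 0.02,
          "A*32:01" = 0.03, "A*26:01" = 0.03, "A*68:01" = 0.04,
          "A*29:02" = 0.03, "A*31:01" = 0.03, "A*25:01" = 0.02,
          "A*30:01" = 0.02, "A*33:01" = 0.02, "A*66:01" = 0.05),
    B = c("B*07:02" = 0.13, "B*08:01" = 0.12, "B*44:02" = 0.09,
          "B*44:03" = 0.05, "B*15:01" = 0.06, "B*35:01" = 0.06,
          "B*57:01" = 0.04, "B*18:01" = 0.04, "B*27:05" = 0.04,
          "B*51:01" = 0.05, "B*40:01" = 0.05, "B*13:02" = 0.03,
          "B*14:02" = 0.03, "B*38:01" = 0.02, "B*49:01" = 0.02,
          "B*52:01" = 0.01, "B*53:01" = 0.01, "B*37:01" = 0.01,
          "B*55:01" = 0.02, "B*58:01" = 0.01, "B*39:01" = 0.11),
    C = c("C*07:01" = 0.15, "C*07:02" = 0.15, "C*04:01" = 0.12,
          "C*03:04" = 0.08, "C*05:01" = 0.08, "C*06:02" = 0.09,
          "C*03:03" = 0.05, "C*12:03" = 0.06, "C*02:02" = 0.05,
          "C*01:02" = 0.04, "C*08:02" = 0.04, "C*16:01" = 0.04,
          "C*15:02" = 0.03, "C*14:02" = 0.02))
}

#' @rdname cohort_config
#' @export
default_kir_freqs <- function() {
  c(KIR2DL1 = 0.97, KIR2DL2 = 0.55, KIR2DL3 = 0.89,
    KIR3DL1 = 0.95, KIR3DL2 = 1.00)
}

#' @rdname cohort_config
#' @export
default_effect_lnors <- function() {
  c("DQA1*01:02-DQB1*06:02" = -4.5,
    "DQB1*03:01" = -1.25,
    "DQA1*02:01" = -1.15,
    "DRB1*03:01-DQB1*02:01" = 1.0,
    "DQB1*03:02" = 1.2)
}

#' Exact carriage probabilities induced by the haplotype pool
#'
#' For each genotype label in `effect_lnors`, computes the probability that
#' an individual formed from two independent haplotype draws carries all of
#' the label's class II alleles (in cis or in trans). Class I alleles in a
#' label get carriage `1 - (1 - q)^2` from the per-locus frequency `q`
#' (ignoring `ld_links`). Used for configuration validation and as
#' permutation weights on synthetic data.
#'
#' @param config A `cohort_config`.
#' @param labels Labels to evaluate (default: names of `effect_lnors`).
#' @return Named numeric vector of carriage probabilities.
#' @export
induced_carriage_probs <- function(config, labels = names(config$effect_lnors)) {
  haps <- strsplit(names(config$class2_haplotypes), "~", fixed = TRUE)
  freqs <- unname(config$class2_haplotypes)
  nh <- length(haps)
  class1_all <- unlist(lapply(config$class1_freqs, names))
  out <- vapply(labels, function(label) {
    alleles <- parse_genotype_label(label)
    is1 <- alleles %in% class1_all
    p <- 1
    for (a in alleles[is1]) {
      loc <- allele_locus(a)
      q <- config$class1_freqs[[loc]][a]
      if (is.na(q)) return(0)
      p <- p * (1 - (1 - q)^2)
    }
    a2 <- alleles[!is1]
    if (length(a2)) {
      pc <- 0
      for (i in seq_len(nh)) for (j in seq_len(nh)) {
        if (all(a2 %in% c(haps[[i]], haps[[j]])))
          pc <- pc + freqs[i] * freqs[j]
      }
      p <- p * pc
    }
    p
  }, 0)
  names(out) <- labels
  out
}
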