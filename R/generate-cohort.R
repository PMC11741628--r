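# Synthetic case-control cohort generation under a logistic disease model.

# Draw n individuals' genotypes and covariates (no disease status yet).
# Returns a cohort-shaped data.frame plus the linear predictor without
# intercept (column .eta) and the iKIR score (column ikir_score).
.sim_batch <- function(config, n) {
  nh <- length(config$class2_haplotypes)
  hnames <- names(config$class2_haplotypes)
  i1 <- sample.int(nh, n, replace = TRUE, prob = config$class2_haplotypes)
  i2 <- sample.int(nh, n, replace = TRUE, prob = config$class2_haplotypes)
  haps <- strsplit(hnames, "~", fixed = TRUE)
  hmat <- do.call(rbind, haps)  # nh x 3: DRB1, DQA1, DQB1
  df <- data.frame(
    id = NA_character_, status = NA_integer_,
    sex = ifelse(stats::runif(n) < config$sex_ratio, "F", "M"),
    kir_genes = NA_character_, stringsAsFactors = FALSE)
  kirdraw <- sapply(names(config$kir_gene_freqs), function(g)
    stats::runif(n) < config$kir_gene_freqs[[g]])
  if (n == 1) kirdraw <- matrix(kirdraw, nrow = 1,
                                dimnames = list(NULL, names(config$kir_gene_freqs)))
  df$kir_genes <- apply(kirdraw, 1, function(r)
    paste(colnames(kirdraw)[r], collapse = ";"))
  df$DRB1_1 <- hmat[i1, 1]; df$DRB1_2 <- hmat[i2, 1]
  df$DQA1_1 <- hmat[i1, 2]; df$DQA1_2 <- hmat[i2, 2]
  df$DQB1_1 <- hmat[i1, 3]; df$DQB1_2 <- hmat[i2, 3]
  df$hap1 <- hnames[i1]; df$hap2 <- hnames[i2]
  # class I draws, with optional genotype-conditional odds multipliers
  for (loc in c("A", "B", "C")) {
    fr <- config$class1_freqs[[loc]]
    k <- length(fr)
    links <- NULL
    if (!is.null(config$ld_links)) {
      links <- config$ld_links[allele_locus(config$ld_links$class1_allele) == loc, ,
                               drop = FALSE]
      if (nrow(links) == 0) links <- NULL
    }
    if (is.null(links)) {
      a1 <- sample(names(fr), n, replace = TRUE, prob = fr)
      a2 <- sample(names(fr), n, replace = TRUE, prob = fr)
    } else {
      W <- matrix(fr, nrow = n, ncol = k, byrow = TRUE,
                  dimnames = list(NULL, names(fr)))
      for (j in seq_len(nrow(links))) {
        carr <- .class2_carriage_batch(df, links$class2_genotype[j])
        W[carr, links$class1_allele[j]] <-
          W[carr, links$class1_allele[j]] * links$odds_multiplier[j]
      }
      cw <- W / rowSums(W)
      cum <- t(apply(cw, 1, cumsum))
      pick <- function(u) colnames(W)[max.col(cum >= u, ties.method = "first")]
      a1 <- pick(stats::runif(n)); a2 <- pick(stats::runif(n))
    }
    df[[paste0(loc, "1")]] <- a1
    df[[paste0(loc, "2")]] <- a2
  }
  df <- df[, c("id", "status", "sex", "kir_genes", CLASS1_COLS, CLASS2_COLS,
               "hap1", "hap2")]
  df <- score_cohort(df, weights = config$weights, threshold = config$threshold,
                     include_kir3dl2 = config$include_kir3dl2)
  cmat <- carriage_matrix(df, names(config$effect_lnors))
  eta <- drop(cmat %*% config$effect_lnors)
  if (length(config$interaction_genotypes)) {
    gi <- rowSums(cmat[, config$interaction_genotypes, drop = FALSE])
    eta <- eta + config$interaction_beta * df$ikir_score * gi
  }
  eta <- eta + config$sex_lnor * (df$sex == "M")
  df$.eta <- eta
  df
}

# class II carriage on a partially built batch (class I columns may be absent)
.class2_carriage_batch <- function(df, label) {
  alleles <- parse_genotype_label(label)
  cols <- as.matrix(df[, intersect(c(CLASS1_COLS, CLASS2_COLS), names(df))])
  out <- rep(TRUE, nrow(df))
  for (a in alleles) out <- out & (rowSums(cols == a, na.rm = TRUE) > 0)
  out
}

#' Generate a synthetic case-control cohort
#'
#' Draws individuals from the generative model in [cohort_config()] and
#' fills the case and control quotas by rejection sampling. The intercept
#' of the disease model is solved numerically (on a large covariate batch)
#' so that the marginal case probability matches the requested case
#' fraction. KIR genes are drawn independently of HLA; class I / class II
#' dependence is injected only through `ld_links`.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with one row per individual and the standard cohort
#'   columns (`id, status, sex, kir_genes, A1..C2, DRB1_1..DQB1_2, hap1,
#'   hap2`) plus computed `ikir_score` and `ikir_stratum`. Attribute
#'   `beta0` records the solved intercept.
#' @examples
#' cfg <- cohort_config(n_cases = 50, n_controls = 50, seed = 7)
#' coh <- generate_cohort(cfg)
#' table(coh$status)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_target <- config$n_cases + config$n_controls
  pi_target <- config$n_cases / n_target
  batch_n <- max(5000L, ceiling(1.5 * n_target))
  first <- .sim_batch(config, batch_n)
  beta0 <- if (pi_target == 0) -Inf else if (pi_target == 1) Inf else
    stats::uniroot(function(b0) mean(stats::plogis(b0 + first$.eta)) - pi_target,
                   interval = c(-40, 40), tol = 1e-10)$root
  cases <- list(); controls <- list()
  n_cases_have <- 0L; n_controls_have <- 0L
  batch <- first
  guard <- 0L
  repeat {
    p <- stats::plogis(beta0 + batch$.eta)
    st <- as.integer(stats::runif(nrow(batch)) < p)
    if (n_cases_have < config$n_cases) {
      take <- which(st == 1L)[seq_len(min(sum(st == 1L), config$n_cases - n_cases_have))]
      if (length(take)) {
        b <- batch[take, ]; b$status <- 1L
        cases[[length(cases) + 1L]] <- b
        n_cases_have <- n_cases_have + length(take)
      }
    }
    if (n_controls_have < config$n_controls) {
      take <- which(st == 0L)[seq_len(min(sum(st == 0L), config$n_controls - n_controls_have))]
      if (length(take)) {
        b <- batch[take, ]; b$status <- 0L
        controls[[length(controls) + 1L]] <- b
        n_controls_have <- n_controls_have + length(take)
      }
    }
    if (n_cases_have >= config$n_cases && n_controls_have >= config$n_controls) break
    guard <- guard + 1L
    if (guard > 1000L) stop("rejection sampling failed to fill quotas; check config")
    batch <- .sim_batch(config, batch_n)
  }
  out <- do.call(rbind, c(cases, controls))
  out <- out[sample.int(nrow(out)), ]
  out$.eta <- NULL
  out$id <- sprintf("S%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "beta0") <- beta0
  attr(out, "weights_id") <- attr(config$weights, "id")
  out
}
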