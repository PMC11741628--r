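# Logistic association analysis: crude ln[OR]s, covariate-adjusted fits,
# stratified effects, interaction (dose) models and resampling power.

#' Crude ln odds ratio from a 2x2 carriage-by-status table
#'
#' @param a Genotype-positive cases.
#' @param b Genotype-positive controls.
#' @param c Genotype-negative cases.
#' @param d Genotype-negative controls.
#' @param continuity `"error"` (default: any zero cell is an error) or
#'   `"haldane"` (add 0.5 to every cell when any cell is zero; changes the
#'   estimate, so it must be requested explicitly).
#' @return `ln((a d) / (b c))`.
#' @examples
#' crude_ln_or(26, 729, 2984, 1681)  # -3.91
#' @export
crude_ln_or <- function(a, b, c, d, continuity = c("error", "haldane")) {
  continuity <- match.arg(continuity)
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  if (any(cells == 0)) {
    if (continuity == "error")
      stop("zero cell in 2x2 table; set continuity = \"haldane\" to add 0.5")
    cells <- cells + 0.5
  }
  log((cells[1] * cells[4]) / (cells[2] * cells[3]))
}

# Wald results for every term of a fitted binomial glm
.wald_results <- function(fit, stratum = NA_character_) {
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  data.frame(term = rownames(sm), ln_or = sm[, 1],
             ci_low = sm[, 1] - z * sm[, 2], ci_high = sm[, 1] + z * sm[, 2],
             p_value = sm[, 4], stratum = stratum,
             row.names = NULL, stringsAsFactors = FALSE)
}

.check_separation <- function(fit) {
  eps <- 1e-8
  mu <- stats::fitted(fit)
  if (!fit$converged || any(abs(stats::coef(fit)) > 15) ||
      all(mu < eps | mu > 1 - eps))
    stop("(near-)perfect separation in logistic fit; estimates unreliable")
  invisible(fit)
}

#' Maximum-likelihood logistic association fit
#'
#' Fits `status ~ predictors` by ML logistic regression and returns Wald
#' estimates, 95% CIs and p-values per term, plus the model AIC and
#' log-likelihood. With a single binary predictor and no covariates the
#' coefficient equals the crude 2x2 ln[OR] exactly.
#'
#' @param status Integer 0/1 outcome vector.
#' @param predictors Data.frame of predictors (numeric, logical or factor).
#' @param check_separation Raise an error on (near-)perfect separation
#'   instead of returning silently diverged estimates. Default `TRUE`.
#' @return A data.frame of per-term results with attributes `aic`,
#'   `loglik`, `formula` and `n`.
#' @export
fit_logistic <- function(status, predictors, check_separation = TRUE) {
  stopifnot(length(unique(status[!is.na(status)])) >= 1)
  if (!any(status == 1) || !any(status == 0))
    stop("need at least one case and one control")
  df <- cbind(data.frame(.y = status), predictors)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  if (check_separation) .check_separation(fit)
  out <- .wald_results(fit)
  attr(out, "aic") <- stats::AIC(fit)
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  attr(out, "formula") <- paste("status ~", paste(names(predictors), collapse = " + "))
  attr(out, "n") <- nrow(df)
  out
}

# Four-cell genotype-by-status counts, always summing to the analysed n
.cell_counts <- function(carriage, status) {
  c(n_gpos_case = sum(carriage & status == 1),
    n_gpos_ctrl = sum(carriage & status == 0),
    n_gneg_case = sum(!carriage & status == 1),
    n_gneg_ctrl = sum(!carriage & status == 0))
}

#' Stratified genotype effect across iKIR score strata
#'
#' Splits the cohort at an iKIR score threshold and fits the genotype
#' effect independently in each stratum by sex-adjusted logistic
#' regression (optionally also adjusting for the Bw4/C1/C2 ligand
#' carriage). Genotypes carried by fewer than `min_case_carriers` cases in
#' the whole cohort are skipped, since such strata are too sparse to
#' stratify.
#'
#' @param cohort Scored cohort (see [score_cohort()]; scored on the fly if
#'   the `ikir_score` column is absent).
#' @param genotype Genotype label.
#' @param threshold iKIR score threshold.
#' @param adjust_ligands Add Bw4/C1/C2 carriage covariates.
#' @param min_case_carriers Skip filter (default 10 case carriers).
#' @param phase Carriage phase mode, see [genotype_carriage()].
#' @return A list with elements `high`, `low` and `whole`, each a one-row
#'   result for the genotype term with `n_by_cell` counts attached, or an
#'   object of class `ikir_skipped` when the filter rejects the genotype.
#' @export
stratified_effect <- function(cohort, genotype, threshold = 1.75,
                              adjust_ligands = FALSE, min_case_carriers = 10,
                              phase = "either") {
  if (!"ikir_score" %in% names(cohort)) cohort <- score_cohort(cohort)
  carr <- genotype_carriage(cohort, genotype, phase)
  n_case_carriers <- sum(carr & cohort$status == 1)
  if (n_case_carriers < min_case_carriers) {
    message("genotype ", genotype, " skipped: ", n_case_carriers,
            " case carriers < ", min_case_carriers)
    return(structure(list(genotype = genotype,
                          reason = sprintf("%d case carriers < %d",
                                           n_case_carriers, min_case_carriers)),
                     class = "ikir_skipped"))
  }
  stratum <- stratify(cohort$ikir_score, threshold)
  fit_one <- function(idx, label) {
    preds <- data.frame(genotype = as.integer(carr[idx]),
                        sex = as.integer(cohort$sex[idx] == "M"))
    if (adjust_ligands) {
      lig <- .cohort_ligand_flags(cohort[idx, ])
      preds <- cbind(preds, lig)
    }
    res <- fit_logistic(cohort$status[idx], preds)
    row <- res[res$term == "genotype", ]
    row$stratum <- label
    attr(row, "n_by_cell") <- .cell_counts(carr[idx], cohort$status[idx])
    row
  }
  list(high = fit_one(stratum == "high", "high"),
       low = fit_one(stratum == "low", "low"),
       whole = fit_one(rep(TRUE, nrow(cohort)), "whole"))
}

.cohort_ligand_flags <- function(cohort, table = ligand_table()) {
  class1 <- as.matrix(cohort[, CLASS1_COLS])
  grp <- matrix(table$group[match(class1, table$allele)], nrow = nrow(cohort))
  has <- function(g) rowSums(grp == g, na.rm = TRUE) > 0
  data.frame(bw4 = as.integer(has("Bw4-80I") | has("Bw4-80T")),
             c1 = as.integer(has("C1")), c2 = as.integer(has("C2")))
}

#' Genotype-by-iKIR-score interaction (dose) model
#'
#' Whole-cohort model `status ~ genotype * score + sex` with the iKIR
#' score entered either as a continuous variable or as the binary
#' high/low stratum indicator. Reports the interaction term and the model
#' AIC (`2k - 2 logLik`) so that the continuous and stratified codings,
#' or score versus count, can be compared.
#'
#' @inheritParams stratified_effect
#' @param score_mode `"continuous"` or `"stratified"`.
#' @param score Optional replacement score vector (e.g. the unweighted
#'   functional iKIR count).
#' @return One-row data.frame for the interaction term with attributes
#'   `aic`, `loglik`, `n`.
#' @export
interaction_model <- function(cohort, genotype, threshold = 1.75,
                              score_mode = c("continuous", "stratified"),
                              score = NULL, phase = "either") {
  score_mode <- match.arg(score_mode)
  if (!"ikir_score" %in% names(cohort)) cohort <- score_cohort(cohort)
  if (is.null(score)) score <- cohort$ikir_score
  sc <- if (score_mode == "continuous") score
        else as.integer(stratify(score, threshold) == "high")
  carr <- as.integer(genotype_carriage(cohort, genotype, phase))
  df <- data.frame(.y = cohort$status, genotype = carr, score = sc,
                   sex = as.integer(cohort$sex == "M"))
  fit <- stats::glm(.y ~ genotype * score + sex, data = df,
                    family = stats::binomial())
  .check_separation(fit)
  out <- .wald_results(fit)
  out <- out[out$term == "genotype:score", ]
  attr(out, "aic") <- stats::AIC(fit)
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  attr(out, "n") <- nrow(df)
  out
}

#' Power analysis by resampling with replacement
#'
#' For each target sample size `s` draws `n_boot` subcohorts of `s/2`
#' cases and `s/2` controls (with replacement) from the base cohort and
#' estimates power as the fraction of subcohorts in which the
#' genotype-by-score interaction is significant at `alpha` (single
#' genotype) or the weighted multi-genotype permutation test rejects
#' (several genotypes).
#'
#' @param cohort Scored cohort.
#' @param genotypes One or more genotype labels.
#' @param sample_sizes Even total sample sizes to evaluate.
#' @param n_boot Subcohorts per sample size.
#' @param alpha Significance level.
#' @param threshold iKIR score threshold.
#' @param n_perm Permutations for the multi-genotype test.
#' @param seed Integer seed.
#' @return Data.frame with columns `s` and `power`.
#' @export
power_by_resampling <- function(cohort, genotypes, sample_sizes, n_boot = 1000,
                                alpha = 0.05, threshold = 1.75, n_perm = 200,
                                seed = 1L) {
  stopifnot(all(sample_sizes %% 2 == 0))
  if (!"ikir_score" %in% names(cohort)) cohort <- score_cohort(cohort)
  set.seed(seed)
  case_idx <- which(cohort$status == 1); ctrl_idx <- which(cohort$status == 0)
  single <- length(genotypes) == 1
  power <- vapply(sample_sizes, function(s) {
    hits <- 0L
    for (b in seq_len(n_boot)) {
      idx <- c(sample(case_idx, s / 2, replace = TRUE),
               sample(ctrl_idx, s / 2, replace = TRUE))
      sub <- cohort[idx, ]
      p <- tryCatch({
        if (single) {
          interaction_model(sub, genotypes, threshold)$p_value
        } else {
          permutation_test(sub, genotypes, threshold = threshold,
                           n_perm = n_perm, seed = sample.int(2^30, 1))$p_value
        }
      }, error = function(e) NA_real_)
      if (!is.na(p) && p < alpha) hits <- hits + 1L
    }
    hits / n_boot
  }, 0)
  data.frame(s = sample_sizes, power = power)
}
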