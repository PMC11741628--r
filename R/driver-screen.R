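# Exhaustive pairwise co-regression screen for driver genotypes, with the
# effective number of tests for Bonferroni adjustment.

#' Number of unordered genotype pairs
#'
#' @param m Number of genotypes.
#' @return `m (m - 1) / 2`.
#' @examples
#' n_pairs(21696)
#' @export
n_pairs <- function(m) {
  m <- as.numeric(m)
  m * (m - 1) / 2
}

#' Enumerate candidate HLA genotypes in a cohort
#'
#' Builds the deduplicated list of single HLA class I alleles, single class
#' II alleles and two- and three-allele class II genotypes (DRB1 / DQA1 /
#' DQB1, in cis or in trans) actually carried in the cohort, with carriage
#' counts. Multi-allele combinations are enumerated from each individual's
#' own allele set, so only carried combinations are produced; labels are
#' canonical (sorted, order-invariant).
#'
#' @param cohort Cohort data.frame.
#' @param max_size Largest class II allele combination (1-3).
#' @param min_carriers Exclude genotypes carried by fewer individuals.
#' @return Data.frame with columns `label`, `n_carriers`, `size`, `class`
#'   (`"I"` or `"II"`), sorted by label.
#' @export
enumerate_genotypes <- function(cohort, max_size = 3, min_carriers = 10) {
  stopifnot(max_size >= 1, max_size <= 3)
  class1 <- unlist(cohort[, CLASS1_COLS])
  t1 <- table(unlist(lapply(seq_len(nrow(cohort)), function(i)
    unique(as.character(cohort[i, CLASS1_COLS])))))
  combos <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cohort))) {
    al <- sort(unique(as.character(cohort[i, CLASS2_COLS])))
    al <- al[nzchar(al) & !is.na(al)]
    for (s in seq_len(min(max_size, length(al)))) {
      cm <- utils::combn(al, s)
      for (k in seq_len(ncol(cm))) {
        lab <- paste(cm[, k], collapse = "-")
        combos[[lab]] <- (if (is.null(combos[[lab]])) 0L else combos[[lab]]) + 1L
      }
    }
  }
  labs2 <- ls(combos)
  out <- rbind(
    data.frame(label = names(t1), n_carriers = as.integer(t1),
               size = 1L, class = "I", stringsAsFactors = FALSE),
    data.frame(label = labs2,
               n_carriers = vapply(labs2, function(l) combos[[l]], 0L),
               size = lengths(strsplit(labs2, "-", fixed = TRUE)),
               class = "II", stringsAsFactors = FALSE))
  out <- out[out$n_carriers >= min_carriers, ]
  out <- out[order(out$label), ]
  rownames(out) <- NULL
  out
}

# sex-adjusted logistic fit on aggregated cells; columns of M are binary
# predictors. Returns coefficient, p for each predictor column.
.agg_logit <- function(status, sex, M) {
  k <- ncol(M)
  key <- interaction(as.data.frame(cbind(M, sex)), drop = TRUE)
  agg_case <- tapply(status, key, sum)
  agg_tot <- tapply(status, key, length)
  lev <- do.call(rbind, strsplit(names(agg_case), ".", fixed = TRUE))
  X <- cbind(1, matrix(as.numeric(lev), nrow(lev)))
  fit <- suppressWarnings(stats::glm.fit(
    X, cbind(agg_case, agg_tot - agg_case), family = stats::binomial()))
  cf <- fit$coefficients
  # Wald SEs from the unscaled covariance of the IRLS solve
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(XtWX + diag(1e-12, ncol(X)))))
  z <- cf / se
  p <- 2 * stats::pnorm(-abs(z))
  list(coef = cf[1 + seq_len(k)], p = p[1 + seq_len(k)],
       separated = any(abs(cf) > 15) | !fit$converged)
}

#' Pairwise driver-genotype screen
#'
#' A genotype is called a "driver" when it is marginally significant
#' (sex-adjusted) and, co-fitted pairwise with every other enumerated
#' genotype, never loses significance at `alpha_retain` nor flips the sign
#' of its coefficient. Near-collinear pairs (|r| >= `collinear_r`) are not
#' co-fitted; instead the member with the smaller marginal p survives the
#' pair, and the simplification is logged in the output.
#'
#' @param status 0/1 outcome vector.
#' @param sex 0/1 (or F/M) covariate vector.
#' @param carriage n x m logical/0-1 matrix of genotype carriage, with
#'   column names.
#' @param alpha_retain Retention significance level (default 0.05).
#' @param collinear_r Collinearity guard (default 0.99).
#' @return Data.frame of driver calls: `label`, `ln_or`, `p` (marginal,
#'   sex-adjusted), `is_driver`, `failing_partner` (first partner that
#'   disqualified the genotype, `NA` for drivers), `n_collinear_skipped`.
#' @export
pairwise_driver_screen <- function(status, sex, carriage, alpha_retain = 0.05,
                                   collinear_r = 0.99) {
  if (is.character(sex)) sex <- as.integer(sex == "M")
  status <- as.integer(status)
  M <- matrix(as.numeric(carriage), nrow(carriage),
              dimnames = dimnames(carriage))
  labels <- colnames(M)
  stopifnot(!is.null(labels))
  m <- ncol(M)
  marg <- lapply(seq_len(m), function(j) .agg_logit(status, sex, M[, j, drop = FALSE]))
  ln_or <- vapply(marg, function(x) x$coef[1], 0)
  pmarg <- vapply(marg, function(x) x$p[1], 0)
  r <- suppressWarnings(stats::cor(M))
  is_driver <- rep(FALSE, m)
  failing <- rep(NA_character_, m)
  n_skip <- rep(0L, m)
  cand <- which(pmarg < alpha_retain & is.finite(ln_or))
  for (jj in cand) {
    ok <- TRUE
    for (kk in seq_len(m)) {
      if (kk == jj) next
      if (is.finite(r[jj, kk]) && abs(r[jj, kk]) >= collinear_r) {
        # collinear: retain the genotype with the smaller marginal p
        n_skip[jj] <- n_skip[jj] + 1L
        if (pmarg[jj] > pmarg[kk]) { ok <- FALSE; failing[jj] <- labels[kk] }
      } else {
        fit <- .agg_logit(status, sex, M[, c(jj, kk)])
        if (!is.finite(fit$coef[1]) || fit$p[1] >= alpha_retain ||
            sign(fit$coef[1]) != sign(ln_or[jj])) {
          ok <- FALSE; failing[jj] <- labels[kk]
        }
      }
      if (!ok) break
    }
    is_driver[jj] <- ok
  }
  data.frame(label = labels, ln_or = ln_or, p = pmarg, is_driver = is_driver,
             failing_partner = failing, n_collinear_skipped = n_skip,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Effective number of independent tests
#'
#' Eigenvalue-based effective test count from the genotype-genotype
#' Pearson correlation matrix of carriage indicators. The default
#' estimator is Li & Ji's
#' \eqn{M_{eff} = \sum_i [ I(\lambda_i \ge 1) + (\lambda_i - \lfloor
#' \lambda_i \rfloor) ]}; Nyholt's variance-based estimator is available
#' as an alternative. Constant columns are dropped with a warning.
#'
#' @param carriage n x m carriage matrix (columns = genotypes).
#' @param method `"liji"` (default) or `"nyholt"`.
#' @return Meff (1 <= Meff <= m), with attribute `method`.
#' @export
effective_tests <- function(carriage, method = c("liji", "nyholt")) {
  method <- match.arg(method)
  M <- matrix(as.numeric(carriage), nrow(carriage))
  v <- apply(M, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant genotype column(s) dropped")
    M <- M[, v > 0, drop = FALSE]
  }
  m <- ncol(M)
  if (m < 2) stop("need >= 2 non-constant genotypes")
  lambda <- eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  meff <- if (method == "liji") {
    # snap eigenvalues sitting within numerical error of an integer, else
    # floor(k - eps) = k - 1 turns a zero fractional part into ~1
    lf <- floor(lambda + 1e-9)
    sum((lambda >= 1 - 1e-9) + pmax(lambda - lf, 0))
  } else {
    1 + (m - 1) * (1 - stats::var(lambda) / m)
  }
  structure(min(max(meff, 1), m), method = method)
}

#' Bonferroni cutoff from an effective test count
#'
#' @param alpha Family-wise significance level.
#' @param meff Effective number of tests (>= 1).
#' @return `alpha / meff`.
#' @examples
#' adjusted_threshold(0.05, 3692)   # 1.35e-5
#' adjusted_threshold(0.05, 21696)  # 2.3e-6
#' @export
adjusted_threshold <- function(alpha, meff) {
  stopifnot(meff >= 1, alpha > 0, alpha <= 1)
  alpha / meff
}
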