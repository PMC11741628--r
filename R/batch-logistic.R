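# Vectorised ML logistic fits on aggregated binomial cells, shared design.
#
# The permutation engine refits the same small sex-adjusted model for every
# permuted stratum assignment. Individual-level data collapse onto the
# 2 (genotype) x 2 (sex) cells, so each refit is a binomial GLM with a
# fixed 4 x 3 design; this solver runs Newton-Raphson for thousands of such
# fits simultaneously using closed-form 3x3 solves. Estimates agree with
# stats::glm to near machine precision (asserted in the test suite).

# X: c x p design (p <= 3); Y: c x B successes; N: c x B totals.
# Returns p x B coefficients; columns that are inestimable (separated or
# empty margins) are NA.
batch_logit_fit <- function(X, Y, N, max_iter = 50L, tol = 1e-10) {
  c_ <- nrow(X); p <- ncol(X); B <- ncol(Y)
  stopifnot(nrow(Y) == c_, identical(dim(Y), dim(N)), p <= 3)
  beta <- matrix(0, p, B)
  active <- rep(TRUE, B)
  # precompute design cross-products per cell
  xx <- list()
  for (j in seq_len(p)) for (k in j:p) xx[[paste(j, k)]] <- X[, j] * X[, k]
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- X %*% beta[, active, drop = FALSE]
    mu <- stats::plogis(eta)
    Na <- N[, active, drop = FALSE]; Ya <- Y[, active, drop = FALSE]
    W <- Na * mu * (1 - mu)
    G <- crossprod(X, Ya - Na * mu)              # p x B gradient
    H <- lapply(xx, function(v) colSums(v * W))  # Hessian elements
    if (p == 3) {
      a <- H[["1 1"]] + 1e-12; b <- H[["1 2"]]; cc <- H[["1 3"]]
      d <- H[["2 2"]] + 1e-12; e <- H[["2 3"]]; f <- H[["3 3"]] + 1e-12
      det <- a * (d * f - e * e) - b * (b * f - cc * e) + cc * (b * e - cc * d)
      i11 <- d * f - e * e; i12 <- cc * e - b * f; i13 <- b * e - cc * d
      i22 <- a * f - cc * cc; i23 <- b * cc - a * e; i33 <- a * d - b * b
      g1 <- G[1, ]; g2 <- G[2, ]; g3 <- G[3, ]
      step <- rbind((i11 * g1 + i12 * g2 + i13 * g3) / det,
                    (i12 * g1 + i22 * g2 + i23 * g3) / det,
                    (i13 * g1 + i23 * g2 + i33 * g3) / det)
    } else if (p == 2) {
      a <- H[["1 1"]] + 1e-12; b <- H[["1 2"]]; d <- H[["2 2"]] + 1e-12
      det <- a * d - b * b
      step <- rbind((d * G[1, ] - b * G[2, ]) / det,
                    (-b * G[1, ] + a * G[2, ]) / det)
    } else {
      step <- G / (H[["1 1"]] + 1e-12)
    }
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 5), -5)  # damp early overshoot
    beta[, active] <- beta[, active, drop = FALSE] + step
    conv <- colSums(abs(step)) < tol
    idx <- which(active)
    active[idx[conv]] <- FALSE
  }
  # flag non-converged / runaway columns
  bad <- active | apply(abs(beta) > 15, 2, any)
  beta[, bad] <- NA_real_
  beta
}

# Stratum-specific sex-adjusted genotype ln[OR]s for many stratum
# assignments at once.
#
# g, sex, status: 0/1 vectors of length n. strata_high: n x B logical
# matrix (TRUE = high stratum). Returns list(high, low): each a length-B
# vector of genotype coefficients (NA where inestimable).
batch_stratum_lnor <- function(g, sex, status, strata_high) {
  n <- length(g)
  cell <- 1L + g + 2L * sex + 4L * status  # 1..8
  D <- matrix(0, n, 8L)
  D[cbind(seq_len(n), cell)] <- 1
  tot <- colSums(D)
  Shigh <- matrix(as.numeric(strata_high), n)
  ch <- crossprod(D, Shigh)        # 8 x B counts in the high stratum
  cl <- tot - ch
  X <- cbind(1, c(0, 1, 0, 1), c(0, 0, 1, 1))  # intercept, genotype, sex
  fit_side <- function(cnt) {
    Y <- cnt[5:8, , drop = FALSE]                      # cases per cell
    N <- Y + cnt[1:4, , drop = FALSE]                  # cases + controls
    # genotype margins must be mixed for the coefficient to exist
    car_case <- Y[2, ] + Y[4, ]; car_tot <- N[2, ] + N[4, ]
    non_case <- Y[1, ] + Y[3, ]; non_tot <- N[1, ] + N[3, ]
    ok <- car_tot > 0 & non_tot > 0 & car_case > 0 & car_case < car_tot &
      non_case > 0 & non_case < non_tot
    out <- rep(NA_real_, ncol(Y))
    if (any(ok)) {
      beta <- batch_logit_fit(X, Y[, ok, drop = FALSE], N[, ok, drop = FALSE])
      out[ok] <- beta[2, ]
    }
    out
  }
  list(high = fit_side(ch), low = fit_side(cl))
}
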