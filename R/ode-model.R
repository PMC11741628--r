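# ODE model of islet autoimmunity: conventional T cells (E) kill
# insulin-producing beta-cells (B) under suppression by regulatory T cells
# (R). Two variants: model 1 has unconstrained antigen-driven T cell
# production, model 2 caps total T cell production by a shared carrying
# capacity K (model 1 is the K -> Inf limit of model 2). Each in-silico
# individual is simulated twice: an iKIR-high arm in which both T cell
# death rates are reduced by the factor (1 - eps), and an iKIR-low
# reference arm.
#
#   dB/dt = -kappa * E * B / (1 + q R)
#   dE/dt = sigma_E + rho_E * E * B/(s + B) * g - delta_E * E
#   dR/dt = sigma_R + rho_R * R * B/(s + B) * g - delta_R * R
#   g = 1 (model 1)   or   g = max(0, 1 - (E + R)/K) (model 2)

#' Parameter set for the beta-cell destruction model
#'
#' Rates are per unit time with beta-cell mass normalised to `B0 = 1`;
#' `theta` is the surviving-mass fraction below which the individual is
#' labelled T1D at `t_end`; `eps` in [0, 1) is the iKIR survival effect
#' (relative reduction of both T cell death rates in the iKIR-high arm).
#'
#' @param kappa Beta-cell kill rate.
#' @param sigma_E,rho_E,delta_E Tconv source, proliferation and death.
#' @param sigma_R,rho_R,delta_R Treg source, proliferation and death.
#' @param q Treg suppression strength.
#' @param K Carrying capacity (model 2; ignored by model 1).
#' @param s Antigen (beta-cell mass) half-saturation.
#' @param eps iKIR death-rate multiplier: high arm uses `delta * (1 - eps)`.
#' @param theta Disease-onset threshold on `B(t_end)/B0`.
#' @param t_end Simulation horizon.
#' @param B0 Initial beta-cell mass.
#' @return A named list of class `ode_params`.
#' @export
ode_params <- function(kappa = 0.5, sigma_E = 0.01, rho_E = 0.5, delta_E = 0.3,
                       sigma_R = 0.05, rho_R = 0.5, delta_R = 0.2,
                       q = 5, K = 5, s = 0.3, eps = 0.4, theta = 0.1,
                       t_end = 30, B0 = 1) {
  p <- list(kappa = kappa, sigma_E = sigma_E, rho_E = rho_E, delta_E = delta_E,
            sigma_R = sigma_R, rho_R = rho_R, delta_R = delta_R,
            q = q, K = K, s = s, eps = eps, theta = theta, t_end = t_end,
            B0 = B0)
  rates <- unlist(p[c("kappa", "sigma_E", "rho_E", "delta_E", "sigma_R",
                      "rho_R", "delta_R", "q", "K", "s")])
  stopifnot(all(rates >= 0), theta > 0, theta < 1, eps >= 0, eps < 1,
            t_end > 0, B0 > 0)
  class(p) <- "ode_params"
  p
}

.ode_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    g <- if (model == 2) max(0, 1 - (E + R) / K) else 1
    act <- B / (s + B)
    dB <- -kappa * E * B / (1 + q * R)
    dE <- sigma_E + rho_E * E * act * g - dE_eff * E
    dR <- sigma_R + rho_R * R * act * g - dR_eff * R
    list(c(dB, dE, dR))
  })
}

#' Simulate one in-silico individual
#'
#' Integrates the three-state system for one parameter set and one iKIR
#' arm. The iKIR-high arm multiplies both T cell death rates by
#' `(1 - eps)`; the outcome is `"T1D"` when the surviving beta-cell
#' fraction at `t_end` falls below `theta`, otherwise `"healthy"`.
#'
#' @param params An [ode_params()] set.
#' @param model 1 (no density dependence) or 2 (carrying capacity).
#' @param ikir_arm `"high"` or `"low"`.
#' @param init Optional named initial state `c(B=, E=, R=)`; default
#'   `B = B0`, `E = sigma_E / delta_E`, `R = sigma_R / delta_R` (resting
#'   steady states of the source-death balance).
#' @param n_out Output grid size (used for the mean Treg count).
#' @param rtol,atol Integrator tolerances (lsoda).
#' @return List with `trajectory` (data.frame `time, B, E, R`), `outcome`,
#'   `final_beta_fraction`, `mean_treg` and `capacity_occupancy`
#'   (max of `(E+R)/K`, `NA` for model 1).
#' @export
simulate_individual <- function(params, model = 2, ikir_arm = c("low", "high"),
                                init = NULL, n_out = 60, rtol = 1e-8,
                                atol = 1e-10) {
  ikir_arm <- match.arg(ikir_arm)
  stopifnot(inherits(params, "ode_params"), model %in% c(1, 2))
  f <- if (ikir_arm == "high") 1 - params$eps else 1
  parms <- c(unlist(params[c("kappa", "sigma_E", "rho_E", "sigma_R", "rho_R",
                             "q", "K", "s")]),
             dE_eff = params$delta_E * f, dR_eff = params$delta_R * f,
             model = model)
  if (is.null(init))
    init <- c(B = params$B0,
              E = params$sigma_E / max(params$delta_E * f, 1e-12),
              R = params$sigma_R / max(params$delta_R * f, 1e-12))
  times <- seq(0, params$t_end, length.out = n_out)
  out <- deSolve::lsoda(init, times, .ode_rhs, parms, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || nrow(out) < n_out)
    stop("integration failure")
  traj <- as.data.frame(out)
  names(traj) <- c("time", "B", "E", "R")
  traj$B <- pmax(traj$B, 0); traj$E <- pmax(traj$E, 0); traj$R <- pmax(traj$R, 0)
  fb <- traj$B[n_out] / params$B0
  list(trajectory = traj,
       outcome = if (fb < params$theta) "T1D" else "healthy",
       final_beta_fraction = fb,
       mean_treg = mean(traj$R),
       capacity_occupancy = if (model == 2)
         max((traj$E + traj$R) / params$K) else NA_real_)
}

#' Default log-uniform sampling ranges for the in-silico cohort
#'
#' Spans growing and shrinking effector responses, weak to strong
#' suppression, and — through the wide `sigma_R` range — the HLA class II
#' protection spectrum (a high islet-specific Treg supply standing in for
#' a protective genotype). Ranges were fixed once, verified by simulation
#' to produce all three outcome classes (always-healthy, always-T1D,
#' arm-dependent).
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_param_ranges <- function() {
  list(kappa = c(10, 1000), sigma_E = c(0.01, 0.1), rho_E = c(0.1, 1),
       delta_E = c(0.3, 1.5), sigma_R = c(0.01, 0.05), rho_R = c(0.2, 2),
       delta_R = c(0.1, 0.5), q = c(100, 1000), K = c(0.5, 3), s = c(0.1, 1))
}

#' Simulate a paired-arm in-silico cohort
#'
#' Samples `n` parameter sets log-uniformly within `ranges` and simulates
#' each individual in both iKIR arms. Individuals whose integration fails
#' are excluded (the run aborts if more than 5% fail).
#'
#' @param ranges Named list of `c(min, max)` ranges (log-uniform sampling).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param model 1 or 2.
#' @param eps,theta,t_end Shared model settings, see [ode_params()].
#' @return Data.frame with the sampled parameters and per-individual
#'   `outcome_high`, `outcome_low`, `mean_treg` (average of the two arms),
#'   `final_beta_high`, `final_beta_low`, `capacity_occupancy` (low arm)
#'   and `outcome_class` (`always_healthy`, `always_T1D`, `arm_dependent`).
#' @export
run_ode_cohort <- function(ranges = default_param_ranges(), n = 10000,
                           seed = 1L, model = 2, eps = 0.4, theta = 0.1,
                           t_end = 30) {
  set.seed(seed)
  draws <- sapply(ranges, function(r) exp(stats::runif(n, log(r[1]), log(r[2]))))
  if (n == 1) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(ranges)))
  res <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    pars <- do.call(ode_params, c(as.list(draws[i, ]),
                                  list(eps = eps, theta = theta, t_end = t_end)))
    sim <- tryCatch(list(high = simulate_individual(pars, model, "high"),
                         low = simulate_individual(pars, model, "low")),
                    error = function(e) NULL)
    if (is.null(sim)) { failed[i] <- TRUE; next }
    res[[i]] <- data.frame(
      outcome_high = sim$high$outcome, outcome_low = sim$low$outcome,
      mean_treg = (sim$high$mean_treg + sim$low$mean_treg) / 2,
      final_beta_high = sim$high$final_beta_fraction,
      final_beta_low = sim$low$final_beta_fraction,
      capacity_occupancy = sim$low$capacity_occupancy,
      stringsAsFactors = FALSE)
  }
  if (mean(failed) > 0.05)
    stop(sprintf("%.1f%% of integrations failed", 100 * mean(failed)))
  if (any(failed))
    message(sum(failed), " individual(s) excluded: integration failure")
  out <- cbind(as.data.frame(draws[!failed, , drop = FALSE]),
               do.call(rbind, res[!failed]))
  out$outcome_class <- ifelse(
    out$outcome_high == out$outcome_low,
    ifelse(out$outcome_high == "T1D", "always_T1D", "always_healthy"),
    "arm_dependent")
  out
}

#' Treg-binned difference in ln[OR] between iKIR arms
#'
#' Groups individuals by mean Treg count (quantile bins) and computes, per
#' bin, `Delta = ln odds(T1D | high arm) - ln odds(T1D | low arm)`. Bins
#' in which either arm has zero or only T1D outcomes have no finite odds
#' and are reported as `NA` (not dropped). In model 1 the Delta profile is
#' expected flat; in model 2 it increases with Treg numbers (the
#' Treg-saturation signature).
#'
#' @param cohort Output of [run_ode_cohort()].
#' @param n_bins Number of quantile bins.
#' @return Data.frame `bin, n, mean_treg_median, delta_lnor`.
#' @export
treg_binned_delta_lnor <- function(cohort, n_bins = 10) {
  qs <- stats::quantile(cohort$mean_treg, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  bin <- cut(cohort$mean_treg, breaks = unique(qs), labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sub <- cohort[bin == b, ]
    nh <- sum(sub$outcome_high == "T1D"); nl <- sum(sub$outcome_low == "T1D")
    n <- nrow(sub)
    delta <- if (nh == 0 || nh == n || nl == 0 || nl == n) NA_real_
             else log(nh / (n - nh)) - log(nl / (n - nl))
    data.frame(bin = b, n = n, mean_treg_median = stats::median(sub$mean_treg),
               delta_lnor = delta)
  }))
  rownames(out) <- NULL
  out
}

#' Spearman trend of the binned Delta ln[OR]
#'
#' @param bins Output of [treg_binned_delta_lnor()].
#' @return `htest` from [stats::cor.test()] (Spearman, one-sided
#'   "greater") on the defined bins.
#' @export
treg_trend_test <- function(bins) {
  ok <- is.finite(bins$delta_lnor)
  if (sum(ok) < 3) stop("fewer than 3 defined bins")
  stats::cor.test(bins$bin[ok], bins$delta_lnor[ok], method = "spearman",
                  alternative = "greater", exact = TRUE)
}
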