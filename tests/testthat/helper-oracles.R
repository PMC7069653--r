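# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's estimation path: direct
# quadrature, ODE integration and closed forms only.

# a small crossover trial (12 subjects over three studies) used where the
# full 35-subject design would be disproportionate
small_design <- function(saliva = c(FALSE, TRUE, TRUE)) {
  trial_design(studies = tibble::tibble(
    study = c("SA", "SB", "SC"),
    n_subjects = c(4L, 4L, 4L),
    saliva = saliva))
}

table2_truth <- function(...) truth_params(...)

# noise-free truth: every variability term zero
noiseless_truth <- function() {
  truth_params(pk_omega2 = c(cl_f = 0, ka = 0), pk_sigma = 0,
               circadian_omega2 = c(bsl0 = 0, amp = 0, trend = 0,
                                    tpeak = 0),
               bsl0_iov2 = 0, s0_omega2 = 0, pd_sigma = 0,
               beta_omega2 = 0, saliva_sigma = 0)
}

# marginal -2 log likelihood of a one-random-effect model by adaptive
# Gauss-Hermite quadrature (64 nodes), centred and scaled at the joint mode
agq_neg2ll_1re <- function(y, pred_of_eta, var_of_pred, omega2,
                           n_nodes = 64) {
  gh <- pracma::gaussHermite(n_nodes)
  ll_joint <- function(e) {
    f <- pred_of_eta(e)
    v <- var_of_pred(f)
    out <- sum(stats::dnorm(y, f, sqrt(v), log = TRUE)) +
      stats::dnorm(e, 0, sqrt(omega2), log = TRUE)
    if (!is.finite(out)) -1e10 else out
  }
  opt <- stats::optimize(function(e) -ll_joint(e), c(-8, 8))
  m <- opt$minimum
  h <- 1e-4
  curv <- -(ll_joint(m + h) - 2 * ll_joint(m) + ll_joint(m - h)) / h^2
  curv <- max(curv, 1e-8)
  s <- 1 / sqrt(curv)
  vals <- vapply(gh$x, function(z) {
    e <- m + sqrt(2) * s * z
    exp(ll_joint(e) - ll_joint(m) + z^2)
  }, numeric(1))
  log_int <- ll_joint(m) + log(sqrt(2) * s) + log(sum(gh$w * vals))
  -2 * log_int
}

# transit-chain concentration by numeric integration of the linear
# three-compartment system (depot -> transit -> central)
pk_ode_oracle <- function(dose, times, cl, v, ka, f = 1) {
  rhs <- function(t, y, parms) {
    list(c(-ka * y[1],
           ka * y[1] - ka * y[2],
           ka * y[2] - (cl / v) * y[3]))
  }
  out <- deSolve::lsoda(c(f * dose, 0, 0), c(0, times), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  1000 * out[-1, 4] / v
}

# attach the per-occasion dose to observation rows (test-side copy of the
# stage plumbing, kept independent of the pipeline internals)
join_dose <- function(data, obs) {
  doses <- data[data$EVID == 1L, c("ID", "OCC", "AMT")]
  names(doses)[3] <- "DOSE"
  dplyr::inner_join(obs, doses, by = c("ID", "OCC"))
}
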