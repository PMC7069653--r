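#' Specify a nonlinear mixed-effects model
#'
#' Describes the statistical side of a model for [fit_population()]: which
#' fixed effects are estimated, which carry inter-individual variability
#' (IIV, a per-subject random effect) or inter-occasion variability (IOV, a
#' per-subject-per-occasion random effect), and the residual error model.
#'
#' Random effects enter multiplicatively by default,
#' `P_i = theta * exp(eta_i + kappa_io)`, giving log-normally distributed
#' individual parameters; an additive parameterisation
#' (`re_dist = "normal"`) is available for linear Gaussian models. The
#' residual model is `O_obs = O_pred (1 + e1) + e2` with independent
#' zero-mean normal `e1`, `e2`, so the observation variance is
#' `pred^2 sigma_prop^2 + sigma_add^2`; a sigma component is estimated
#' whenever its initial value is positive.
#'
#' @param theta Named numeric vector of fixed-effect initial values
#'   (estimated).
#' @param fixed Named numeric vector of structural parameters held fixed
#'   (still usable as random-effect anchors, e.g. a fixed typical value with
#'   estimated IIV).
#' @param transform Named character vector, `"log"` or `"identity"`, per
#'   estimated theta; defaults to `"log"` for positive initials and
#'   `"identity"` otherwise.
#' @param lower,upper Named natural-scale bounds for identity-transformed
#'   thetas (e.g. an amplitude bounded in (-1, 1)).
#' @param iiv Character vector of parameter names (from `theta` or `fixed`)
#'   carrying IIV.
#' @param omega2 Named numeric initial IIV variances, one per `iiv` entry
#'   (default 0.1).
#' @param iov Character vector of parameter names carrying IOV.
#' @param iov2 Named numeric initial IOV variances (default 0.05).
#' @param re_dist Named character vector (`"lognormal"`/`"normal"`) per
#'   random-effect parameter; default lognormal.
#' @param sigma_prop,sigma_add Initial residual SDs (proportional is
#'   dimensionless, additive in observation units). At least one must be
#'   positive.
#' @return An object of class `me_spec`.
#' @export
me_spec <- function(theta, fixed = numeric(), transform = NULL,
                    lower = numeric(), upper = numeric(),
                    iiv = character(), omega2 = NULL,
                    iov = character(), iov2 = NULL,
                    re_dist = NULL,
                    sigma_prop = 0.1, sigma_add = 0) {
  stopifnot(is.numeric(theta), length(theta) >= 1, !is.null(names(theta)))
  all_names <- c(names(theta), names(fixed))
  if (anyDuplicated(all_names)) {
    stop("Duplicated parameter names across `theta` and `fixed`.",
         call. = FALSE)
  }
  if (!all(iiv %in% all_names)) {
    stop("`iiv` names must appear in `theta` or `fixed`.", call. = FALSE)
  }
  if (!all(iov %in% all_names)) {
    stop("`iov` names must appear in `theta` or `fixed`.", call. = FALSE)
  }
  tr <- stats::setNames(ifelse(theta > 0, "log", "identity"), names(theta))
  if (!is.null(transform)) tr[names(transform)] <- transform
  if (any(tr == "log" & theta <= 0)) {
    stop("log-transformed thetas need positive initial values.",
         call. = FALSE)
  }
  om <- stats::setNames(rep(0.1, length(iiv)), iiv)
  if (!is.null(omega2)) om[names(omega2)] <- omega2
  ov <- stats::setNames(rep(0.05, length(iov)), iov)
  if (!is.null(iov2)) ov[names(iov2)] <- iov2
  if (any(c(om, ov) <= 0)) {
    stop("Initial random-effect variances must be > 0.", call. = FALSE)
  }
  if (sigma_prop < 0 || sigma_add < 0 || (sigma_prop == 0 && sigma_add == 0)) {
    stop("Residual model is degenerate: need sigma_prop > 0 or ",
         "sigma_add > 0.", call. = FALSE)
  }
  rd <- stats::setNames(rep("lognormal", length(all_names)), all_names)
  if (!is.null(re_dist)) rd[names(re_dist)] <- re_dist
  structure(
    list(theta = theta, fixed = fixed, transform = tr,
         lower = lower, upper = upper,
         iiv = iiv, omega2 = om, iov = iov, iov2 = ov, re_dist = rd,
         sigma_prop = sigma_prop, sigma_add = sigma_add),
    class = "me_spec"
  )
}

#' Individual parameter from a population value and a deviation
#'
#' The exponential IIV model: `P_i = tv * exp(eta)`, giving log-normal
#' individual parameters that stay positive (in magnitude) for any finite
#' deviation.
#'
#' @param tv Typical (population) value, nonzero.
#' @param eta Individual deviation(s) on the log scale.
#' @return Individual parameter value(s).
#' @export
individual_param <- function(tv, eta) {
  if (any(!is.finite(tv)) || any(tv <= 0)) {
    stop("`tv` must be finite and > 0.", call. = FALSE)
  }
  tv * exp(eta)
}

#' Residual observation variance
#'
#' Variance implied by the combined residual model
#' `O_obs = O_pred (1 + e1) + e2`: `pred^2 sigma_prop^2 + sigma_add^2`.
#'
#' @param pred Model prediction(s), >= 0.
#' @param sigma_prop Proportional residual SD (dimensionless).
#' @param sigma_add Additive residual SD (observation units).
#' @return Variance in squared observation units.
#' @export
residual_variance <- function(pred, sigma_prop = 0, sigma_add = 0) {
  if (any(pred < 0)) stop("`pred` must be >= 0.", call. = FALSE)
  if (sigma_prop == 0 && sigma_add == 0) {
    stop("Degenerate residual model: both sigma components are zero.",
         call. = FALSE)
  }
  pred^2 * sigma_prop^2 + sigma_add^2
}

# ---- internal engine ------------------------------------------------------

# Split data into plain per-subject lists; `pred_fn(p, d)` is called with a
# named list of per-row parameter values and a plain list of the subject's
# data columns (tibble overhead is kept out of the inner loop).
engine_split <- function(data, spec) {
  stopifnot(all(c("ID", "DV") %in% names(data)))
  if (!"OCC" %in% names(data)) data$OCC <- 1L
  ids <- unique(data$ID)
  subjects <- lapply(ids, function(id) {
    idx <- which(data$ID == id)
    d <- lapply(data, function(col) col[idx])
    occ_levels <- sort(unique(d$OCC))
    list(id = id, d = d, y = d$DV, rows = idx,
         occ = match(d$OCC, occ_levels), occ_levels = occ_levels,
         n_occ = length(occ_levels))
  })
  names(subjects) <- as.character(ids)
  subjects
}

# layout of the inner random-effect vector b for one subject:
# [eta_1..eta_niiv, kappa_{iov1,occ1..occK}, kappa_{iov2,occ1..occK}, ...]
engine_b_dim <- function(spec, n_occ) {
  length(spec$iiv) + length(spec$iov) * n_occ
}

# prior precision vector matching the b layout
engine_prec <- function(omega2, iov2, n_occ) {
  c(1 / omega2, rep(1 / iov2, each = n_occ))
}

# precompute which parameter gets which slice of b (resolved once per fit)
engine_plan <- function(spec) {
  re_names <- union(spec$iiv, spec$iov)
  lapply(re_names, function(nm) {
    list(nm = nm,
         iiv_j = match(nm, spec$iiv),
         iov_j = match(nm, spec$iov),
         lognormal = spec$re_dist[[nm]] != "normal")
  })
}

# per-row individual parameters: p0 is as.list(theta_all), prepared once
# per outer evaluation
engine_ind_params <- function(p0, plan, n_iiv, b, subj) {
  p <- p0
  for (pl in plan) {
    e <- 0
    if (!is.na(pl$iiv_j)) e <- b[pl$iiv_j]
    if (!is.na(pl$iov_j)) {
      e <- e + b[n_iiv + (pl$iov_j - 1L) * subj$n_occ + subj$occ]
    }
    p[[pl$nm]] <- if (pl$lognormal) p[[pl$nm]] * exp(e) else p[[pl$nm]] + e
  }
  p
}

# -2 log joint density (data + random-effect prior) for one subject
engine_q <- function(b, subj, p0, plan, n_iiv, prec, log_prior_norm,
                     sp2, sa2, pred_fn) {
  p <- engine_ind_params(p0, plan, n_iiv, b, subj)
  f <- pred_fn(p, subj$d)
  if (any(!is.finite(f))) return(1e10)
  v <- f * f * sp2 + sa2
  if (any(v <= 0)) return(1e10)
  r <- subj$y - f
  sum(log(2 * pi * v) + r * r / v) + sum(prec * b * b) + log_prior_norm
}

# damped Gauss-Newton MAP solve for one subject's random effects.
# Returns the mode, q at the mode, and the curvature J'WJ + prec evaluated
# at the mode (the FOCE-with-interaction expansion). When the stage
# supplies `pred_jac` (per-row derivatives of the prediction with respect
# to each individual parameter), the random-effect Jacobian comes from the
# chain rule dP/d(eta) = P for the exponential parameterisation; otherwise
# forward differences are used.
engine_inner <- function(b0, subj, p0, plan, n_iiv, prec, log_prior_norm,
                         sp2, sa2, pred_fn, pred_jac = NULL,
                         max_iter = 40L) {
  nb <- length(b0)
  qf <- function(b) engine_q(b, subj, p0, plan, n_iiv, prec,
                             log_prior_norm, sp2, sa2, pred_fn)
  # evaluate q together with the prediction and individual parameters so
  # the accepted candidate feeds the next Gauss-Newton iteration directly
  qeval <- function(b) {
    p <- engine_ind_params(p0, plan, n_iiv, b, subj)
    f <- pred_fn(p, subj$d)
    if (any(!is.finite(f))) return(list(q = 1e10, f = f, p = p))
    v <- f * f * sp2 + sa2
    if (any(v <= 0)) return(list(q = 1e10, f = f, p = p))
    r <- subj$y - f
    list(q = sum(log(2 * pi * v) + r * r / v) + sum(prec * b * b) +
           log_prior_norm,
         f = f, p = p)
  }
  jac <- function(b, f, p) {
    J <- matrix(0, length(f), nb)
    if (!is.null(pred_jac)) {
      D <- pred_jac(p, subj$d)
      for (pl in plan) {
        dcol <- D[[pl$nm]] *
          (if (pl$lognormal) p[[pl$nm]] else 1)
        if (length(dcol) == 1L) dcol <- rep(dcol, length(f))
        if (!is.na(pl$iiv_j)) J[, pl$iiv_j] <- dcol
        if (!is.na(pl$iov_j)) {
          for (k in seq_len(subj$n_occ)) {
            col <- n_iiv + (pl$iov_j - 1L) * subj$n_occ + k
            J[subj$occ == k, col] <- dcol[subj$occ == k]
          }
        }
      }
    } else {
      for (k in seq_len(nb)) {
        bk <- b; bk[k] <- bk[k] + 1e-5
        pk <- engine_ind_params(p0, plan, n_iiv, bk, subj)
        J[, k] <- (pred_fn(pk, subj$d) - f) * 1e5
      }
    }
    J
  }
  b <- b0
  cur <- qeval(b)
  # a stale warm start can sit in the wrong basin; fall back to the prior
  # mode whenever it is at least as good
  if (any(b != 0)) {
    c0 <- qeval(numeric(nb))
    if (c0$q <= cur$q) { b <- numeric(nb); cur <- c0 }
  }
  lam <- 1e-4
  P <- diag(prec, nb)
  dix <- seq(1L, nb * nb, by = nb + 1L)
  J <- NULL
  for (it in seq_len(max_iter)) {
    v <- pmax(cur$f * cur$f * sp2 + sa2, 1e-12)
    J <- jac(b, cur$f, cur$p)
    w <- 1 / v
    r <- subj$y - cur$f
    g <- -crossprod(J, w * r) + prec * b
    H <- crossprod(J * sqrt(w)) + P
    accepted <- FALSE
    for (tries in 1:12) {
      Hl <- H
      Hl[dix] <- H[dix] * (1 + lam)
      delta <- tryCatch(drop(solve(Hl, -g)), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- qeval(b + delta)
        if (is.finite(cand$q) && cand$q <= cur$q + 1e-12) {
          accepted <- TRUE
          break
        }
      }
      lam <- lam * 8
    }
    if (!accepted) break
    b <- b + delta
    improve <- cur$q - cand$q
    cur <- cand
    lam <- max(lam / 8, 1e-8)
    if (improve < 1e-12 && max(abs(delta)) < 1e-7) break
  }
  # curvature at the mode for the Laplace log-determinant (analytic
  # Jacobian is recomputed exactly at the mode; the numeric one is at most
  # one sub-1e-7 step stale and is reused)
  v <- pmax(cur$f * cur$f * sp2 + sa2, 1e-12)
  if (!is.null(pred_jac)) J <- jac(b, cur$f, cur$p)
  H <- crossprod(J * sqrt(1 / v)) + P
  list(b = b, q = cur$q, H = H)
}

# exact numeric Hessian of q/2 (central differences), for method = "laplace"
engine_exact_hessian <- function(b, qf) {
  nb <- length(b)
  h <- pmax(1e-4, 1e-4 * abs(b))
  H <- matrix(0, nb, nb)
  q0 <- qf(b)
  for (i in seq_len(nb)) {
    ei <- hi <- numeric(nb); ei[i] <- h[i]
    H[i, i] <- (qf(b + ei) - 2 * q0 + qf(b - ei)) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- numeric(nb); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (qf(b + ei + ej) - qf(b + ei - ej) -
             qf(b - ei + ej) + qf(b - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H / 2
}

# Marginal -2 log likelihood (OFV), Laplace approximation around the
# conditional modes. Inner solves always start from the prior mode so the
# OFV is a deterministic, history-free function of the parameters; warm
# starting across outer iterations was measurably faster per evaluation
# but the resulting hysteresis wrecks finite-difference outer gradients.
engine_ofv <- function(subjects, theta_all, spec, omega2, iov2,
                       sigma_prop, sigma_add, pred_fn, pred_jac = NULL,
                       method = "foce", cache = NULL, native_ctx = NULL) {
  if (!is.null(native_ctx) && method == "foce") {
    return(.engine_ofv_native(
      native_ctx$model, native_ctx$subjects,
      unname(theta_all[native_ctx$pord]),
      native_ctx$iiv_par, native_ctx$iov_par,
      unname(omega2), unname(iov2), sigma_prop, sigma_add))
  }
  sp2 <- sigma_prop^2
  sa2 <- sigma_add^2
  p0 <- as.list(theta_all)
  plan <- engine_plan(spec)
  n_iiv <- length(spec$iiv)
  total <- 0
  for (i in seq_along(subjects)) {
    subj <- subjects[[i]]
    nb <- engine_b_dim(spec, subj$n_occ)
    if (nb == 0L) {
      q <- engine_q(numeric(0), subj, p0, plan, n_iiv, numeric(0), 0,
                    sp2, sa2, pred_fn)
      total <- total + q
      next
    }
    prec <- engine_prec(omega2, iov2, subj$n_occ)
    lpn <- sum(log(2 * pi / prec))
    b0 <- numeric(nb)
    if (!is.null(cache) && !is.null(cache$b[[i]]) &&
        length(cache$b[[i]]) == nb) {
      b0 <- cache$b[[i]]
    }
    sol <- engine_inner(b0, subj, p0, plan, n_iiv, prec, lpn,
                        sp2, sa2, pred_fn, pred_jac)
    if (!is.null(cache)) cache$b[[i]] <- sol$b
    H <- if (method == "laplace") {
      engine_exact_hessian(
        sol$b,
        function(b) engine_q(b, subj, p0, plan, n_iiv, prec, lpn,
                             sp2, sa2, pred_fn))
    } else {
      sol$H
    }
    ld <- tryCatch(2 * sum(log(diag(chol(H)))), error = function(e) NA_real_)
    if (!is.finite(ld)) return(1e10)
    total <- total + sol$q + ld - nb * log(2 * pi)
    if (!is.finite(total)) return(1e10)
  }
  total
}

# ---- outer parameter packing ----------------------------------------------

engine_pack <- function(spec, theta, omega2, iov2, sigma_prop, sigma_add) {
  x <- numeric(0)
  for (nm in names(spec$theta)) {
    x <- c(x, if (spec$transform[[nm]] == "log") log(theta[[nm]])
           else theta[[nm]])
  }
  x <- c(x, log(sqrt(omega2)), log(sqrt(iov2)))
  if (spec$sigma_prop > 0) x <- c(x, log(sigma_prop))
  if (spec$sigma_add > 0) x <- c(x, log(sigma_add))
  x
}

engine_unpack <- function(spec, x) {
  nt <- length(spec$theta)
  th <- numeric(nt)
  names(th) <- names(spec$theta)
  for (j in seq_len(nt)) {
    th[j] <- if (spec$transform[[j]] == "log") exp(x[j]) else x[j]
  }
  i <- nt
  no <- length(spec$iiv)
  omega2 <- stats::setNames(exp(2 * x[i + seq_len(no)]), spec$iiv)
  i <- i + no
  nv <- length(spec$iov)
  iov2 <- stats::setNames(exp(2 * x[i + seq_len(nv)]), spec$iov)
  i <- i + nv
  sp <- spec$sigma_prop
  if (sp > 0) { i <- i + 1L; sp <- exp(x[i]) }
  sa <- spec$sigma_add
  if (sa > 0) { i <- i + 1L; sa <- exp(x[i]) }
  list(theta = th, theta_all = c(th, spec$fixed), omega2 = omega2,
       iov2 = iov2, sigma_prop = sp, sigma_add = sa)
}

engine_bounds <- function(spec) {
  nt <- length(spec$theta)
  lo <- rep(-Inf, nt); hi <- rep(Inf, nt)
  names(lo) <- names(hi) <- names(spec$theta)
  for (nm in names(spec$lower)) {
    if (spec$transform[[nm]] == "identity") lo[nm] <- spec$lower[[nm]]
  }
  for (nm in names(spec$upper)) {
    if (spec$transform[[nm]] == "identity") hi[nm] <- spec$upper[[nm]]
  }
  nre <- length(spec$iiv) + length(spec$iov)
  lo <- c(lo, rep(-7, nre)); hi <- c(hi, rep(3, nre))
  nsig <- (spec$sigma_prop > 0) + (spec$sigma_add > 0)
  lo <- c(lo, rep(-12, nsig)); hi <- c(hi, rep(5, nsig))
  list(lower = unname(lo), upper = unname(hi))
}

#' Objective function value of a nonlinear mixed-effects model
#'
#' Computes the approximate marginal -2 log likelihood (OFV) at given
#' population parameters by Laplace approximation around the per-subject
#' conditional modes. The default curvature uses the Gauss-Newton
#' approximation at the mode with residual variance evaluated at the
#' conditional prediction (the FOCE-with-interaction expansion);
#' `method = "laplace"` uses the exact numeric Hessian instead. With no
#' random effects the result is the exact Gaussian -2 log likelihood.
#'
#' @param data Tibble/data frame with at least `ID` and `DV`, plus whatever
#'   columns `pred_fn` needs; optional `OCC` for occasion structure.
#' @param pred_fn Prediction function `function(p, d)` receiving a named list
#'   of per-row individual parameter values and the subject's rows, returning
#'   the prediction vector.
#' @param spec An [me_spec()].
#' @param theta,omega2,iov2 Named population values at which to evaluate;
#'   default to the spec's initial values.
#' @param sigma_prop,sigma_add Residual SDs; default to the spec's initials.
#' @param method `"foce"` (Gauss-Newton curvature, default) or `"laplace"`
#'   (exact numeric Hessian).
#' @return The OFV (scalar).
#' @export
neg2ll <- function(data, pred_fn, spec, theta = NULL, omega2 = NULL,
                   iov2 = NULL, sigma_prop = NULL, sigma_add = NULL,
                   method = c("foce", "laplace"), pred_jac = NULL) {
  method <- match.arg(method)
  if (nrow(data) == 0) stop("`data` is empty.", call. = FALSE)
  th <- spec$theta
  if (!is.null(theta)) th[names(theta)] <- theta
  om <- spec$omega2
  if (!is.null(omega2)) om[names(omega2)] <- omega2
  ov <- spec$iov2
  if (!is.null(iov2)) ov[names(iov2)] <- iov2
  sp <- if (is.null(sigma_prop)) spec$sigma_prop else sigma_prop
  sa <- if (is.null(sigma_add)) spec$sigma_add else sigma_add
  subjects <- engine_split(data, spec)
  engine_ofv(subjects, c(th, spec$fixed), spec, om, ov, sp, sa,
             pred_fn, pred_jac, method = method)
}

#' Fit a population model by approximate maximum likelihood
#'
#' Maximises the Laplace/FOCE marginal likelihood over fixed effects,
#' random-effect variances and residual SDs. The outer optimiser is
#' [stats::nlminb()] on a transformed scale (log for positive fixed effects
#' and all SDs, identity with bounds otherwise); the inner per-subject
#' problems are solved by a damped Gauss-Newton method warm-started across
#' outer iterations. The optimiser is deterministic given the data and
#' initial values.
#'
#' @inheritParams neg2ll
#' @param se Compute finite-difference standard errors at the optimum
#'   (adds a Hessian evaluation; see [standard_errors()]).
#' @param control Passed to [stats::nlminb()]; sensible iteration caps are
#'   supplied by default.
#' @param profile Optional name of one log-transformed fixed effect to
#'   profile after the first convergence: the parameter is pinned on a
#'   small multiplicative grid around its estimate, the remaining
#'   parameters are re-optimised at each pin, and the full fit is restarted
#'   from the best pin if it improves the OFV. This walks the long shallow
#'   valleys that couple a typical value with its variability (the classic
#'   absorption-rate ridge) which defeat plain quasi-Newton steps.
#' @param profile_steps Log-scale offsets of the profile grid.
#' @return An object of class `htp_fit`: estimates (`theta`, `omega2`,
#'   `iov2`, `sigma`), `ofv`, empirical Bayes estimates (`ebes`),
#'   convergence metadata, and (optionally) an SE table. Supports
#'   [generics::tidy()], [generics::glance()] and [predict_individual()].
#' @export
fit_population <- function(data, pred_fn, spec, method = c("foce", "laplace"),
                           se = FALSE, control = list(), pred_jac = NULL,
                           native = NULL, profile = NULL,
                           profile_steps = c(-0.4, -0.2, 0.2, 0.4)) {
  method <- match.arg(method)
  if (nrow(data) == 0) stop("`data` is empty.", call. = FALSE)
  subjects <- engine_split(data, spec)
  if (length(subjects) < max(1L, length(spec$iiv))) {
    warning("Fewer subjects than IIV terms; the configuration may be ",
            "unidentifiable.", call. = FALSE)
  }
  native_ctx <- if (!is.null(native) && method == "foce") {
    engine_native_prep(subjects, spec, native)
  }
  obj <- function(x) {
    pp <- engine_unpack(spec, x)
    engine_ofv(subjects, pp$theta_all, spec, pp$omega2, pp$iov2,
               pp$sigma_prop, pp$sigma_add, pred_fn, pred_jac,
               method = method, native_ctx = native_ctx)
  }
  x0 <- engine_pack(spec, spec$theta, spec$omega2, spec$iov2,
                    spec$sigma_prop, spec$sigma_add)
  bounds <- engine_bounds(spec)
  # rel.tol keeps the endgame proportionate: OFV differences far below
  # the 3.84 decision scale carry no inferential weight
  ctrl <- utils::modifyList(
    list(iter.max = 400L, eval.max = 1200L, rel.tol = 1e-9),
    control)
  opt <- NULL
  if (!is.null(profile) && profile %in% names(spec$theta) &&
      spec$transform[[profile]] == "log") {
    ps <- engine_profile_search(subjects, spec, pred_fn, pred_jac,
                                method, ctrl, profile, profile_steps)
    if (!is.null(ps) && is.finite(ps$opt$objective)) opt <- ps$opt
  }
  if (is.null(opt)) {
    opt <- stats::nlminb(x0, obj, lower = bounds$lower,
                         upper = bounds$upper, control = ctrl)
  }
  # restart once from the optimum: a cheap stationarity safeguard
  opt2 <- stats::nlminb(opt$par, obj, lower = bounds$lower,
                        upper = bounds$upper, control = ctrl)
  if (is.finite(opt2$objective) && opt2$objective <= opt$objective) {
    opt2$iterations <- opt$iterations + opt2$iterations
    opt2$evaluations <- opt$evaluations + opt2$evaluations
    opt <- opt2
  }
  pp <- engine_unpack(spec, opt$par)
  converged <- opt$convergence == 0
  if (!converged) {
    warning("Outer optimisation did not report clean convergence (",
            opt$message, "); returning the best iterate.", call. = FALSE)
  }
  ebes <- engine_all_ebes(subjects, pp, spec, pred_fn, pred_jac,
                          native_ctx)
  fit <- structure(
    list(theta = pp$theta, theta_all = pp$theta_all, fixed = spec$fixed,
         omega2 = pp$omega2, iov2 = pp$iov2,
         sigma = c(prop = pp$sigma_prop, add = pp$sigma_add),
         ofv = opt$objective,
         convergence = list(status = converged, code = opt$convergence,
                            iterations = opt$iterations,
                            evaluations = unname(opt$evaluations[1]),
                            message = opt$message),
         ebes = ebes, spec = spec, method = method,
         data = data, pred_fn = pred_fn, pred_jac = pred_jac,
         native_ctx = native_ctx,
         n_obs = nrow(data), n_subjects = length(subjects),
         se_table = NULL, stage = "custom"),
    class = "htp_fit"
  )
  if (se) fit <- standard_errors(fit)
  fit
}

# Prepare the flattened per-subject arrays consumed by the compiled inner
# solver. `native` is a list(model, xcols, pord): the model id, the data
# columns forming the covariate matrix, and the parameter-name order the
# compiled model expects.
engine_native_prep <- function(subjects, spec, native) {
  pord <- native$pord
  stopifnot(all(pord %in% names(c(spec$theta, spec$fixed))),
            all(spec$iiv %in% pord), all(spec$iov %in% pord))
  subs <- lapply(subjects, function(s) {
    X <- do.call(cbind, lapply(native$xcols, function(cn) s$d[[cn]]))
    list(y = as.numeric(s$y), X = X, occ = as.integer(s$occ),
         n_occ = as.integer(s$n_occ))
  })
  list(model = as.integer(native$model), subjects = unname(subs),
       pord = pord,
       iiv_par = as.integer(match(spec$iiv, pord) - 1L),
       iov_par = as.integer(match(spec$iov, pord) - 1L))
}

# one bounded quasi-Newton run; used by the profile search, where many
# short re-optimisations are needed
engine_mini_opt <- function(subjects, spec2, pred_fn, pred_jac, method,
                            ctrl) {
  obj <- function(x) {
    pp <- engine_unpack(spec2, x)
    engine_ofv(subjects, pp$theta_all, spec2, pp$omega2, pp$iov2,
               pp$sigma_prop, pp$sigma_add, pred_fn, pred_jac,
               method = method)
  }
  x0 <- engine_pack(spec2, spec2$theta, spec2$omega2, spec2$iov2,
                    spec2$sigma_prop, spec2$sigma_add)
  b <- engine_bounds(spec2)
  opt <- stats::nlminb(x0, obj, lower = b$lower,
                       upper = b$upper, control = ctrl)
  list(opt = opt, pp = engine_unpack(spec2, opt$par))
}

# Profile-first search for one ridge-prone fixed effect: pin the parameter
# on a log-scale grid around its initial value, re-optimise all remaining
# parameters at each pin (warm-chained outward from the centre, so each
# conditional fit starts on the valley floor found by its neighbour), then
# release the pin and refit freely from the best grid point. Conditional
# fits are well behaved because the ridge direction is eliminated.
engine_profile_search <- function(subjects, spec, pred_fn, pred_jac,
                                  method, ctrl, profile, steps) {
  mini_ctrl <- utils::modifyList(ctrl,
                                 list(iter.max = 80L, eval.max = 320L))
  others <- setdiff(names(spec$theta), profile)
  base_val <- spec$theta[[profile]]
  spec_at <- function(val, pp) {
    me_spec(theta = pp$theta[others],
            fixed = c(spec$fixed, stats::setNames(val, profile)),
            transform = spec$transform[others],
            lower = spec$lower, upper = spec$upper,
            iiv = spec$iiv, omega2 = pp$omega2,
            iov = spec$iov, iov2 = if (length(spec$iov)) pp$iov2,
            re_dist = spec$re_dist,
            sigma_prop = pp$sigma_prop, sigma_add = pp$sigma_add)
  }
  fit_at <- function(val, pp) {
    tryCatch(engine_mini_opt(subjects, spec_at(val, pp), pred_fn,
                             pred_jac, method, mini_ctrl),
             error = function(e) NULL)
  }
  init_pp <- list(theta = spec$theta, omega2 = spec$omega2,
                  iov2 = spec$iov2, sigma_prop = spec$sigma_prop,
                  sigma_add = spec$sigma_add)
  r0 <- fit_at(base_val, init_pp)
  if (is.null(r0)) return(NULL)
  best <- r0
  best_val <- base_val
  for (sgn in c(-1, 1)) {
    pp_chain <- r0$pp
    for (s in sort(steps[sign(steps) == sgn] * sgn)) {
      val <- base_val * exp(sgn * s)
      r <- fit_at(val, pp_chain)
      if (is.null(r) || !is.finite(r$opt$objective)) break
      pp_chain <- r$pp
      if (r$opt$objective < best$opt$objective) {
        best <- r
        best_val <- val
      }
    }
  }
  theta_start <- c(best$pp$theta,
                   stats::setNames(best_val, profile))[names(spec$theta)]
  spec_f <- me_spec(theta = theta_start, fixed = spec$fixed,
                    transform = spec$transform,
                    lower = spec$lower, upper = spec$upper,
                    iiv = spec$iiv, omega2 = best$pp$omega2,
                    iov = spec$iov,
                    iov2 = if (length(spec$iov)) best$pp$iov2,
                    re_dist = spec$re_dist,
                    sigma_prop = best$pp$sigma_prop,
                    sigma_add = best$pp$sigma_add)
  tryCatch(engine_mini_opt(subjects, spec_f, pred_fn, pred_jac, method,
                           ctrl),
           error = function(e) NULL)
}

engine_all_ebes <- function(subjects, pp, spec, pred_fn,
                            pred_jac = NULL, native_ctx = NULL) {
  bvals <- if (!is.null(native_ctx)) {
    .engine_ebes_native(
      native_ctx$model, native_ctx$subjects,
      unname(pp$theta_all[native_ctx$pord]),
      native_ctx$iiv_par, native_ctx$iov_par,
      unname(pp$omega2), unname(pp$iov2),
      pp$sigma_prop, pp$sigma_add)
  }
  sp2 <- pp$sigma_prop^2; sa2 <- pp$sigma_add^2
  p0 <- as.list(pp$theta_all)
  plan <- engine_plan(spec)
  n_iiv <- length(spec$iiv)
  rows <- lapply(seq_along(subjects), function(i) {
    subj <- subjects[[i]]
    nb <- engine_b_dim(spec, subj$n_occ)
    if (nb == 0L) return(NULL)
    if (!is.null(bvals)) {
      sol <- list(b = bvals[[i]])
    } else {
      prec <- engine_prec(pp$omega2, pp$iov2, subj$n_occ)
      lpn <- sum(log(2 * pi / prec))
      sol <- engine_inner(numeric(nb), subj, p0, plan, n_iiv, prec, lpn,
                          sp2, sa2, pred_fn, pred_jac)
    }
    tibble::tibble(
      ID = subj$id,
      param = c(spec$iiv, rep(spec$iov, each = subj$n_occ)),
      type = c(rep("eta", n_iiv),
               rep("kappa", length(spec$iov) * subj$n_occ)),
      OCC = c(rep(NA, n_iiv), rep(subj$occ_levels,
                                  times = length(spec$iov))),
      value = sol$b
    )
  })
  dplyr::bind_rows(rows)
}

#' Empirical Bayes estimates of a subject's random effects
#'
#' MAP estimates of the per-subject deviations (eta, and kappa per occasion)
#' given population parameters: the maximiser of the conditional posterior.
#' A subject with no observations returns the prior mode (zero).
#'
#' @param data Observation rows (may contain several subjects).
#' @param pred_fn,spec As in [fit_population()].
#' @param theta,omega2,iov2,sigma_prop,sigma_add Population values (named
#'   where applicable); defaults come from the spec.
#' @return Tibble with columns `ID`, `param`, `type` (eta/kappa), `OCC`
#'   (kappa only) and `value`.
#' @export
compute_ebes <- function(data, pred_fn, spec, theta = NULL, omega2 = NULL,
                         iov2 = NULL, sigma_prop = NULL,
                         sigma_add = NULL, pred_jac = NULL) {
  th <- spec$theta
  if (!is.null(theta)) th[names(theta)] <- theta
  om <- spec$omega2
  if (!is.null(omega2)) om[names(omega2)] <- omega2
  ov <- spec$iov2
  if (!is.null(iov2)) ov[names(iov2)] <- iov2
  pp <- list(theta_all = c(th, spec$fixed), omega2 = om, iov2 = ov,
             sigma_prop = if (is.null(sigma_prop)) spec$sigma_prop
                          else sigma_prop,
             sigma_add = if (is.null(sigma_add)) spec$sigma_add
                         else sigma_add)
  subjects <- engine_split(data, spec)
  engine_all_ebes(subjects, pp, spec, pred_fn, pred_jac)
}

#' Standard errors from the curvature of the objective function
#'
#' Central finite-difference Hessian of OFV/2 at the optimum over all
#' estimated quantities (fixed effects, IIV/IOV variances, residual SDs),
#' with step 1e-4 x |estimate|; the covariance is its inverse and
#' RSE = 100 x SE / |estimate|. A non-positive-definite Hessian yields a
#' warning and missing SEs.
#'
#' @param fit An `htp_fit`.
#' @return The fit with its `se_table` filled in (tibble: parameter, type,
#'   estimate, se, rse).
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "htp_fit"))
  spec <- fit$spec
  subjects <- engine_split(fit$data, spec)
  est <- c(fit$theta,
           if (length(fit$omega2)) {
             stats::setNames(fit$omega2,
                             paste0("omega2_", names(fit$omega2)))
           },
           if (length(fit$iov2)) {
             stats::setNames(fit$iov2, paste0("iov2_", names(fit$iov2)))
           })
  type <- c(rep("theta", length(fit$theta)),
            rep("omega2", length(fit$omega2)),
            rep("iov2", length(fit$iov2)))
  if (spec$sigma_prop > 0) {
    est <- c(est, sigma_prop = unname(fit$sigma["prop"]))
    type <- c(type, "sigma")
  }
  if (spec$sigma_add > 0) {
    est <- c(est, sigma_add = unname(fit$sigma["add"]))
    type <- c(type, "sigma")
  }
  nt <- length(fit$theta); no <- length(fit$omega2); nv <- length(fit$iov2)
  half_ofv <- function(x) {
    th <- x[seq_len(nt)]
    om <- x[nt + seq_len(no)]
    ov <- x[nt + no + seq_len(nv)]
    i <- nt + no + nv
    sp <- spec$sigma_prop; sa <- spec$sigma_add
    if (sp > 0) { i <- i + 1L; sp <- x[i] }
    if (sa > 0) { i <- i + 1L; sa <- x[i] }
    if (any(om <= 0) || any(ov <= 0) || sp < 0 || sa < 0) return(NA_real_)
    names(th) <- names(fit$theta); names(om) <- names(fit$omega2)
    names(ov) <- names(fit$iov2)
    engine_ofv(subjects, c(th, spec$fixed), spec, om, ov, sp, sa,
               fit$pred_fn, fit$pred_jac, method = fit$method,
               native_ctx = fit$native_ctx) / 2
  }
  x <- unname(est)
  hstep <- pmax(1e-4 * abs(x), 1e-7)
  np <- length(x)
  H <- matrix(NA_real_, np, np)
  f0 <- half_ofv(x)
  for (i in seq_len(np)) {
    ei <- numeric(np); ei[i] <- hstep[i]
    H[i, i] <- (half_ofv(x + ei) - 2 * f0 + half_ofv(x - ei)) / hstep[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- numeric(np); ej[j] <- hstep[j]
        H[i, j] <- H[j, i] <-
          (half_ofv(x + ei + ej) - half_ofv(x + ei - ej) -
             half_ofv(x - ei + ej) + half_ofv(x - ei - ej)) /
          (4 * hstep[i] * hstep[j])
      }
    }
  }
  se <- rep(NA_real_, np)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) <= 0)) {
    warning("OFV Hessian is not positive definite; standard errors are ",
            "reported as missing.", call. = FALSE)
  } else {
    se <- sqrt(diag(cov))
  }
  fit$se_table <- tibble::tibble(
    parameter = names(est), type = type, estimate = unname(est),
    se = se, rse = 100 * se / abs(unname(est))
  )
  fit
}

#' Objective-function difference between nested fits
#'
#' `OFV_reduced - OFV_full`; under the usual asymptotics one extra parameter
#' is supported at the 5% level when the drop exceeds 3.84.
#'
#' @param fit_reduced,fit_full `htp_fit` objects fitted to identical data.
#' @return Scalar difference.
#' @export
delta_ofv <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "htp_fit"), inherits(fit_full, "htp_fit"))
  if (fit_reduced$n_obs != fit_full$n_obs ||
      !isTRUE(all.equal(sort(fit_reduced$data$DV), sort(fit_full$data$DV)))) {
    stop("Fits were not obtained on identical data; OFVs are not ",
         "comparable.", call. = FALSE)
  }
  fit_reduced$ofv - fit_full$ofv
}
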