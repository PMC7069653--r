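#' Configure the staged challenge-test analysis
#'
#' Options for [run_pipeline()]: the circadian period candidates, the
#' saliva-stage predictor and functional-form candidates, stage toggles,
#' whether to compute standard errors, the fixed reference clock time, and
#' the seed recorded in the report (the estimation itself is
#' deterministic).
#'
#' @param period_candidates Candidate cosine periods (h) for the baseline
#'   stage.
#' @param predictors Saliva-stage predictor candidates, subset of
#'   `c("free", "total")`.
#' @param forms Saliva-stage functional-form candidates, subset of
#'   `c("power", "linear")`.
#' @param run_saliva `NULL` (run when saliva observations exist), or
#'   TRUE/FALSE to force.
#' @param se Compute standard errors for the stage fits kept in the report.
#' @param tpeak Fixed reference clock time of the cosine (h).
#' @param seed Integer recorded in the report for provenance.
#' @return A classed list.
#' @export
pipeline_config <- function(period_candidates = c(4, 8, 12, 16, 24),
                            predictors = c("free", "total"),
                            forms = c("power", "linear"),
                            run_saliva = NULL, se = FALSE,
                            tpeak = 11.5, seed = 1L) {
  stopifnot(length(period_candidates) >= 1, all(period_candidates > 0),
            length(predictors) >= 1, length(forms) >= 1)
  predictors <- match.arg(predictors, c("free", "total"),
                          several.ok = TRUE)
  forms <- match.arg(forms, c("power", "linear"), several.ok = TRUE)
  structure(
    list(period_candidates = period_candidates, predictors = predictors,
         forms = forms, run_saliva = run_saliva, se = se, tpeak = tpeak,
         seed = seed),
    class = "pipeline_config"
  )
}

# dose amount per subject-occasion, from the dose event rows
dose_table <- function(data) {
  doses <- data[data$EVID == 1L, c("ID", "OCC", "AMT")]
  names(doses)[3] <- "DOSE"
  doses
}

# two-stage initialiser: cheap per-subject log-scale curve fits give the
# population fit starting values on the right side of the (ka, omega_ka)
# ridge that trips gradient optimisers started from generic values
pk_two_stage_init <- function(obs) {
  per_subject <- lapply(split(obs, obs$ID), function(d) {
    y <- d$DV[d$DV > 0]
    tad <- d$TAD[d$DV > 0]
    dose <- d$DOSE[d$DV > 0]
    if (length(y) < 3) return(NULL)
    ssq <- function(lp) {
      f <- pk_conc_vec(dose, tad, exp(lp[1]), exp(lp[3]), exp(lp[2]))
      sum((log(y) - log(pmax(f, 1e-8)))^2)
    }
    best <- NULL
    for (ka0 in c(0.5, 1.5, 4)) {
      o <- tryCatch(stats::nlminb(log(c(20, ka0, 100)), ssq),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$objective < best$objective)) {
        best <- o
      }
    }
    if (is.null(best)) NULL else exp(best$par)
  })
  mat <- do.call(rbind, Filter(Negate(is.null), per_subject))
  if (is.null(mat) || nrow(mat) < 2) {
    return(c(cl_f = 20, ka = 1.5, v_f = 100,
             omega2_cl_f = 0.1, omega2_ka = 0.1, sigma = 0.15))
  }
  lmat <- log(mat)
  med <- exp(apply(lmat, 2, stats::median))
  vv <- pmin(pmax(apply(lmat, 2, stats::var), 0.02), 1)
  c(cl_f = med[1], ka = med[2], v_f = med[3],
    omega2_cl_f = unname(vv[1]), omega2_ka = unname(vv[2]), sigma = 0.15)
}

#' Stage 1: population PK fit of 5-HTP
#'
#' Fits the transit-compartment oral model to the plasma 5-HTP
#' observations with IIV on CL/F and ka and a proportional residual error
#' (the final PK model structure). Initial estimates come from a two-stage
#' pass (per-subject curve fits, then medians and log-scale variances)
#' unless supplied explicitly. Empirical Bayes estimates are retained for
#' the sequential PD stage.
#'
#' @param data Challenge dataset tibble.
#' @param init Optional named initial values (`cl_f`, `ka`, `v_f`,
#'   `omega2_cl_f`, `omega2_ka`, `sigma`); any missing entry falls back to
#'   the two-stage value.
#' @param se Compute standard errors.
#' @param control Outer-optimiser control.
#' @return An `htp_fit` (stage `"pk"`).
#' @export
fit_pk <- function(data, init = NULL, se = FALSE, control = list()) {
  obs <- data[data$EVID == 0L & data$DVID == 1L & data$MDV == 0L, ]
  if (nrow(obs) == 0) {
    stop("PK stage: the dataset contains no 5-HTP observations (DVID 1).",
         call. = FALSE)
  }
  obs <- dplyr::inner_join(obs, dose_table(data), by = c("ID", "OCC"))
  if (nrow(obs) == 0) {
    stop("PK stage: no dose events match the 5-HTP observations.",
         call. = FALSE)
  }
  ini <- pk_two_stage_init(obs)
  if (!is.null(init)) ini[names(init)] <- init
  spec <- me_spec(
    theta = c(cl_f = unname(ini["cl_f"]), ka = unname(ini["ka"]),
              v_f = unname(ini["v_f"])),
    iiv = c("cl_f", "ka"),
    omega2 = c(cl_f = unname(ini["omega2_cl_f"]),
               ka = unname(ini["omega2_ka"])),
    sigma_prop = unname(ini["sigma"])
  )
  pred_fn <- function(p, d) pk_conc_vec(d$DOSE, d$TAD, p$cl_f, p$v_f, p$ka)
  fit <- fit_population(obs, pred_fn, spec, se = se, control = control,
                        pred_jac = pk_pred_jac,
                        native = list(model = 1L,
                                      xcols = c("DOSE", "TAD"),
                                      pord = c("cl_f", "v_f", "ka")))
  fit$stage <- "pk"
  fit
}

# derivative of (expm1(x) - x)/x^2; series guards the removable
# singularity
pk_hprime <- function(x) {
  out <- (x * expm1(x) - 2 * (expm1(x) - x)) / x^3
  small <- abs(x) < 1e-4
  if (any(small)) out[small] <- 1 / 6 + x[small] / 12 + x[small]^2 / 40
  out
}

# analytic derivatives of the transit-chain concentration with respect to
# the random-effect-carrying parameters (CL/F and ka)
pk_pred_jac <- function(p, d) {
  cl <- p$cl_f; v <- p$v_f; ka <- p$ka
  t <- d$TAD
  ke <- cl / v
  x <- (ka - ke) * t
  h <- (expm1(x) - x) / (x * x)
  sm <- abs(x) < 1e-8
  if (any(sm)) h[sm] <- 0.5 + x[sm] / 6
  hp <- pk_hprime(x)
  base <- 1000 * d$DOSE / v * t * t * exp(-ka * t)
  f <- base * ka * ka * h
  list(cl_f = -base * ka * ka * hp * t / v,
       ka = f * (2 / ka - t) + base * ka * ka * hp * t)
}

# individual 5-HTP concentration from the PK stage empirical Bayes
# estimates; rows of `at` need ID, TAD and DOSE
pk_individual_conc <- function(pk_fit, at) {
  eta <- tidyr::pivot_wider(
    pk_fit$ebes[pk_fit$ebes$type == "eta", c("ID", "param", "value")],
    names_from = "param", values_from = "value")
  idx <- match(at$ID, eta$ID)
  cl_i <- pk_fit$theta[["cl_f"]] * exp(eta$cl_f[idx])
  ka_i <- pk_fit$theta[["ka"]] * exp(eta$ka[idx])
  pk_conc_vec(at$DOSE, at$TAD, cl_i, pk_fit$theta[["v_f"]], ka_i)
}

#' Stage 2: circadian baseline fit on placebo data with period selection
#'
#' Fits the cosine-plus-trend baseline to the placebo-occasion serum
#' cortisol, with IIV on all four baseline parameters (BSL0, amplitude,
#' trend, Tpeak) and proportional residual error, once per candidate
#' period; the period with the smallest OFV wins (ties within 0.01 go to
#' the smaller period). Tpeak's typical value is fixed; only its
#' variability is estimated. With a single placebo occasion per subject a
#' per-occasion deviation on BSL0 is not separable from the per-subject
#' one, so IOV enters at the joint PD stage instead.
#'
#' @param data Challenge dataset tibble.
#' @param period_candidates Candidate periods (h).
#' @param tpeak Fixed reference clock time (h).
#' @param include_trend Include the linear decline term (`FALSE` fits the
#'   pure cosinor model, e.g. for a likelihood-ratio comparison).
#' @param init Optional named initials (`bsl0`, `amp`, `trend`, omega2s,
#'   `sigma`); `bsl0` defaults to the placebo median.
#' @param se,control As in [fit_pk()].
#' @return An `htp_fit` (stage `"baseline"`) with `$period` and
#'   `$selection` (tibble of period vs OFV).
#' @export
fit_baseline <- function(data, period_candidates = c(4, 8, 12, 16, 24),
                         tpeak = 11.5, include_trend = TRUE, init = NULL,
                         se = FALSE, control = list()) {
  obs <- data[data$EVID == 0L & data$DVID == 2L & data$MDV == 0L &
                data$TRT == 0L, ]
  if (nrow(obs) == 0) {
    stop("Baseline stage: no placebo-occasion serum cortisol records.",
         call. = FALSE)
  }
  ini <- c(bsl0 = stats::median(obs$DV), amp = -0.2, trend = 1,
           omega2_bsl0 = 0.05, omega2_amp = 0.05, omega2_trend = 0.05,
           omega2_tpeak = 0.02, sigma = 0.1)
  if (!is.null(init)) ini[names(init)] <- init
  make_spec <- function(start, period) {
    theta <- c(bsl0 = unname(start["bsl0"]), amp = unname(start["amp"]))
    fixed <- c(tpeak = tpeak, s0 = 0, period = period)
    if (include_trend) {
      theta <- c(theta, trend = unname(start["trend"]))
    } else {
      fixed <- c(fixed, trend = 0)
    }
    me_spec(
      theta = theta, fixed = fixed,
      transform = c(amp = "identity"),
      lower = c(amp = -0.99), upper = c(amp = 0.99),
      iiv = c("bsl0", "amp", if (include_trend) "trend", "tpeak"),
      omega2 = c(bsl0 = unname(start["omega2_bsl0"]),
                 amp = unname(start["omega2_amp"]),
                 if (include_trend) c(trend = unname(start["omega2_trend"])),
                 tpeak = unname(start["omega2_tpeak"])),
      sigma_prop = unname(start["sigma"])
    )
  }
  obs$C5HTP <- 0
  pred_fn <- function(p, d) {
    circadian_vec(d$CLOCK, p$bsl0, p$amp, p$tpeak, p$trend, p$period)
  }
  pred_jac <- function(p, d) circadian_jac(d$CLOCK, p, p$period)
  native <- list(model = 2L, xcols = c("CLOCK", "C5HTP"),
                 pord = c("bsl0", "amp", "tpeak", "trend", "s0", "period"))
  fits <- vector("list", length(period_candidates))
  for (k in seq_along(period_candidates)) {
    fits[[k]] <- fit_population(obs, pred_fn,
                                make_spec(ini, period_candidates[k]),
                                control = control, pred_jac = pred_jac,
                                native = native)
  }
  ofv <- vapply(fits, function(f) f$ofv, numeric(1))
  best_ofv <- min(ofv)
  tied <- which(ofv <= best_ofv + 0.01)
  pick <- tied[which.min(period_candidates[tied])]
  fit <- fits[[pick]]
  if (se) fit <- standard_errors(fit)
  fit$stage <- "baseline"
  fit$period <- period_candidates[pick]
  fit$selection <- tibble::tibble(
    period = period_candidates, ofv = ofv,
    selected = seq_along(ofv) == pick)
  fit
}

# analytic derivatives of the cosine-plus-trend baseline with respect to
# its four parameters
circadian_jac <- function(clock, p, n) {
  w <- 2 * pi / n
  dt <- clock - p$tpeak
  cs <- cos(w * dt)
  level <- p$bsl0 - p$trend * dt
  C <- 1 + p$amp * cs
  list(bsl0 = C,
       amp = level * cs,
       trend = -dt * C,
       tpeak = p$trend * C + level * p$amp * sin(w * dt) * w)
}

#' Stage 3: joint baseline + drug-effect fit on all serum cortisol
#'
#' Sequential PK/PD estimation: each subject's 5-HTP concentration curve is
#' fixed at the PK-stage empirical Bayes prediction, and the cortisol model
#' `E = BSL(clock) + S0 * C5HTP` is fitted to the combined placebo and
#' treatment serum cortisol, re-estimating the baseline parameters jointly
#' with S0 (initialised at the placebo-stage estimates). IIV is carried on
#' all four baseline parameters and S0; inter-occasion variability on BSL0
#' captures day-to-day baseline shifts; proportional residual error.
#' Subjects with treatment cortisol but no PK estimates are dropped with a
#' warning.
#'
#' @param data Challenge dataset tibble.
#' @param pk_fit The stage-1 `htp_fit` (frozen; never re-estimated here).
#' @param baseline_fit Optional stage-2 `htp_fit` supplying the period and
#'   initial values.
#' @param period Cosine period (h) when no `baseline_fit` is given.
#' @param form `"linear"` (default) or `"emax"`. The saturating form is
#'   refused when the dataset contains a single dose level - one dose
#'   cannot identify Emax and EC50 separately - unless `force = TRUE`.
#' @param force Override the single-dose-level refusal.
#' @param tpeak Fixed reference clock time (h).
#' @param init Optional named initials (override the baseline-stage ones).
#' @param se,control As in [fit_pk()].
#' @return An `htp_fit` (stage `"pd"`) with `$period`.
#' @export
fit_pd <- function(data, pk_fit, baseline_fit = NULL, period = 8,
                   form = c("linear", "emax"), force = FALSE,
                   tpeak = 11.5, init = NULL, se = FALSE, control = list()) {
  form <- match.arg(form)
  stopifnot(inherits(pk_fit, "htp_fit"))
  obs <- data[data$EVID == 0L & data$DVID == 2L & data$MDV == 0L, ]
  if (nrow(obs) == 0) {
    stop("PD stage: no serum cortisol records.", call. = FALSE)
  }
  doses <- dose_table(data)
  if (form == "emax" && length(unique(doses$DOSE)) < 2 && !force) {
    stop("PD stage: a single dose level cannot identify Emax and EC50 ",
         "separately; fit the linear approximation instead, or use ",
         "`force = TRUE`.", call. = FALSE)
  }
  obs <- dplyr::left_join(obs, doses, by = c("ID", "OCC"))
  have_eta <- unique(pk_fit$ebes$ID)
  need_eta <- unique(obs$ID[obs$TRT == 1L])
  orphans <- setdiff(need_eta, have_eta)
  if (length(orphans)) {
    warning("PD stage: dropping subject(s) without PK estimates: ",
            paste(orphans, collapse = ", "), call. = FALSE)
    obs <- obs[!obs$ID %in% orphans, ]
  }
  obs$C5HTP <- 0
  trt <- obs$TRT == 1L
  obs$C5HTP[trt] <- pk_individual_conc(pk_fit, obs[trt, ])
  if (!is.null(baseline_fit)) {
    period <- baseline_fit$period %||% period
    tpeak <- baseline_fit$theta_all[["tpeak"]]
  }
  plc <- obs$DV[obs$TRT == 0L]
  ini <- c(bsl0 = stats::median(if (length(plc)) plc else obs$DV),
           amp = -0.2, trend = 1, s0 = 0.05,
           omega2_bsl0 = 0.05, omega2_amp = 0.05, omega2_trend = 0.05,
           omega2_tpeak = 0.02, omega2_s0 = 0.1, iov2_bsl0 = 0.05,
           sigma = 0.1)
  if (!is.null(baseline_fit)) {
    ini[c("bsl0", "amp", "trend")] <-
      baseline_fit$theta[c("bsl0", "amp", "trend")]
    ini[paste0("omega2_", names(baseline_fit$omega2))] <-
      baseline_fit$omega2
    ini["sigma"] <- baseline_fit$sigma[["prop"]]
  }
  if (!is.null(init)) ini[names(init)] <- init
  if (form == "linear") {
    theta <- c(bsl0 = unname(ini["bsl0"]), amp = unname(ini["amp"]),
               trend = unname(ini["trend"]), s0 = unname(ini["s0"]))
    drug_names <- "s0"
  } else {
    theta <- c(bsl0 = unname(ini["bsl0"]), amp = unname(ini["amp"]),
               trend = unname(ini["trend"]), emax = 100, ec50 = 2000)
    drug_names <- c("emax", "ec50")
  }
  spec <- me_spec(
    theta = theta,
    fixed = if (form == "linear") {
      c(tpeak = tpeak, period = period)
    } else {
      c(tpeak = tpeak)
    },
    transform = c(amp = "identity"),
    lower = c(amp = -0.99), upper = c(amp = 0.99),
    iiv = c("bsl0", "amp", "trend", "tpeak",
            if (form == "linear") "s0"),
    omega2 = c(bsl0 = unname(ini["omega2_bsl0"]),
               amp = unname(ini["omega2_amp"]),
               trend = unname(ini["omega2_trend"]),
               tpeak = unname(ini["omega2_tpeak"]),
               if (form == "linear") c(s0 = unname(ini["omega2_s0"]))),
    iov = "bsl0", iov2 = c(bsl0 = unname(ini["iov2_bsl0"])),
    sigma_prop = unname(ini["sigma"])
  )
  if (form == "linear") {
    pred_fn <- function(p, d) {
      circadian_vec(d$CLOCK, p$bsl0, p$amp, p$tpeak, p$trend, p$period) +
        p$s0 * d$C5HTP
    }
    pred_jac <- function(p, d) {
      out <- circadian_jac(d$CLOCK, p, p$period)
      out$s0 <- d$C5HTP
      out
    }
    native <- list(model = 2L, xcols = c("CLOCK", "C5HTP"),
                   pord = c("bsl0", "amp", "tpeak", "trend", "s0",
                            "period"))
  } else {
    pred_fn <- local({
      n <- period
      function(p, d) {
        circadian_vec(d$CLOCK, p$bsl0, p$amp, p$tpeak, p$trend, n) +
          p$emax * d$C5HTP / (p$ec50 + d$C5HTP)
      }
    })
    pred_jac <- NULL
    native <- NULL
  }
  fit <- fit_population(obs, pred_fn, spec, se = se, control = control,
                        pred_jac = pred_jac, native = native)
  fit$stage <- "pd"
  fit$period <- period
  fit$form <- form
  fit
}

#' Stage 4: saliva-serum cortisol link with predictor and form selection
#'
#' Fits `Csal = beta * Ccol^gamma` (IIV on beta, proportional residual
#' error; `gamma` fixed at 1 for the linear form) to the saliva cortisol
#' observations, where the serum predictor `Ccol` is the individual
#' model-predicted total serum cortisol from the PD stage - used directly
#' (converted to nmol/L) or converted to free cortisol by the Coolens
#' calculation with the subject's CBG. All requested predictor x form
#' combinations are fitted and ranked by OFV.
#'
#' @param data Challenge dataset tibble.
#' @param pd_fit The stage-3 `htp_fit` (supplies individual serum cortisol
#'   predictions).
#' @param pk_fit The stage-1 `htp_fit` (needed to rebuild the 5-HTP
#'   covariate at saliva sampling times).
#' @param predictors,forms Candidate sets (see [pipeline_config()]).
#' @param se,control As in [fit_pk()].
#' @return An `htp_fit` (stage `"saliva"`) for the winning combination,
#'   with `$predictor`, `$form` and `$selection`.
#' @export
fit_saliva <- function(data, pd_fit, pk_fit,
                       predictors = c("free", "total"),
                       forms = c("power", "linear"),
                       se = FALSE, control = list()) {
  predictors <- match.arg(predictors, c("free", "total"), several.ok = TRUE)
  forms <- match.arg(forms, c("power", "linear"), several.ok = TRUE)
  obs <- data[data$EVID == 0L & data$DVID == 3L & data$MDV == 0L, ]
  if (nrow(obs) == 0) {
    stop("Saliva stage: no saliva cortisol records (DVID 3).",
         call. = FALSE)
  }
  if ("free" %in% predictors && any(is.na(obs$CBG))) {
    stop("Saliva stage: the free-cortisol predictor needs CBG for every ",
         "saliva subject.", call. = FALSE)
  }
  obs <- dplyr::left_join(obs, dose_table(data), by = c("ID", "OCC"))
  obs$C5HTP <- 0
  trt <- obs$TRT == 1L
  obs$C5HTP[trt] <- pk_individual_conc(pk_fit, obs[trt, ])
  serum <- predict_individual(pd_fit, obs)
  total_ngml <- pmax(serum$ipred, 0)
  obs$CCOL_TOTAL <- convert_units(total_ngml, "cortisol_ngml_to_nmoll")
  obs$CCOL_FREE <- 1000 * free_cortisol_coolens(
    convert_units(total_ngml, "cortisol_ngml_to_umoll"),
    convert_units(obs$CBG, "cbg_mgl_to_umoll"))
  combos <- expand.grid(predictor = predictors, form = forms,
                        stringsAsFactors = FALSE)
  fits <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    predictor <- combos$predictor[k]
    form <- combos$form[k]
    d <- obs
    d$CCOL <- if (predictor == "free") d$CCOL_FREE else d$CCOL_TOTAL
    gamma0 <- if (form == "power") 1.2 else 1
    beta0 <- stats::median(d$DV) / stats::median(d$CCOL)^gamma0
    spec <- if (form == "power") {
      me_spec(theta = c(beta = beta0, gamma = gamma0), iiv = "beta",
              omega2 = c(beta = 0.1), sigma_prop = 0.2)
    } else {
      me_spec(theta = c(beta = beta0), fixed = c(gamma = 1), iiv = "beta",
              omega2 = c(beta = 0.1), sigma_prop = 0.2)
    }
    pred_fn <- function(p, d) p$beta * d$CCOL^p$gamma
    pred_jac <- function(p, d) list(beta = d$CCOL^p$gamma)
    fits[[k]] <- fit_population(d, pred_fn, spec, control = control,
                                pred_jac = pred_jac,
                                native = list(model = 3L, xcols = "CCOL",
                                              pord = c("beta", "gamma")))
  }
  ofv <- vapply(fits, function(f) f$ofv, numeric(1))
  pick <- which.min(ofv)
  fit <- fits[[pick]]
  if (se) fit <- standard_errors(fit)
  fit$stage <- "saliva"
  fit$predictor <- combos$predictor[pick]
  fit$form <- combos$form[pick]
  fit$selection <- tibble::tibble(
    predictor = combos$predictor, form = combos$form, ofv = ofv,
    selected = seq_along(ofv) == pick)
  fit
}

#' Run the full staged analysis
#'
#' Executes the stages in order - PK fit, placebo baseline fit with period
#' selection, joint baseline+PD fit, saliva-link fit with predictor and
#' form selection - and collects the fits, the selections and a combined
#' parameter table. The saliva stage is skipped automatically when the
#' dataset contains no saliva observations (or when toggled off). The
#' whole report is reproducible from the dataset and configuration.
#'
#' @param data Challenge dataset tibble (see [read_challenge_dataset()]).
#' @param config A [pipeline_config()].
#' @return An object of class `htp_report`; see [tidy.htp_report()].
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- validate_challenge_dataset(data)
  pk <- fit_pk(data, se = config$se)
  baseline <- fit_baseline(data,
                           period_candidates = config$period_candidates,
                           tpeak = config$tpeak)
  pd <- fit_pd(data, pk_fit = pk, baseline_fit = baseline, se = config$se)
  run_sal <- config$run_saliva
  if (is.null(run_sal)) {
    run_sal <- any(data$EVID == 0L & data$DVID == 3L & data$MDV == 0L)
  }
  saliva <- NULL
  if (isTRUE(run_sal)) {
    saliva <- fit_saliva(data, pd_fit = pd, pk_fit = pk,
                         predictors = config$predictors,
                         forms = config$forms, se = config$se)
  }
  report <- structure(
    list(pk = pk, baseline = baseline, pd = pd, saliva = saliva,
         period = baseline$period,
         saliva_predictor = saliva$predictor %||% NA_character_,
         saliva_form = saliva$form %||% NA_character_,
         config = config),
    class = "htp_report"
  )
  report
}

#' Combined parameter table of a pipeline report
#'
#' One row per estimated quantity across the stage models, in the layout of
#' a population parameter table: model block, parameter, estimate, RSE%,
#' IIV variance (omega^2) and IOV variance where applicable.
#'
#' @param x An `htp_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.htp_report <- function(x, ...) {
  block <- function(fit, model) {
    if (is.null(fit)) return(NULL)
    tab <- tidy(fit)
    theta_tab <- tab[tab$type == "theta" | tab$type == "sigma", ]
    out <- tibble::tibble(
      model = model, parameter = theta_tab$parameter,
      estimate = theta_tab$estimate, rse = theta_tab$rse,
      omega2 = NA_real_, iov2 = NA_real_)
    for (nm in names(fit$omega2)) {
      out$omega2[out$parameter == nm] <- fit$omega2[[nm]]
    }
    for (nm in names(fit$iov2)) {
      out$iov2[out$parameter == nm] <- fit$iov2[[nm]]
    }
    # random effects anchored on fixed typical values (e.g. tpeak) still
    # deserve a row
    anchored <- setdiff(names(fit$omega2), out$parameter)
    if (length(anchored)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        model = model, parameter = anchored,
        estimate = fit$theta_all[anchored], rse = NA_real_,
        omega2 = unname(fit$omega2[anchored]), iov2 = NA_real_))
    }
    out
  }
  dplyr::bind_rows(
    block(x$pk, "5-HTP PK"),
    block(x$pd, "cortisol circadian + PD"),
    block(x$saliva, "saliva cortisol")
  )
}

#' @export
print.htp_report <- function(x, ...) {
  cat("<htp_report> staged challenge-test analysis\n")
  cat("  selected period:", x$period, "h\n")
  if (!is.null(x$saliva)) {
    cat("  saliva link:", x$saliva_form, "on", x$saliva_predictor,
        "cortisol\n")
  } else {
    cat("  saliva stage: not run\n")
  }
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Write the pipeline parameter table as delimited text
#'
#' @param report An `htp_report`.
#' @param path Output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(report, path) {
  tab <- tidy(report)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
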