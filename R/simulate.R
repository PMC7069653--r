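#' Design of a simulated 5-HTP challenge trial
#'
#' Describes a pooled set of crossover challenge studies: per-study subject
#' counts and saliva availability, dosing, and the sampling grids. The
#' defaults emulate the pooled dataset the analysis is meant for: 35 male
#' subjects across three studies (13/11/11, saliva collected in two of the
#' three), a single 200 mg oral 5-HTP dose per treatment occasion, about 8
#' plasma 5-HTP samples over 0-9 h post dose, about 11 serum cortisol
#' samples per occasion over clock times 11:00-20:00, 8 saliva samples per
#' occasion, and subject CBG drawn from a truncated normal with mean 45.94
#' and SD 5.94 mg/L.
#'
#' @param studies Tibble with columns `study` (id), `n_subjects`, `saliva`
#'   (logical: saliva sampled in that study).
#' @param dose Oral 5-HTP dose (mg), > 0.
#' @param dose_clock Clock time of administration (decimal h).
#' @param pk_tad Times after dose (h) of the 5-HTP plasma samples
#'   (treatment occasions only).
#' @param cortisol_clock Clock times (h) of the serum cortisol samples
#'   (every occasion).
#' @param saliva_clock Clock times (h) of the saliva samples (saliva
#'   studies only).
#' @param cbg_mean,cbg_sd CBG distribution (mg/L), truncated at 0.
#' @return A classed list describing the design.
#' @export
trial_design <- function(studies = tibble::tibble(
                           study = c("STUDY-A", "STUDY-B", "STUDY-C"),
                           n_subjects = c(13L, 11L, 11L),
                           saliva = c(FALSE, TRUE, TRUE)),
                         dose = 200,
                         dose_clock = 11,
                         pk_tad = c(0.5, 1, 1.5, 2, 3, 4, 6, 9),
                         cortisol_clock = c(11, 11.5, 12, 12.5, 13, 14, 15,
                                            16, 17, 18.5, 20),
                         saliva_clock = c(11, 12, 13, 14, 15, 16, 18, 20),
                         cbg_mean = 45.94, cbg_sd = 5.94) {
  stopifnot(all(c("study", "n_subjects", "saliva") %in% names(studies)),
            nrow(studies) >= 1)
  if (sum(studies$n_subjects) < 2) {
    stop("Need at least 2 subjects in total.", call. = FALSE)
  }
  check_positive(c(dose = dose))
  if (any(pk_tad <= 0)) {
    stop("`pk_tad` must be > 0 (a pre-dose 5-HTP sample carries no signal ",
         "under a proportional error model).", call. = FALSE)
  }
  clocks <- c(dose_clock, cortisol_clock, saliva_clock,
              dose_clock + max(pk_tad))
  if (any(clocks < 0) || any(clocks >= 24)) {
    stop("All sampling must fall within a single day (clock in [0, 24)).",
         call. = FALSE)
  }
  if (cbg_sd < 0) stop("`cbg_sd` must be >= 0.", call. = FALSE)
  structure(
    list(studies = studies, dose = dose, dose_clock = dose_clock,
         pk_tad = pk_tad, cortisol_clock = cortisol_clock,
         saliva_clock = saliva_clock, cbg_mean = cbg_mean, cbg_sd = cbg_sd),
    class = "trial_design"
  )
}

#' Generating parameter values for a simulated trial
#'
#' The full set of population values, variability terms and residual SDs
#' used by [simulate_trial()]. The defaults are the final challenge-test
#' model estimates: CL/F 20.40 L/h (omega^2 0.16), ka 1.89/h (omega^2 0.38),
#' V/F 102 L, PK proportional SD 0.11; baseline BSL0 88.6 ng/mL (omega^2
#' 0.056, IOV variance 0.049), amplitude -0.23 (omega^2 0.086), trend 4.16
#' ng/mL/h (omega^2 0.17), Tpeak 11.5 h (omega^2 0.021), period 8 h; S0
#' 0.072 (omega^2 0.31), PD proportional SD 0.069; saliva link beta 1.01
#' (omega^2 0.081), gamma 1.10, saliva proportional SD 0.23. Any component
#' can be overridden (set variabilities to 0 for noise-free data).
#'
#' @param pk,circadian,link Structural parameter bundles
#'   ([pk_params()], [circadian_params()], [saliva_link_params()]).
#' @param pk_omega2 Named IIV variances for `cl_f` and `ka`.
#' @param pk_sigma Proportional residual SD of the 5-HTP observations.
#' @param circadian_omega2 Named IIV variances for `bsl0`, `amp`, `trend`,
#'   `tpeak`.
#' @param bsl0_iov2 Inter-occasion variance on `bsl0`.
#' @param s0 Linear stimulation slope.
#' @param s0_omega2 IIV variance of `s0`.
#' @param pd_sigma Proportional residual SD of serum cortisol.
#' @param beta_omega2 IIV variance of the saliva scale factor.
#' @param saliva_sigma Proportional residual SD of saliva cortisol.
#' @return A classed list of generating values.
#' @export
truth_params <- function(pk = pk_params(cl_f = 20.40, v_f = 102, ka = 1.89),
                         pk_omega2 = c(cl_f = 0.16, ka = 0.38),
                         pk_sigma = 0.11,
                         circadian = circadian_params(bsl0 = 88.6,
                                                      amp = -0.23,
                                                      tpeak = 11.5,
                                                      trend = 4.16,
                                                      period = 8),
                         circadian_omega2 = c(bsl0 = 0.056, amp = 0.086,
                                              trend = 0.17, tpeak = 0.021),
                         bsl0_iov2 = 0.049,
                         s0 = 0.072, s0_omega2 = 0.31, pd_sigma = 0.069,
                         link = saliva_link_params(beta = 1.01,
                                                   gamma = 1.10),
                         beta_omega2 = 0.081, saliva_sigma = 0.23) {
  stopifnot(inherits(pk, "pk_params"), inherits(circadian, "circadian_params"),
            inherits(link, "saliva_link_params"))
  vars <- c(pk_omega2, circadian_omega2, bsl0_iov2 = bsl0_iov2,
            s0_omega2 = s0_omega2, beta_omega2 = beta_omega2,
            pk_sigma = pk_sigma, pd_sigma = pd_sigma,
            saliva_sigma = saliva_sigma)
  if (any(vars < 0)) {
    stop("Variability terms must be >= 0.", call. = FALSE)
  }
  if (s0 < 0) stop("`s0` must be >= 0.", call. = FALSE)
  structure(
    list(pk = pk, pk_omega2 = pk_omega2, pk_sigma = pk_sigma,
         circadian = circadian, circadian_omega2 = circadian_omega2,
         bsl0_iov2 = bsl0_iov2, s0 = s0, s0_omega2 = s0_omega2,
         pd_sigma = pd_sigma, link = link, beta_omega2 = beta_omega2,
         saliva_sigma = saliva_sigma),
    class = "truth_params"
  )
}

#' Draw subject CBG concentrations
#'
#' Truncated-normal (> 0) CBG draws in mg/L; with the default mean 45.94
#' and SD 5.94 the truncation is essentially inactive.
#'
#' @param n Number of subjects.
#' @param seed Optional integer seed (draws are reproducible per seed).
#' @param mean,sd Distribution parameters (mg/L).
#' @return Numeric vector of length `n`, all > 0.
#' @export
sample_cbg <- function(n, seed = NULL, mean = 45.94, sd = 5.94) {
  stopifnot(n >= 1, sd >= 0)
  draw <- function() {
    x <- stats::rnorm(n, mean, sd)
    for (i in 1:100) {
      bad <- x <= 0
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# proportional-noise draw; negative results are resampled (not truncated)
# to avoid low-concentration bias
draw_proportional <- function(pred, sigma) {
  if (sigma == 0) return(pred)
  dv <- pred * (1 + stats::rnorm(length(pred), 0, sigma))
  for (i in 1:100) {
    bad <- dv < 0
    if (!any(bad)) break
    dv[bad] <- pred[bad] * (1 + stats::rnorm(sum(bad), 0, sigma))
  }
  dv
}

#' Simulate a pooled crossover challenge-test dataset
#'
#' Generates an event-record dataset with the statistical structure the
#' staged analysis assumes: per-subject log-normal deviations on CL/F, ka,
#' all four baseline parameters, S0 and beta; a per-occasion deviation on
#' BSL0; 5-HTP kinetics on treatment occasions; serum total cortisol as
#' circadian baseline plus linear stimulation; saliva cortisol as the power
#' link applied to Coolens free cortisol computed from the noise-free
#' simulated total cortisol and the subject's CBG; and proportional
#' residual noise on every observation (negative draws are resampled).
#' Crossover order (placebo first or second) is randomised per subject.
#'
#' @param design A [trial_design()].
#' @param truth A [truth_params()].
#' @param seed Integer seed; the dataset is byte-identical per seed.
#' @return A challenge dataset tibble (see [read_challenge_dataset()] for
#'   the column dictionary).
#' @export
simulate_trial <- function(design = trial_design(), truth = truth_params(),
                           seed = 1L) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "truth_params"))
  withr::with_seed(seed, simulate_trial_impl(design, truth))
}

simulate_trial_impl <- function(design, truth) {
  studies <- design$studies
  study_of <- rep(studies$study, studies$n_subjects)
  saliva_of <- rep(studies$saliva, studies$n_subjects)
  n <- length(study_of)
  cbg <- sample_cbg(n, seed = NULL, mean = design$cbg_mean,
                    sd = design$cbg_sd)
  tp <- truth
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    eta <- function(v) if (v > 0) stats::rnorm(1, 0, sqrt(v)) else 0
    # redraw a subject whose noise-free cortisol curve dips below zero in
    # the sampling window (extreme trend/baseline combinations are not
    # physiologically admissible under the trended cosinor model)
    for (try in 1:200) {
      cl_i <- tp$pk$cl_f * exp(eta(tp$pk_omega2[["cl_f"]]))
      ka_i <- tp$pk$ka * exp(eta(tp$pk_omega2[["ka"]]))
      bsl0_i <- tp$circadian$bsl0 * exp(eta(tp$circadian_omega2[["bsl0"]]))
      amp_i <- tp$circadian$amp * exp(eta(tp$circadian_omega2[["amp"]]))
      trend_i <- tp$circadian$trend *
        exp(eta(tp$circadian_omega2[["trend"]]))
      tpeak_i <- tp$circadian$tpeak *
        exp(eta(tp$circadian_omega2[["tpeak"]]))
      s0_i <- tp$s0 * exp(eta(tp$s0_omega2))
      beta_i <- tp$link$beta * exp(eta(tp$beta_omega2))
      kap_occ <- c(eta(tp$bsl0_iov2), eta(tp$bsl0_iov2))
      clocks <- sort(unique(c(design$cortisol_clock, design$saliva_clock)))
      ok <- all(vapply(kap_occ, function(kap) {
        min(circadian_vec(clocks, bsl0_i * exp(kap), amp_i, tpeak_i,
                          trend_i, tp$circadian$period)) > 0
      }, logical(1)))
      if (ok) break
      if (try == 200) stop("Could not draw an admissible subject; check ",
                           "the variability settings.", call. = FALSE)
    }
    trt_first <- stats::runif(1) < 0.5
    occ_rows <- vector("list", 2L)
    for (occ in 1:2) {
      trt <- as.integer(if (trt_first) occ == 1 else occ == 2)
      bsl0_io <- bsl0_i * exp(kap_occ[occ])
      tad_cort <- design$cortisol_clock - design$dose_clock
      c5_cort <- if (trt == 1) {
        pk_conc_vec(design$dose, tad_cort, cl_i, tp$pk$v_f, ka_i)
      } else {
        numeric(length(tad_cort))
      }
      bsl <- circadian_vec(design$cortisol_clock, bsl0_io, amp_i, tpeak_i,
                           trend_i, tp$circadian$period)
      total_true <- bsl + s0_i * c5_cort
      parts <- list()
      if (trt == 1) {
        parts$dose <- tibble::tibble(
          EVID = 1L, AMT = design$dose, TAD = 0,
          CLOCK = design$dose_clock, DVID = NA_integer_, DV = NA_real_,
          MDV = 1L)
        conc <- pk_conc_vec(design$dose, design$pk_tad, cl_i, tp$pk$v_f,
                            ka_i)
        parts$pk <- tibble::tibble(
          EVID = 0L, AMT = NA_real_, TAD = design$pk_tad,
          CLOCK = design$dose_clock + design$pk_tad, DVID = 1L,
          DV = draw_proportional(conc, tp$pk_sigma), MDV = 0L)
      }
      parts$cortisol <- tibble::tibble(
        EVID = 0L, AMT = NA_real_, TAD = tad_cort,
        CLOCK = design$cortisol_clock, DVID = 2L,
        DV = draw_proportional(total_true, tp$pd_sigma), MDV = 0L)
      if (saliva_of[i]) {
        idx <- match(design$saliva_clock, design$cortisol_clock)
        total_sal <- if (all(!is.na(idx))) total_true[idx] else {
          tad_sal <- design$saliva_clock - design$dose_clock
          c5_sal <- if (trt == 1) {
            pk_conc_vec(design$dose, tad_sal, cl_i, tp$pk$v_f, ka_i)
          } else 0
          circadian_vec(design$saliva_clock, bsl0_io, amp_i, tpeak_i,
                        trend_i, tp$circadian$period) + s0_i * c5_sal
        }
        free_umol <- free_cortisol_coolens(
          convert_units(total_sal, "cortisol_ngml_to_umoll"),
          convert_units(cbg[i], "cbg_mgl_to_umoll"))
        sal_true <- beta_i * (free_umol * 1000)^tp$link$gamma
        parts$saliva <- tibble::tibble(
          EVID = 0L, AMT = NA_real_,
          TAD = design$saliva_clock - design$dose_clock,
          CLOCK = design$saliva_clock, DVID = 3L,
          DV = draw_proportional(sal_true, tp$saliva_sigma), MDV = 0L)
      }
      occ_d <- dplyr::bind_rows(parts)
      occ_d$OCC <- occ
      occ_d$TRT <- trt
      occ_rows[[occ]] <- occ_d
    }
    d <- dplyr::bind_rows(occ_rows)
    d$STUDY <- study_of[i]
    d$ID <- i
    d$CBG <- cbg[i]
    rows[[i]] <- d
  }
  out <- dplyr::bind_rows(rows)
  out[, c("STUDY", "ID", "OCC", "TRT", "EVID", "AMT", "TAD", "CLOCK",
          "DVID", "DV", "CBG", "MDV")]
}

#' Noise-free typical-subject curves
#'
#' Population (typical-subject) trajectories of all three observation types
#' on a dense grid, for test oracles and predictive-check overlays: 5-HTP
#' concentration after dosing, serum total cortisol on placebo and
#' treatment occasions, and saliva cortisol derived from the free fraction
#' of the typical total cortisol at the typical CBG.
#'
#' @param design A [trial_design()].
#' @param truth A [truth_params()].
#' @param n_grid Number of grid points over the sampling window.
#' @return Tibble with columns `type` (`htp`, `cortisol`, `saliva`), `TRT`,
#'   `CLOCK`, `TAD`, `value`.
#' @export
population_curves <- function(design = trial_design(),
                              truth = truth_params(), n_grid = 181) {
  clock <- seq(min(design$cortisol_clock), max(design$cortisol_clock),
               length.out = n_grid)
  tad <- pmax(clock - design$dose_clock, 0)
  conc <- pk_conc_vec(design$dose, tad, truth$pk$cl_f, truth$pk$v_f,
                      truth$pk$ka)
  bsl <- circadian_vec(clock, truth$circadian$bsl0, truth$circadian$amp,
                       truth$circadian$tpeak, truth$circadian$trend,
                       truth$circadian$period)
  free_nmol <- function(total_ngml) {
    1000 * free_cortisol_coolens(
      convert_units(total_ngml, "cortisol_ngml_to_umoll"),
      convert_units(design$cbg_mean, "cbg_mgl_to_umoll"))
  }
  dplyr::bind_rows(
    tibble::tibble(type = "htp", TRT = 1L, CLOCK = clock, TAD = tad,
                   value = conc),
    tibble::tibble(type = "cortisol", TRT = 0L, CLOCK = clock, TAD = tad,
                   value = bsl),
    tibble::tibble(type = "cortisol", TRT = 1L, CLOCK = clock, TAD = tad,
                   value = bsl + truth$s0 * conc),
    tibble::tibble(type = "saliva", TRT = 0L, CLOCK = clock, TAD = tad,
                   value = truth$link$beta * free_nmol(bsl)^truth$link$gamma),
    tibble::tibble(type = "saliva", TRT = 1L, CLOCK = clock, TAD = tad,
                   value = truth$link$beta *
                     free_nmol(bsl + truth$s0 * conc)^truth$link$gamma)
  )
}
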