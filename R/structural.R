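#' 5-HTP plasma concentration after an oral dose
#'
#' Central-compartment concentration of the one-compartment model with a
#' transit absorption compartment: depot -(ktr)-> transit -(ka)-> central
#' -(CL/V)->, with the transit and absorption rate constants constrained
#' equal (ktr = ka = k). With equal transfer rates the chain has the closed
#' form
#' \deqn{C(t) = 1000 \frac{F \cdot dose}{V} k^2
#'   \frac{e^{-k_e t} - e^{-k t}(1 + (k - k_e) t)}{(k - k_e)^2}}
#' with \eqn{k_e = CL/V}. The removable singularity at \eqn{k = k_e} is
#' handled by the numerically stable factorisation
#' \eqn{C(t) = 1000 (F \cdot dose / V) k^2 t^2 e^{-kt} h(x)} with
#' \eqn{x = (k-k_e)t} and \eqn{h(x) = (\mathrm{expm1}(x) - x)/x^2}, which is
#' evaluated by a Taylor series for tiny |x|.
#'
#' Units: dose in mg, V in L, times in h; the factor 1000 converts mg/L to
#' ng/mL.
#'
#' @param dose Oral dose (mg), >= 0. Scalar or vector recyclable with `t`.
#' @param t Time after dose (h), >= 0. Vectorised.
#' @param pk A [pk_params()] bundle.
#' @return Concentration (ng/mL), nonnegative, same length as the recycled
#'   inputs.
#' @examples
#' pk <- pk_params(cl_f = 20.40, v_f = 102, ka = 1.89)
#' pk_concentration(200, c(0, 1, 2, 4, 9), pk)
#' @export
pk_concentration <- function(dose, t, pk) {
  stopifnot(inherits(pk, "pk_params"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0 (time after dose).", call. = FALSE)
  }
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("`dose` must be finite and >= 0.", call. = FALSE)
  }
  pk_conc_vec(dose, t, pk$cl_f, pk$v_f, pk$ka, pk$f)
}

# vectorised core used by the estimation engine: cl, v, ka may be per-row
# vectors (individual parameters). No class checks here; hot path.
# (expm1(x) - x) / x^2 is numerically stable down to tiny |x|; the series
# branch only guards the removable singularity itself.
pk_conc_vec <- function(dose, t, cl, v, ka, f = 1) {
  ke <- cl / v
  x <- (ka - ke) * t
  h <- (expm1(x) - x) / (x * x)
  small <- abs(x) < 1e-8
  if (any(small)) h[small] <- 0.5 + x[small] / 6
  1000 * f * dose / v * ka * ka * t * t * exp(-ka * t) * h
}

#' Elimination and absorption half-lives
#'
#' `elimination_half_life()` returns ln(2) * V/F / (CL/F); at the
#' challenge-test estimates (CL/F 20.40 L/h, V/F 102 L) this is 3.47 h.
#' `absorption_half_life()` returns ln(2)/ka (0.367 h at ka = 1.89/h).
#'
#' @inheritParams pk_concentration
#' @return Half-life in hours.
#' @export
elimination_half_life <- function(pk) {
  stopifnot(inherits(pk, "pk_params"))
  log(2) * pk$v_f / pk$cl_f
}

#' @rdname elimination_half_life
#' @export
absorption_half_life <- function(pk) {
  stopifnot(inherits(pk, "pk_params"))
  log(2) / pk$ka
}

#' Circadian serum cortisol baseline
#'
#' Cosine-plus-trend model of the daytime serum cortisol baseline:
#' \deqn{BSL(t) = (BSL_0 - Trend (t - T_{peak}))
#'   (1 + AMP \cos(2\pi (t - T_{peak}) / n))}
#' where t is clock time of day (decimal hours). `trend = 0` recovers the
#' pure cosinor model. Clock time is deliberately not wrapped modulo 24: the
#' model is meant for sampling windows within a single study day, and the
#' linear trend makes late-night extrapolation hazardous; if the evaluated
#' baseline is nonpositive anywhere a warning flags the extrapolation.
#'
#' @param clock_time Clock time of day (decimal h). Vectorised.
#' @param cp A [circadian_params()] bundle.
#' @return Baseline cortisol (ng/mL).
#' @examples
#' cp <- circadian_params(bsl0 = 88.6, amp = -0.23, tpeak = 11.5,
#'                        trend = 4.16, period = 8)
#' circadian_baseline(c(11.5, 13.5, 16), cp)
#' @export
circadian_baseline <- function(clock_time, cp) {
  stopifnot(inherits(cp, "circadian_params"))
  if (any(!is.finite(clock_time))) {
    stop("`clock_time` must be finite.", call. = FALSE)
  }
  out <- circadian_vec(clock_time, cp$bsl0, cp$amp, cp$tpeak, cp$trend,
                       cp$period)
  if (any(out <= 0)) {
    warning("Baseline is nonpositive at some evaluated times; the linear ",
            "trend extrapolates poorly outside the sampled daytime window.",
            call. = FALSE)
  }
  out
}

# hot-path core; parameters may be per-row vectors
circadian_vec <- function(clock, bsl0, amp, tpeak, trend, period) {
  dt <- clock - tpeak
  (bsl0 - trend * dt) * (1 + amp * cos(2 * pi * dt / period))
}

#' Drug effect on serum cortisol
#'
#' `linear_effect()` adds the first-order stimulation S0 * C(5-HTP) to the
#' baseline; it is the small-concentration approximation of the saturating
#' model used when a single dose level precludes estimating Emax and EC50
#' separately. `emax_effect()` is the saturating form
#' BSL + Emax * C / (EC50 + C), bounded above by BSL + Emax.
#'
#' @param bsl Baseline cortisol (ng/mL). Vectorised.
#' @param c5htp 5-HTP concentration (ng/mL), >= 0. Vectorised.
#' @param pd A [pd_params()] bundle (with `s0` for the linear form, `emax`
#'   and `ec50` for the saturating form).
#' @return Total serum cortisol (ng/mL).
#' @export
linear_effect <- function(bsl, c5htp, pd) {
  stopifnot(inherits(pd, "pd_params"))
  if (is.null(pd$s0)) {
    stop("`pd` has no `s0`; use `emax_effect()` or supply `s0`.",
         call. = FALSE)
  }
  check_conc(c5htp)
  bsl + pd$s0 * c5htp
}

#' @rdname linear_effect
#' @export
emax_effect <- function(bsl, c5htp, pd) {
  stopifnot(inherits(pd, "pd_params"))
  if (is.null(pd$emax) || is.null(pd$ec50)) {
    stop("`pd` lacks `emax`/`ec50`; configure them or use `linear_effect()`.",
         call. = FALSE)
  }
  check_conc(c5htp)
  bsl + pd$emax * c5htp / (pd$ec50 + c5htp)
}

#' Saliva cortisol from a serum cortisol predictor
#'
#' Power-law link Csal = beta * Ccol^gamma relating saliva cortisol to a
#' serum cortisol predictor (total or free). `gamma = 1` is the linear
#' sub-model. Both sides are conventionally expressed in nmol/L in this
#' package; beta is unit-bearing, so the convention matters.
#'
#' @param ccol Serum cortisol predictor (nmol/L), >= 0. Vectorised.
#' @param link A [saliva_link_params()] bundle.
#' @return Saliva cortisol (nmol/L).
#' @export
saliva_from_serum <- function(ccol, link) {
  stopifnot(inherits(link, "saliva_link_params"))
  check_conc(ccol)
  link$beta * ccol^link$gamma
}

#' Free serum cortisol by the Coolens calculation
#'
#' Given total serum cortisol T and corticosteroid-binding globulin G, both
#' in micromol/L, the unbound (free) cortisol U solves a binding quadratic
#' whose positive root is
#' \deqn{Z = 0.0167 + 0.182 (G - T), \quad U = \sqrt{Z^2 + 0.0122\,T} - Z.}
#' The affinity constants are valid in the micromol/L domain only; convert
#' assay units first (see [convert_units()]).
#'
#' @param total Total serum cortisol (micromol/L), >= 0. Vectorised.
#' @param cbg CBG concentration (micromol/L), >= 0. Vectorised.
#' @return Free serum cortisol (micromol/L), nonnegative.
#' @examples
#' free_cortisol_coolens(0.3, 0.7)
#' @export
free_cortisol_coolens <- function(total, cbg) {
  check_conc(total, "total")
  check_conc(cbg, "cbg")
  kk <- coolens_constants()
  z <- kk$b + kk$k * (cbg - total)
  pmax(sqrt(z^2 + kk$a * total) - z, 0)
}

#' Unit conversions between assay and molar domains
#'
#' Cortisol assays report ng/mL while the Coolens calculation lives in
#' micromol/L; CBG is assayed in mg/L. Conversions use a cortisol molar mass
#' of 362.46 g/mol and a CBG molar mass of 52 kDa.
#'
#' @param value Nonnegative value(s) to convert.
#' @param kind One of `"cortisol_ngml_to_nmoll"`, `"cortisol_ngml_to_umoll"`,
#'   `"cbg_mgl_to_umoll"`, or the inverse conversions
#'   `"cortisol_nmoll_to_ngml"`, `"cortisol_umoll_to_ngml"`,
#'   `"cbg_umoll_to_mgl"`.
#' @return Converted value(s).
#' @examples
#' convert_units(362.46, "cortisol_ngml_to_nmoll")  # 1000 nmol/L
#' convert_units(45.94, "cbg_mgl_to_umoll")
#' @export
convert_units <- function(value, kind) {
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("`value` must be finite and >= 0.", call. = FALSE)
  }
  mw_cortisol <- 362.46
  switch(
    match.arg(kind, c("cortisol_ngml_to_nmoll", "cortisol_ngml_to_umoll",
                      "cbg_mgl_to_umoll", "cortisol_nmoll_to_ngml",
                      "cortisol_umoll_to_ngml", "cbg_umoll_to_mgl")),
    cortisol_ngml_to_nmoll = value * 1000 / mw_cortisol,
    cortisol_ngml_to_umoll = value / mw_cortisol,
    cbg_mgl_to_umoll = value / 52,
    cortisol_nmoll_to_ngml = value * mw_cortisol / 1000,
    cortisol_umoll_to_ngml = value * mw_cortisol,
    cbg_umoll_to_mgl = value * 52
  )
}

check_conc <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`", name, "` must be finite and >= 0.", call. = FALSE)
  }
  invisible(x)
}
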