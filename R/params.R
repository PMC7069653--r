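#' Parameter bundles for the structural models
#'
#' Constructors for the fixed-effect parameter sets used throughout the
#' package: pharmacokinetics of orally dosed 5-HTP, the circadian serum
#' cortisol baseline, the pharmacodynamic stimulation model, and the
#' saliva-serum cortisol link. Each constructor validates its domain
#' invariants and returns a lightweight named list with a class tag, so the
#' bundles print readably and can be passed around pipelines.
#'
#' @param cl_f Apparent clearance CL/F (L/h), strictly positive.
#' @param v_f Apparent volume of distribution V/F (L), strictly positive.
#' @param ka Absorption rate constant (1/h), strictly positive. The transit
#'   rate constant `ktr` is constrained equal to `ka` (a single rate governs
#'   the depot -> transit -> central chain).
#' @param f Bioavailability fraction, fixed at 1 (the dose is apparent-dose;
#'   CL and V already carry /F).
#' @return A classed list of validated parameters.
#' @examples
#' pk_params(cl_f = 20.40, v_f = 102, ka = 1.89)
#' @export
pk_params <- function(cl_f, v_f, ka, f = 1) {
  check_positive(c(cl_f = cl_f, v_f = v_f, ka = ka, f = f))
  structure(
    list(cl_f = cl_f, v_f = v_f, ka = ka, ktr = ka, f = f),
    class = c("pk_params", "htp_params")
  )
}

#' @rdname pk_params
#' @param bsl0 Initial baseline cortisol BSL0 (ng/mL), strictly positive.
#' @param amp Cosine amplitude (dimensionless), |amp| < 1 so the
#'   multiplicative factor stays positive.
#' @param tpeak Reference clock time (h of day, in [0, 24)).
#' @param trend Linear decline slope (ng/mL per h). 0 removes the trend and
#'   leaves the pure cosinor model.
#' @param period Cosine period n (h), positive; the candidate set used for
#'   model selection is {4, 8, 12, 16, 24}.
#' @export
circadian_params <- function(bsl0, amp, tpeak, trend = 0, period = 8) {
  check_positive(c(bsl0 = bsl0, period = period))
  if (!is.finite(amp) || abs(amp) >= 1) {
    stop("`amp` must be finite with |amp| < 1 (keeps the baseline positive).",
         call. = FALSE)
  }
  if (!is.finite(tpeak) || tpeak < 0 || tpeak >= 24) {
    stop("`tpeak` must be a clock time in [0, 24).", call. = FALSE)
  }
  if (!is.finite(trend)) stop("`trend` must be finite.", call. = FALSE)
  structure(
    list(bsl0 = bsl0, amp = amp, tpeak = tpeak, trend = trend,
         period = period),
    class = c("circadian_params", "htp_params")
  )
}

#' @rdname pk_params
#' @param s0 Linear stimulation slope (ng/mL cortisol per ng/mL 5-HTP),
#'   nonnegative. The first-order approximation of Emax/EC50 when 5-HTP
#'   concentrations stay well below EC50.
#' @param emax Maximum stimulation (ng/mL); optional, only for the saturating
#'   model.
#' @param ec50 5-HTP concentration at half-maximal stimulation (ng/mL);
#'   optional, required together with `emax`.
#' @export
pd_params <- function(s0 = NULL, emax = NULL, ec50 = NULL) {
  if (xor(is.null(emax), is.null(ec50))) {
    stop("`emax` and `ec50` must be supplied together.", call. = FALSE)
  }
  if (is.null(s0) && is.null(emax)) {
    stop("Supply `s0` (linear model) or both `emax` and `ec50`.",
         call. = FALSE)
  }
  if (!is.null(s0)) {
    if (!is.finite(s0) || s0 < 0) {
      stop("`s0` must be finite and >= 0.", call. = FALSE)
    }
  }
  if (!is.null(emax)) check_positive(c(emax = emax, ec50 = ec50))
  structure(
    list(s0 = s0, emax = emax, ec50 = ec50),
    class = c("pd_params", "htp_params")
  )
}

#' @rdname pk_params
#' @param beta Scale factor of the saliva-serum power link, > 0. Unit-bearing:
#'   with both sides in nmol/L the link reads Csal = beta * Ccol^gamma.
#' @param gamma Power exponent, > 0; `gamma = 1` reduces the link to a
#'   straight proportionality.
#' @export
saliva_link_params <- function(beta, gamma = 1) {
  check_positive(c(beta = beta, gamma = gamma))
  structure(
    list(beta = beta, gamma = gamma),
    class = c("saliva_link_params", "htp_params")
  )
}

#' Coolens affinity constants
#'
#' The fixed constants of the Coolens free-cortisol calculation, valid when
#' total cortisol and CBG are expressed in micromol/L. Exposed as a function
#' so the values are immutable defaults rather than mutable state.
#'
#' @return Named list with elements `a` (0.0122), `b` (0.0167) and
#'   `k` (0.182).
#' @export
coolens_constants <- function() {
  list(a = 0.0122, b = 0.0167, k = 0.182)
}

#' @export
print.htp_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  vals <- unlist(Filter(Negate(is.null), unclass(x)))
  for (nm in names(vals)) cat(" ", nm, "=", format(vals[[nm]]), "\n")
  invisible(x)
}

# shared validator: all values finite and strictly positive
check_positive <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop("Parameter(s) must be finite and > 0: ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
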