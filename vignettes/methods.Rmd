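---
title: "Models and estimation methods for the 5-HTP challenge test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimation methods for the 5-HTP challenge test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(htpchallenge)
```

## The problem

A 5-HTP challenge raises serum cortisol through the HPA axis, and the
size and shape of that rise is the readout of central serotonergic
function. Two features make the analysis harder than a standard
concentration–effect fit. First, cortisol has a pronounced diurnal
rhythm, so the observed treatment-day profile is the sum of a drug
effect driven by time after dose and a baseline driven by clock time;
the two time scales must be modelled jointly. Second, saliva sampling is
the attractive, stress-free alternative to venipuncture, but saliva
cortisol tracks the free (unbound) serum fraction, which must be derived
from total cortisol and corticosteroid-binding globulin (CBG).

This package implements the full chain as a staged population
(nonlinear mixed-effects) analysis, and validates it by
simulation–estimation, because the motivating pooled trial data are not
publicly deposited.

## Structural models

**5-HTP kinetics.** One-compartment disposition with first-order
elimination and a single transit compartment before absorption, the
transit and absorption rate constants constrained equal
(`ktr = ka = k`). With equal transfer rates the depot–transit–central
chain has the closed form

$$C(t) = 1000\,\frac{F\,D}{V}\,k^2 t^2 e^{-k t}\, h\big((k-k_e)t\big),
\qquad h(x) = \frac{e^x - 1 - x}{x^2},\; k_e = CL/V,$$

in ng/mL for a dose in mg and a volume in L. The factorised form is
numerically stable: $h$ is evaluated through `expm1`, with a short
series below $|x| < 10^{-8}$, so the removable singularity at
$k \to k_e$ needs no special-casing in practice (the unit tests pin the
closed form against `deSolve` integration to $10^{-6}$ relative,
including near-singular rate constants). The transit compartment delays
the concentration upswing without a discontinuous lag time. A single
dose level implies `F` is not identifiable; it is fixed at 1 and `CL`
and `V` are apparent (CL/F, V/F).

**Circadian baseline.** A cosinor with a linear daytime decline, on
clock time $t$ (decimal hours):

$$BSL(t) = \big(BSL_0 - Trend\,(t - T_{peak})\big)
\big(1 + AMP\,\cos(2\pi (t - T_{peak})/n)\big).$$

`trend = 0` recovers the pure cosinor. The period $n$ is treated as a
model-selection quantity over {4, 8, 12, 16, 24} h rather than a
continuous parameter: the sampled window (roughly 11:00–20:00) covers at
most half of a 24 h cycle, so a continuously estimated period would be
poorly identified, while an OFV comparison over a small candidate set is
stable and reproducible. An 8 h period should be read as a descriptive
harmonic of the daytime profile, not as a biological ultradian claim —
over a 9 h window a short cosine plus a negative trend is simply a good
basis for the observed shape. For the same reason the model must not be
extrapolated into the night: the linear trend eventually drives the
baseline negative, and `circadian_baseline()` warns (rather than errors)
when it does. Clock time is deliberately not wrapped modulo 24; the
simulator guarantees sampling windows inside a single day.

$T_{peak}$ deserves a note: with a negative amplitude the multiplicative
factor is *minimised* at $T_{peak}$, so the name labels the reference
time of the cosine, not a cortisol maximum. The model is implemented
exactly as written; the sign convention follows the reported estimates
(AMP = −0.23).

**Drug effect.** With one dose level the saturating model
$E = BSL + E_{max} C/(EC_{50} + C)$ cannot separate $E_{max}$ from
$EC_{50}$; only their ratio is identified. The analysis therefore uses
the first-order approximation $E = BSL + S_0\,C$ with
$S_0 = E_{max}/EC_{50}$, and `fit_pd()` refuses a saturating fit on
single-dose-level data unless `force = TRUE`. $S_0$ is treated as
ng/mL cortisol per ng/mL 5-HTP; at a typical peak 5-HTP concentration
(~1400 ng/mL) the default $S_0 = 0.072$ yields a stimulation of about
100 ng/mL on top of an ~80 ng/mL baseline, which is the plausibility
check behind that unit reading.

**Saliva link.** $C_{sal} = \beta\,C_{col}^{\gamma}$, with $\gamma = 1$
as the linear sub-model. $\beta$ is unit-bearing, so the convention is
fixed: both sides in nmol/L (serum ng/mL × 1000/362.46). The predictor
$C_{col}$ is either the individual model-predicted total serum cortisol
or the free cortisol derived from it by the Coolens calculation

$$Z = 0.0167 + 0.182\,(G - T), \qquad U = \sqrt{Z^2 + 0.0122\,T} - Z$$

with $T$, $G$, $U$ in µmol/L. The affinity constants are only valid in
the µmol/L domain, so every call goes through explicit unit conversion
(cortisol molar mass 362.46 g/mol, CBG 52 kDa). The square root is part
of the standard form of this calculation (the quadratic's positive
root); a rendering without it is dimensionally incoherent. Each
subject's measured CBG is used, constant across occasions.

## Statistical model and estimation

Individual parameters are log-normal,
$P_i = \theta\,e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$, with diagonal
covariance throughout (the reported model has scalar $\omega^2$ per
parameter; no off-diagonal terms). Day-to-day baseline shifts are
inter-occasion variability (IOV): one extra deviation per occasion on
the log of $BSL_0$, $\kappa_{io} \sim N(0, \omega^2_{IOV})$, shared
variance across occasions — the standard NONMEM-style construction. The
residual model is $O_{obs} = O_{pred}(1 + \varepsilon_1) +
\varepsilon_2$; all final stage models use the proportional term only.

The marginal −2 log-likelihood (OFV) is computed by Laplace
approximation around each subject's conditional mode: an inner damped
Gauss–Newton search for the MAP random effects, then
$q(\hat b) + \log\det(J^TWJ + \Omega^{-1}) - n_b\log 2\pi$ with the
residual variance (and hence $W$) evaluated at the *conditional*
prediction — the interaction form, which the proportional error model
requires. The Gauss–Newton curvature at the mode is the
FOCE-with-interaction expansion; `method = "laplace"` swaps in an exact
numeric Hessian for small problems. On linear-Gaussian toys the
approximation is exact, which is how it is pinned against 64-node
adaptive Gauss–Hermite quadrature and against `lme4` ML estimates in the
test suite.

Numerical choices that matter:

* The outer optimiser is bounded `nlminb` on transformed parameters
  (log for positive fixed effects and all standard deviations, identity
  with bounds for the amplitude). The inner solves always start from the
  prior mode, so the OFV is a deterministic, history-free function of
  the outer parameters. Warm-starting the inner solves across outer
  iterations is measurably faster per evaluation but makes successive
  evaluations of the same point differ at the $10^{-6}$ level, which is
  enough to corrupt finite-difference gradients and stall the outer
  search on ridge-shaped likelihoods — determinism is worth the extra
  inner iterations.
* Inner convergence: improvement below $10^{-12}$ and step below
  $10^{-7}$; outer `rel.tol` $10^{-9}$ (OFV differences far below the
  3.84 decision scale carry no inferential weight), plus one restart
  from the optimum as a stationarity safeguard.
* The likelihood surface couples the absorption rate with its
  variability in a long, shallow, curved valley. Two measures keep fits
  out of the low-$k_a$ false basin: data-driven initial estimates from a
  two-stage pass (per-subject curve fits, then medians and log-scale
  variances), and an optional profile search (`profile` argument of
  `fit_population()`) that pins one parameter on a grid and re-optimises
  the rest. With deterministic inner solves the default fits land in the
  correct basin on all tested replicates, so the profile search is off
  by default.
* Standard errors: central finite-difference Hessian of OFV/2 over all
  estimated quantities, step $10^{-4}|\hat\theta|$;
  RSE% $= 100\,SE/|\hat\theta|$. A non-positive-definite Hessian yields
  missing SEs with a warning rather than an error.
* The inner solver for the three structural stage models is compiled
  (Rcpp/RcppArmadillo) with analytic Jacobians; the reference R
  implementation accepts arbitrary prediction functions and is asserted
  equal to the compiled path in the tests ($10^{-6}$ on the OFV).

## The staged analysis

`run_pipeline()` follows the two-step logic of challenge-test practice:

1. **PK** (`fit_pk`): 5-HTP observations only, IIV on CL/F and ka,
   proportional error. Empirical Bayes estimates are frozen afterwards.
2. **Placebo baseline** (`fit_baseline`): placebo-occasion serum
   cortisol, IIV on all four baseline parameters, one fit per candidate
   period, minimum OFV wins (ties within 0.01 go to the smaller
   period and are visible in the returned selection table). $T_{peak}$'s
   typical value is fixed at 11.5 h — its RSE is not separately
   reported in the reference estimates, and letting it float adds an
   unidentified phase shift — while its IIV is estimated. IOV is *not*
   estimated here: with a single placebo occasion per subject a
   per-occasion deviation is indistinguishable from the per-subject one.
3. **Joint baseline + PD** (`fit_pd`): all serum cortisol from both
   occasions; each subject's 5-HTP concentration is the individual
   PK prediction (sequential estimation with individual PK parameters —
   the PD stage can never alter PK estimates). Baseline parameters are
   re-estimated jointly with $S_0$, initialised at the placebo-stage
   values: the reference analysis reports one combined circadian+PD
   block, which implies joint re-estimation rather than frozen baseline
   parameters. IOV on $BSL_0$ enters here, one draw per occasion.
4. **Saliva link** (`fit_saliva`): all predictor × form combinations
   ({total, free} × {power, linear}) are fitted and ranked by OFV; IIV
   on $\beta$ only. The free predictor uses the subject's CBG.

A dataset without saliva records (one of the three pooled studies has
none) simply skips stage 4.

## The simulator and what passing recovery shows

`simulate_trial()` generates the design the analysis assumes: 35
subjects in three studies (13/11/11; saliva in two), a placebo and a
treatment occasion in randomised order, 200 mg dosed at 11:00, ~8 5-HTP
samples over 0–9 h, ~11 serum cortisol samples per occasion over
11:00–20:00, 8 saliva samples per occasion, CBG truncated-normal
(45.94 ± 5.94 mg/L). Exact per-study sampling schedules are not public;
evenly spaced grids sized to reproduce the per-type observation density
are used instead. Generating values default to the reported final-model
estimates, including all variability terms. Saliva is generated from
the *noise-free* simulated total cortisol through Coolens and the power
link, so the structural identity holds exactly before residual noise;
negative noise draws are resampled rather than truncated to avoid
low-concentration bias. A subject whose noise-free cortisol curve dips
below zero inside the sampling window (possible under extreme
trend/baseline deviations) is redrawn: this mildly truncates the
random-effect distribution (a few percent of draws) and is the price of
simulating from a baseline model that is only locally valid in time.

Recovery tests fit the staged models to such data and require the
medians over replicates to land near truth (15% for well-identified
fixed effects, 20–40% where the reported uncertainty is larger), the 8 h
period to win the selection, the trend term to clear ΔOFV > 3.84, and
power/free to beat their alternatives. Passing shows the chain —
simulator, likelihood, optimiser, selection logic — is internally
consistent and unbiased at the reported design and parameter values. It
does **not** show that real challenge data satisfy the model: real
cortisol has non-cosine rhythm components, assay error is not purely
proportional, sampling is irregular, and dropout/censoring exist and are
not simulated.

## Problem sizes

The test suite runs the recovery study at 10 replicates of the full
35-subject design and reduced (12-subject) designs for mechanical
checks; `scripts/acceptance.R` runs 20 replicates. The VPC default is
1000 simulated individuals with residual variability excluded, matching
predictive-check practice for these models (inclusion is an option, and
is what the self-consistency test uses).

## Known limitations

* Diagonal random-effect covariance only; no correlation between CL and
  ka deviations.
* The baseline model is descriptive and local in time; no mechanistic
  HPA cascade (ACTH/CRH), no feedback, single-dose regimens only.
* FOCE/Laplace is a deterministic approximation; no SAEM or importance
  sampling, no bootstrap confidence intervals.
* An optional study-level random effect (suggested by between-study
  clearance differences) is out of scope; pooling assumes the three
  study designs are exchangeable.
* A time-binned VPC is well defined for the PK and saliva models; for
  the PD model the two interleaved time scales (clock time and time
  after dose) make one ill-defined, and per-subject trellis displays
  plus goodness-of-fit tables are the intended diagnostics. A clock-time
  VPC (`x = "CLOCK"`) is available as an explicitly labelled extension.
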