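test_that("transit-chain concentration matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  pk <- pk_params(cl_f = 20.40, v_f = 102, ka = 1.89)
  times <- c(0.25, 0.5, 1, 2, 3, 4.5, 6, 9, 12, 24)
  closed <- pk_concentration(200, times, pk)
  ode <- pk_ode_oracle(200, times, pk$cl_f, pk$v_f, pk$ka)
  expect_equal(closed, unname(ode), tolerance = 1e-6)

  # randomised parameter sets, including near-singular ka ~ ke
  set.seed(11)
  for (i in 1:12) {
    cl <- runif(1, 5, 60)
    v <- runif(1, 40, 200)
    ka <- if (i <= 3) cl / v * (1 + 1e-4) else runif(1, 0.2, 6)
    closed <- pk_concentration(200, times,
                               pk_params(cl_f = cl, v_f = v, ka = ka))
    ode <- pk_ode_oracle(200, times, cl, v, ka)
    expect_equal(closed, unname(ode), tolerance = 1e-6)
  }
})

test_that("concentration is zero at t = 0, nonnegative, and mass balances", {
  pk <- pk_params(cl_f = 20.40, v_f = 102, ka = 1.89)
  expect_equal(pk_concentration(200, 0, pk), 0)
  tt <- seq(0, 48, by = 0.05)
  conc <- pk_concentration(200, tt, pk)
  expect_true(all(conc >= 0))
  expect_lt(conc[length(conc)], 1)
  # eliminated amount integrates to the absorbed dose: CL * AUC = F * dose
  auc <- sum((conc[-1] + conc[-length(conc)]) / 2 * diff(tt)) / 1000
  expect_equal(pk$cl_f * auc, 200, tolerance = 1e-3)
})

test_that("guard branch is continuous at ka -> ke", {
  cl <- 20.4; v <- 102
  ke <- cl / v
  t <- c(0.5, 2, 6, 12)
  at_eps <- pk_concentration(200, t,
                             pk_params(cl_f = cl, v_f = v,
                                       ka = ke * (1 + 1e-4)))
  just_above <- pk_concentration(200, t,
                                 pk_params(cl_f = cl, v_f = v,
                                           ka = ke * (1 + 1e-9)))
  limit <- 1000 * 200 / v * ke^2 * t^2 * exp(-ke * t) / 2
  expect_equal(just_above, limit, tolerance = 1e-6)
  expect_equal(at_eps / limit, rep(1, 4), tolerance = 1e-3)
})

test_that("half-lives reproduce the printed challenge-test values", {
  pk <- pk_params(cl_f = 20.40, v_f = 102, ka = 1.89)
  expect_equal(round(elimination_half_life(pk), 2), 3.47)
  expect_equal(round(absorption_half_life(pk), 3), 0.367)
  expect_equal(elimination_half_life(pk_params(cl_f = log(2), v_f = 1,
                                               ka = 1)), 1)
  expect_equal(absorption_half_life(pk_params(cl_f = 1, v_f = 1,
                                              ka = log(2))), 1)
  # linear in V/F, decreasing in ka
  expect_equal(elimination_half_life(pk_params(cl_f = 20.40, v_f = 204,
                                               ka = 1.89)),
               2 * elimination_half_life(pk))
  expect_lt(absorption_half_life(pk_params(cl_f = 1, v_f = 1, ka = 3)),
            absorption_half_life(pk_params(cl_f = 1, v_f = 1, ka = 2)))
})

test_that("circadian baseline follows the cosine-plus-trend form", {
  cp <- circadian_params(bsl0 = 88.60, amp = -0.23, tpeak = 11.5,
                         trend = 4.16, period = 8)
  # at the reference time the cosine factor is 1 + amp
  expect_equal(circadian_baseline(11.5, cp), 88.60 * (1 - 0.23))
  # two hours after the reference time the cosine term vanishes
  expect_equal(circadian_baseline(13.5, cp), (88.60 - 4.16 * 2) * 1)
  expect_equal(circadian_baseline(13.5, cp), 80.28)
  # cosine component is periodic; the trend shifts by -trend * period
  t <- c(11.2, 12.9, 15.4)
  f1 <- circadian_baseline(t, cp)
  f2 <- circadian_baseline(t + 8, cp)
  expect_equal(f2 - f1, (-4.16 * 8) * (1 + cp$amp * cos(2 * pi *
                 (t - cp$tpeak) / 8)), tolerance = 1e-12)
  # trend = 0 recovers the pure cosinor model
  cp0 <- circadian_params(bsl0 = 88.60, amp = -0.23, tpeak = 11.5,
                          trend = 0, period = 8)
  expect_equal(circadian_baseline(t, cp0),
               88.60 * (1 - 0.23 * cos(2 * pi * (t - 11.5) / 8)))
  # nonpositive extrapolation warns rather than errors
  expect_warning(circadian_baseline(35, cp), "extrapolates")
})

test_that("drug-effect models behave as linear and saturating forms", {
  pd <- pd_params(s0 = 0.072)
  expect_equal(linear_effect(80.28, 0, pd), 80.28)
  expect_equal(linear_effect(80.28, 1000, pd), 152.28)
  # additivity in concentration
  expect_equal(linear_effect(50, 700, pd) - linear_effect(50, 300, pd),
               0.072 * 400)
  pde <- pd_params(emax = 100, ec50 = 2000)
  expect_equal(emax_effect(80, 2000, pde), 80 + 50)
  expect_equal(emax_effect(80, 0, pde), 80)
  expect_lt(max(emax_effect(80, 10^(1:6), pde)), 180)
  # small-concentration limit agrees with the linear form at s0 = emax/ec50
  pdl <- pd_params(s0 = 100 / 2000)
  c_small <- c(0.1, 0.5, 1, 2)  # all with c/ec50 <= 1e-3
  rel <- abs(emax_effect(0, c_small, pde) - linear_effect(0, c_small, pdl)) /
    linear_effect(0, c_small, pdl)
  expect_true(all(rel <= 2e-3))
  expect_error(emax_effect(80, 1, pd), "emax")
  expect_error(linear_effect(80, -1, pd), ">= 0")
})

test_that("saliva link scales as a power law", {
  link <- saliva_link_params(beta = 1.01, gamma = 1.10)
  expect_equal(saliva_from_serum(1, link), 1.01)
  expect_equal(saliva_from_serum(10, link), 1.01 * 10^1.1)
  expect_equal(round(saliva_from_serum(10, link), 2), 12.72)
  lin <- saliva_link_params(beta = 0.7, gamma = 1)
  expect_equal(saliva_from_serum(c(1, 5, 40), lin), 0.7 * c(1, 5, 40))
  expect_error(saliva_from_serum(-1, link), ">= 0")
})

test_that("Coolens free cortisol solves the binding quadratic", {
  expect_equal(free_cortisol_coolens(0, 0.9), 0)
  # hand evaluation: Z = 0.0167 + 0.182*(0.7-0.3) = 0.0895
  expect_equal(free_cortisol_coolens(0.3, 0.7),
               sqrt(0.0895^2 + 0.0122 * 0.3) - 0.0895)
  expect_equal(free_cortisol_coolens(0.3, 0.7), 0.01852893,
               tolerance = 1e-6)
  # finite, nonnegative and increasing in total on the physiological grid
  tt <- seq(0.05, 1.0, by = 0.05)
  for (g in seq(0.6, 1.1, by = 0.1)) {
    u <- free_cortisol_coolens(tt, g)
    expect_true(all(is.finite(u)) && all(u >= 0))
    expect_true(all(diff(u) > 0))
  }
  expect_error(free_cortisol_coolens(-0.1, 0.9), ">= 0")
})

test_that("unit conversions use the cortisol and CBG molar masses", {
  expect_equal(convert_units(362.46, "cortisol_ngml_to_nmoll"), 1000)
  expect_equal(convert_units(45.94, "cbg_mgl_to_umoll"), 45.94 / 52)
  expect_equal(round(convert_units(45.94, "cbg_mgl_to_umoll"), 3), 0.883)
  # round trips
  x <- c(0.3, 12, 88.6)
  expect_equal(convert_units(convert_units(x, "cortisol_ngml_to_nmoll"),
                             "cortisol_nmoll_to_ngml"), x,
               tolerance = 1e-12)
  expect_equal(convert_units(convert_units(x, "cbg_mgl_to_umoll"),
                             "cbg_umoll_to_mgl"), x, tolerance = 1e-12)
  expect_error(convert_units(1, "parsec_to_furlong"))
})

test_that("parameter constructors enforce their domains", {
  expect_error(pk_params(cl_f = -1, v_f = 100, ka = 1), "> 0")
  expect_equal(pk_params(cl_f = 1, v_f = 1, ka = 2)$ktr, 2)
  expect_error(circadian_params(bsl0 = 80, amp = 1.2, tpeak = 11),
               "amp")
  expect_error(circadian_params(bsl0 = 80, amp = 0.2, tpeak = 25),
               "clock")
  expect_error(saliva_link_params(beta = 0, gamma = 1), "> 0")
  expect_error(pd_params(), "s0")
  expect_error(pd_params(emax = 10), "together")
  expect_equal(coolens_constants(),
               list(a = 0.0122, b = 0.0167, k = 0.182))
})
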