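test_that("simulated trials are reproducible and structurally sound", {
  des <- small_design()
  d1 <- simulate_trial(des, seed = 5)
  d2 <- simulate_trial(des, seed = 5)
  d3 <- simulate_trial(des, seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))

  expect_silent(validate_challenge_dataset(d1))
  # three observation types, 5-HTP scarcer than serum cortisol, saliva
  # only in the two saliva studies
  n_by_type <- table(d1$DVID[d1$EVID == 0L])
  expect_true(all(c("1", "2", "3") %in% names(n_by_type)))
  expect_lt(n_by_type[["1"]], n_by_type[["2"]])
  expect_setequal(unique(d1$STUDY[!is.na(d1$DVID) & d1$DVID == 3L]),
                  c("SB", "SC"))
  # every treatment occasion has exactly one dose row; placebo none
  occ <- dplyr::summarise(dplyr::group_by(d1, ID, OCC, TRT),
                          nd = sum(EVID == 1L), .groups = "drop")
  expect_true(all(occ$nd[occ$TRT == 1] == 1))
  expect_true(all(occ$nd[occ$TRT == 0] == 0))
  # both crossover orders occur
  first_occ <- occ[occ$OCC == 1, ]
  expect_true(any(first_occ$TRT == 1) && any(first_occ$TRT == 0))
})

test_that("without variability every record equals the population curve", {
  des <- small_design()
  tr <- noiseless_truth()
  d <- simulate_trial(des, tr, seed = 3)
  obs <- d[d$EVID == 0L, ]
  pk <- tr$pk
  cp <- tr$circadian
  # 5-HTP records: typical transit-chain curve
  htp <- obs[obs$DVID == 1L, ]
  expect_equal(htp$DV, pk_concentration(des$dose, htp$TAD, pk),
               tolerance = 1e-12)
  # serum cortisol: baseline plus linear stimulation on treatment days
  cort <- obs[obs$DVID == 2L, ]
  bsl <- circadian_baseline(cort$CLOCK, cp)
  drug <- tr$s0 * ifelse(cort$TRT == 1L,
                         pk_concentration(des$dose, cort$TAD, pk), 0)
  expect_equal(cort$DV, bsl + drug, tolerance = 1e-12)
  # saliva: power link applied to Coolens free cortisol of the noise-free
  # total, in nmol/L
  sal <- obs[obs$DVID == 3L, ]
  total <- circadian_baseline(sal$CLOCK, cp) +
    tr$s0 * ifelse(sal$TRT == 1L,
                   pk_concentration(des$dose, sal$TAD, pk), 0)
  free_nmol <- 1000 * free_cortisol_coolens(
    convert_units(total, "cortisol_ngml_to_umoll"),
    convert_units(sal$CBG, "cbg_mgl_to_umoll"))
  expect_equal(sal$DV, tr$link$beta * free_nmol^tr$link$gamma,
               tolerance = 1e-12)
})

test_that("CBG draws have the right moments and stay positive", {
  x <- sample_cbg(10000, seed = 2)
  expect_lt(abs(mean(x) - 45.94), 0.2)
  expect_lt(abs(sd(x) - 5.94), 0.2)
  expect_true(all(x > 0))
  expect_equal(sample_cbg(5, seed = 1, sd = 0), rep(45.94, 5))
  expect_identical(sample_cbg(10, seed = 9), sample_cbg(10, seed = 9))
})

test_that("population curves compose the structural models", {
  tr <- truth_params()
  pc <- population_curves(truth = tr, n_grid = 61)
  cort0 <- pc[pc$type == "cortisol" & pc$TRT == 0L, ]
  cort1 <- pc[pc$type == "cortisol" & pc$TRT == 1L, ]
  htp <- pc[pc$type == "htp", ]
  # treatment minus placebo equals the linear effect of the typical curve
  expect_equal(cort1$value - cort0$value, tr$s0 * htp$value,
               tolerance = 1e-12)
  # placebo saliva is the power link of free baseline cortisol
  sal0 <- pc[pc$type == "saliva" & pc$TRT == 0L, ]
  free_nmol <- 1000 * free_cortisol_coolens(
    convert_units(cort0$value, "cortisol_ngml_to_umoll"),
    rep(convert_units(45.94, "cbg_mgl_to_umoll"), nrow(cort0)))
  expect_equal(sal0$value, tr$link$beta * free_nmol^tr$link$gamma,
               tolerance = 1e-12)
  # all typical curves positive over the sampling window
  expect_true(all(pc$value >= 0))
})

test_that("design validation rejects impossible sampling schemes", {
  expect_error(trial_design(dose = 0), "> 0")
  expect_error(trial_design(pk_tad = c(0, 1, 2)), "pre-dose")
  expect_error(trial_design(cortisol_clock = c(11, 25)), "single day")
  expect_error(truth_params(pk_sigma = -0.1), ">= 0")
})
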