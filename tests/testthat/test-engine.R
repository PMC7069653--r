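test_that("OFV equals the Gaussian closed form without random effects", {
  set.seed(3)
  x <- seq(0, 10, length.out = 15)
  y <- 2 + 0.5 * x + rnorm(15, 0, 0.3)
  d <- tibble::tibble(ID = 1L, DV = y, X = x)
  spec <- me_spec(theta = c(a = 1, b = 1),
                  transform = c(a = "identity", b = "identity"),
                  sigma_prop = 0, sigma_add = 0.3)
  pred_fn <- function(p, d) p$a + p$b * d$X
  ofv <- neg2ll(d, pred_fn, spec, theta = c(a = 2, b = 0.5))
  res <- y - (2 + 0.5 * x)
  exact <- sum(log(2 * pi * 0.09) + res^2 / 0.09)
  expect_equal(ofv, exact, tolerance = 1e-9)
})

test_that("Laplace OFV matches 64-node adaptive quadrature on toys", {
  skip_if_not_installed("pracma")
  set.seed(7)
  # linear random-intercept model, additive error: Laplace is exact
  x <- c(0, 1, 2, 4, 6)
  b_true <- 0.8
  y <- (5 + b_true) + 0.3 * x + rnorm(5, 0, 0.4)
  d <- tibble::tibble(ID = 1L, DV = y, X = x)
  spec <- me_spec(theta = c(mu = 5, slope = 0.3),
                  transform = c(mu = "identity", slope = "identity"),
                  iiv = "mu", omega2 = c(mu = 0.5),
                  re_dist = c(mu = "normal"),
                  sigma_prop = 0, sigma_add = 0.4)
  pred_fn <- function(p, d) p$mu + p$slope * d$X
  for (method in c("foce", "laplace")) {
    ofv <- neg2ll(d, pred_fn, spec, method = method)
    oracle <- agq_neg2ll_1re(
      y, pred_of_eta = function(e) (5 + e) + 0.3 * x,
      var_of_pred = function(f) rep(0.4^2, length(f)),
      omega2 = 0.5)
    expect_lt(abs(ofv - oracle), 1e-3)
  }
  # two-subject version: contributions add
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, ID = 2L, DV = DV + 0.9))
  ofv2 <- neg2ll(d2, pred_fn, spec)
  oracle2 <- agq_neg2ll_1re(
    y, function(e) (5 + e) + 0.3 * x, function(f) rep(0.16, length(f)),
    0.5) +
    agq_neg2ll_1re(
      y + 0.9, function(e) (5 + e) + 0.3 * x,
      function(f) rep(0.16, length(f)), 0.5)
  expect_lt(abs(ofv2 - oracle2), 1e-3)
})

test_that("OFV approaches the fixed-effect value as omega -> 0", {
  set.seed(9)
  x <- seq(0.5, 8, length.out = 8)
  y <- 10 * exp(-0.3 * x) * (1 + rnorm(8, 0, 0.1))
  d <- tibble::tibble(ID = 1L, DV = y, X = x)
  pred_fn <- function(p, d) p$a * exp(-p$k * d$X)
  spec_re <- me_spec(theta = c(a = 10, k = 0.3), iiv = "a",
                     omega2 = c(a = 1e-8), sigma_prop = 0.1)
  spec_fix <- me_spec(theta = c(a = 10, k = 0.3), sigma_prop = 0.1)
  expect_equal(neg2ll(d, pred_fn, spec_re), neg2ll(d, pred_fn, spec_fix),
               tolerance = 1e-4)
})

test_that("fit_population matches lme4 ML on a linear mixed model", {
  skip_if_not_installed("lme4")
  set.seed(21)
  n_subj <- 30; n_obs <- 6
  dd <- tidyr::expand_grid(ID = 1:n_subj, X = seq(0, 5, length.out = n_obs))
  bi <- rnorm(n_subj, 0, 0.9)
  dd$DV <- 4 + bi[dd$ID] + 0.7 * dd$X + rnorm(nrow(dd), 0, 0.5)
  spec <- me_spec(theta = c(mu = 3, slope = 0.5),
                  transform = c(mu = "identity", slope = "identity"),
                  iiv = "mu", omega2 = c(mu = 0.4),
                  re_dist = c(mu = "normal"),
                  sigma_prop = 0, sigma_add = 0.4)
  pred_fn <- function(p, d) p$mu + p$slope * d$X
  fit <- fit_population(dd, pred_fn, spec)
  lmm <- lme4::lmer(DV ~ X + (1 | ID), data = dd, REML = FALSE)
  expect_equal(unname(fit$theta["mu"]), unname(lme4::fixef(lmm)[1]),
               tolerance = 1e-3)
  expect_equal(unname(fit$theta["slope"]), unname(lme4::fixef(lmm)[2]),
               tolerance = 1e-3)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(unname(fit$omega2["mu"]), vc$vcov[1], tolerance = 1e-3)
  expect_equal(unname(fit$sigma["add"])^2, vc$vcov[2], tolerance = 1e-3)
  expect_equal(fit$ofv, -2 * as.numeric(stats::logLik(lmm)),
               tolerance = 1e-6)
})

test_that("individual parameters and residual variance follow their forms", {
  expect_equal(individual_param(20.40, 0), 20.40)
  expect_equal(individual_param(20.40, 0.1), 20.40 * exp(0.1))
  expect_equal(round(individual_param(20.40, 0.1), 3), 22.545)
  expect_true(all(individual_param(3, c(-50, -1, 0, 1, 50)) > 0))
  expect_error(individual_param(-1, 0), "> 0")

  expect_equal(residual_variance(100, sigma_prop = 0.11), 121)
  expect_equal(residual_variance(0, sigma_add = 2), 4)
  v <- residual_variance(seq(0, 50, by = 5), sigma_prop = 0.1,
                         sigma_add = 1)
  expect_true(all(diff(v) >= 0))
  expect_error(residual_variance(10), "Degenerate")
})

test_that("EBEs shrink toward zero and fade with uninformative data", {
  set.seed(31)
  x <- c(1, 3)
  spec <- me_spec(theta = c(a = 10), iiv = "a", omega2 = c(a = 0.2),
                  sigma_prop = 0.15)
  pred_fn <- function(p, d) p$a * exp(-0.3 * d$X)
  # sparse data: MAP eta lies between 0 and the per-subject LS deviation
  a_i <- 10 * exp(0.5)
  y <- a_i * exp(-0.3 * x)
  d <- tibble::tibble(ID = 1L, DV = y, X = x)
  eb <- compute_ebes(d, pred_fn, spec)
  eta_hat <- eb$value[eb$param == "a"]
  expect_gt(eta_hat, 0)
  expect_lt(eta_hat, 0.5)
  # with a huge prior variance the individual fit is recovered
  spec_wide <- me_spec(theta = c(a = 10), iiv = "a", omega2 = c(a = 100),
                       sigma_prop = 0.15)
  eb2 <- compute_ebes(d, pred_fn, spec_wide)
  expect_equal(eb2$value[1], 0.5, tolerance = 1e-3)
})

test_that("standard errors match the closed-form regression covariance", {
  set.seed(41)
  x <- seq(0, 10, length.out = 40)
  y <- 3 + 1.2 * x + rnorm(40, 0, 0.5)
  d <- tibble::tibble(ID = 1L, DV = y, X = x)
  spec <- me_spec(theta = c(a = 2, b = 1),
                  transform = c(a = "identity", b = "identity"),
                  sigma_prop = 0, sigma_add = 0.5)
  pred_fn <- function(p, d) p$a + p$b * d$X
  fit <- fit_population(d, pred_fn, spec, se = TRUE)
  # ML covariance of (a, b) at fixed sigma-hat: sigma^2 (X'X)^{-1}
  Xm <- cbind(1, x)
  s2 <- fit$sigma[["add"]]^2
  cov_ab <- s2 * solve(crossprod(Xm))
  se_tab <- fit$se_table
  expect_equal(se_tab$se[se_tab$parameter == "a"], sqrt(cov_ab[1, 1]),
               tolerance = 1e-3)
  expect_equal(se_tab$se[se_tab$parameter == "b"], sqrt(cov_ab[2, 2]),
               tolerance = 1e-3)
  # RSE is 100 * se / |estimate|
  expect_equal(se_tab$rse, 100 * se_tab$se / abs(se_tab$estimate))
})

test_that("refitting from the optimum is stationary and delta_ofv nests", {
  set.seed(51)
  dd <- tidyr::expand_grid(ID = 1:12, X = c(0.5, 1, 2, 4, 7))
  ai <- 10 * exp(rnorm(12, 0, 0.3))
  dd$DV <- ai[dd$ID] * exp(-0.35 * dd$X) * (1 + rnorm(nrow(dd), 0, 0.08))
  pred_fn <- function(p, d) p$a * exp(-p$k * d$X)
  spec <- me_spec(theta = c(a = 8, k = 0.3), iiv = "a",
                  omega2 = c(a = 0.1), sigma_prop = 0.1)
  fit <- suppressWarnings(fit_population(dd, pred_fn, spec))
  spec2 <- me_spec(theta = fit$theta, iiv = "a",
                   omega2 = fit$omega2, sigma_prop = fit$sigma[["prop"]])
  fit2 <- suppressWarnings(fit_population(dd, pred_fn, spec2))
  expect_lt(abs(fit$ofv - fit2$ofv), 1e-4)

  # nested comparison: freeing a fixed k cannot worsen the optimum
  spec_red <- me_spec(theta = c(a = 8), fixed = c(k = 0.5), iiv = "a",
                      omega2 = c(a = 0.1), sigma_prop = 0.1)
  fit_red <- suppressWarnings(fit_population(dd, pred_fn, spec_red))
  expect_equal(delta_ofv(fit, fit), 0)
  expect_gte(delta_ofv(fit_red, fit), -0.1)
  d_other <- dplyr::mutate(dd, DV = DV * 1.3)
  fit_other <- suppressWarnings(fit_population(d_other, pred_fn, spec))
  expect_error(delta_ofv(fit_other, fit), "identical data")
})

test_that("compiled and reference OFV paths agree on the PK stage model", {
  d <- simulate_trial(small_design(), seed = 77)
  obs <- d[d$EVID == 0L & d$DVID == 1L & d$MDV == 0L, ]
  obs <- join_dose(d, obs)
  spec <- me_spec(theta = c(cl_f = 20.4, ka = 1.89, v_f = 102),
                  iiv = c("cl_f", "ka"),
                  omega2 = c(cl_f = 0.16, ka = 0.38), sigma_prop = 0.11)
  pred_fn <- function(p, d) {
    pk_concentration(d$DOSE, d$TAD,
                     pk_params(cl_f = p$cl_f, v_f = p$v_f, ka = p$ka))
  }
  ofv_r <- neg2ll(obs, pred_fn, spec)
  subjects <- htpchallenge:::engine_split(obs, spec)
  ctx <- htpchallenge:::engine_native_prep(
    subjects, spec, list(model = 1L, xcols = c("DOSE", "TAD"),
                         pord = c("cl_f", "v_f", "ka")))
  ofv_c <- htpchallenge:::engine_ofv(
    subjects, c(spec$theta, spec$fixed), spec, spec$omega2, spec$iov2,
    spec$sigma_prop, spec$sigma_add, pred_fn, native_ctx = ctx)
  expect_equal(ofv_r, ofv_c, tolerance = 1e-6)
})
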