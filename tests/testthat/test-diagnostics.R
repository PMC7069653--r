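pk_fit_small <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      d <- simulate_trial(small_design(), seed = 12)
      fit <<- suppressWarnings(fit_pk(d))
    }
    fit
  }
})

test_that("VPC band collapses to the typical curve without variability", {
  fit <- pk_fit_small()
  v <- vpc(fit, x = "TAD", n_sim = 200, include_omega = FALSE,
           include_sigma = FALSE, seed = 1)
  expect_equal(v$summary$sim_lo, v$summary$sim_hi)
  expect_equal(v$summary$sim_lo, v$summary$sim_median)
  # and the median equals the population prediction at each time point
  pop <- predict_individual(fit)
  pop_by_t <- tapply(pop$pred, pop$TAD, stats::median)
  expect_equal(v$summary$sim_median,
               as.numeric(pop_by_t[as.character(v$summary$x)]),
               tolerance = 1e-9)
})

test_that("VPC is seed-reproducible and ordered, residual noise widens it", {
  fit <- pk_fit_small()
  v1 <- vpc(fit, n_sim = 300, seed = 42)
  v2 <- vpc(fit, n_sim = 300, seed = 42)
  expect_identical(v1$summary, v2$summary)
  expect_true(all(v1$summary$sim_lo <= v1$summary$sim_median))
  expect_true(all(v1$summary$sim_median <= v1$summary$sim_hi))
  vs <- vpc(fit, n_sim = 300, seed = 42, include_sigma = TRUE)
  expect_true(all(vs$summary$sim_hi - vs$summary$sim_lo >=
                    v1$summary$sim_hi - v1$summary$sim_lo))
  expect_warning(vpc(fit, n_sim = 20, seed = 1), "unstable")
})

test_that("goodness-of-fit table defines residuals consistently", {
  fit <- pk_fit_small()
  g <- gof_table(fit)
  expect_equal(nrow(g), fit$n_obs)
  expect_equal(g$residual, g$DV - g$ipred)
  expect_equal(g$wres,
               g$residual / sqrt(residual_variance(
                 pmax(g$ipred, 0), fit$sigma[["prop"]],
                 fit$sigma[["add"]])))
  # on well-specified data the weighted residuals are calibrated
  expect_lt(abs(mean(g$wres)), 0.15)
  expect_lt(abs(sd(g$wres) - 1), 0.2)
})

test_that("trellis data panels subjects and favours individual predictions", {
  fit <- pk_fit_small()
  td <- trellis_data(fit)
  expect_equal(length(unique(td$panel)),
               nrow(unique(td[, c("ID", "OCC")])))
  sse <- dplyr::summarise(
    dplyr::group_by(td, .data$ID),
    ind = sum((DV - ipred)^2), pop = sum((DV - pred)^2),
    .groups = "drop")
  expect_gte(mean(sse$ind <= sse$pop), 0.8)
})

test_that("plot builders return ggplot objects without rendering", {
  fit <- pk_fit_small()
  expect_s3_class(autoplot(vpc(fit, n_sim = 100, seed = 3)), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_trellis(fit, x = "TAD"), "ggplot")
})
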