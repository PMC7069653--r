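#' Visual predictive check
#'
#' Simulates `n_sim` individuals from the fitted model - fresh random
#' effects drawn from the estimated IIV (and IOV) variances, predictions
#' evaluated on the observed design rows - and summarises, per bin of the
#' chosen independent variable, the simulated median and 95% prediction
#' interval against the observations. Residual variability is excluded by
#' default, so the band reflects inter-individual variability only;
#' `include_sigma = TRUE` adds residual noise to the simulated
#' observations. Bins are the unique x values when few, otherwise quantile
#' bins holding at least 10 observations each.
#'
#' For the cortisol PD model, whose records mix two time scales (time after
#' dose and clock time), a time-binned VPC is not well defined; use
#' [gof_table()] and [trellis_data()] there, or a clock-time VPC
#' (`x = "CLOCK"`) as an explicitly labelled extension.
#'
#' @param fit An `htp_fit`.
#' @param x Name of the binning variable in the fit data (e.g. `"TAD"` for
#'   the PK model, `"CCOL"` for the saliva model).
#' @param n_sim Number of simulated individuals (a warning is issued below
#'   50, where the percentiles are unstable).
#' @param include_sigma Add residual noise to simulated values.
#' @param include_omega Draw random effects (FALSE gives the typical
#'   population curve and a zero-width band).
#' @param seed Integer seed; the result is reproducible per seed.
#' @param data Optional alternative design/observation rows.
#' @return An object of class `htp_vpc`: `$summary` (one row per bin with
#'   observed and simulated statistics), `$observations`, and the settings.
#' @export
vpc <- function(fit, x = "TAD", n_sim = 1000, include_sigma = FALSE,
                include_omega = TRUE, seed = 1L, data = NULL) {
  stopifnot(inherits(fit, "htp_fit"))
  if (n_sim < 50) {
    warning("n_sim < 50 gives unstable prediction-interval estimates.",
            call. = FALSE)
  }
  d <- if (is.null(data)) fit$data else data
  if (!x %in% names(d)) {
    stop("Binning variable `", x, "` is not a column of the fit data.",
         call. = FALSE)
  }
  spec <- fit$spec
  nb <- length(spec$iiv) + length(spec$iov)
  sd_b <- sqrt(c(fit$omega2, fit$iov2))
  sim <- function() {
    out <- matrix(NA_real_, nrow(d), n_sim)
    for (s in seq_len(n_sim)) {
      b <- if (include_omega && nb > 0) stats::rnorm(nb, 0, sd_b)
           else numeric(nb)
      p <- as.list(fit$theta_all)
      # per simulated individual: one eta per IIV parameter plus one
      # occasion draw per IOV parameter (a fresh occasion is simulated)
      dev <- stats::setNames(numeric(length(p)), names(p))
      for (j in seq_along(spec$iiv)) dev[spec$iiv[j]] <-
        dev[spec$iiv[j]] + b[j]
      for (j in seq_along(spec$iov)) dev[spec$iov[j]] <-
        dev[spec$iov[j]] + b[length(spec$iiv) + j]
      for (nm in union(spec$iiv, spec$iov)) {
        p[[nm]] <- if (spec$re_dist[[nm]] == "normal") p[[nm]] + dev[nm]
                   else p[[nm]] * exp(dev[nm])
      }
      f <- fit$pred_fn(p, d)
      if (include_sigma) {
        v <- pmax(residual_variance(pmax(f, 0), fit$sigma[["prop"]],
                                    fit$sigma[["add"]]), 0)
        f <- f + stats::rnorm(length(f), 0, sqrt(v))
      }
      out[, s] <- f
    }
    out
  }
  sims <- withr::with_seed(seed, sim())
  xv <- d[[x]]
  ux <- sort(unique(xv))
  if (length(ux) <= max(15, floor(nrow(d) / 10))) {
    bin <- match(xv, ux)
  } else {
    n_bins <- max(1, min(10, floor(nrow(d) / 10)))
    brk <- unique(stats::quantile(xv, probs = seq(0, 1, length.out =
                                                    n_bins + 1)))
    bin <- as.integer(cut(xv, breaks = brk, include.lowest = TRUE))
  }
  summ <- lapply(sort(unique(bin)), function(bn) {
    idx <- bin == bn
    sm <- sims[idx, , drop = FALSE]
    tibble::tibble(
      bin = bn, x = stats::median(xv[idx]), n_obs = sum(idx),
      obs_median = stats::median(d$DV[idx]),
      sim_median = stats::median(sm),
      sim_lo = stats::quantile(sm, 0.025, names = FALSE),
      sim_hi = stats::quantile(sm, 0.975, names = FALSE))
  })
  structure(
    list(summary = dplyr::bind_rows(summ),
         observations = tibble::tibble(x = xv, DV = d$DV, bin = bin),
         n_sim = n_sim, include_sigma = include_sigma,
         include_omega = include_omega, seed = seed, x = x),
    class = "htp_vpc"
  )
}

#' @export
print.htp_vpc <- function(x, ...) {
  cat("<htp_vpc>", x$n_sim, "simulated individuals over", x$x,
      "| sigma", if (x$include_sigma) "included" else "excluded", "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Observations over the simulated median and 95% prediction band.
#'
#' @param object An `htp_vpc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.htp_vpc <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_median)) +
    ggplot2::geom_point(data = object$observations,
                        ggplot2::aes(x = .data$x, y = .data$DV),
                        shape = 1, alpha = 0.6) +
    ggplot2::labs(x = object$x, y = "observation",
                  title = sprintf("VPC (%d simulated individuals)",
                                  object$n_sim))
}

#' Goodness-of-fit table
#'
#' One record per observation with the population prediction (all random
#' effects zero), the individual prediction (empirical Bayes estimates),
#' the residual, and the weighted residual
#' `(obs - ipred) / sqrt(Var(ipred))` under the fitted residual model.
#'
#' @param fit An `htp_fit`.
#' @param data Optional alternative observation rows.
#' @return A tibble (the fit data plus `pred`, `ipred`, `residual`,
#'   `wres`).
#' @export
gof_table <- function(fit, data = NULL) {
  out <- predict_individual(fit, newdata = data)
  out$residual <- out$DV - out$ipred
  v <- residual_variance(pmax(out$ipred, 0), fit$sigma[["prop"]],
                         fit$sigma[["add"]])
  out$wres <- out$residual / sqrt(v)
  out
}

#' Per-subject prediction series for trellis plots
#'
#' Observations, population prediction and individual prediction per
#' subject and occasion, with an identification label (study, subject,
#' treatment), the data behind the classic trellis panel display.
#'
#' @param fit An `htp_fit`.
#' @param data Optional alternative observation rows.
#' @return A tibble with a `panel` label column; one panel per subject x
#'   occasion present.
#' @export
trellis_data <- function(fit, data = NULL) {
  out <- predict_individual(fit, newdata = data)
  study <- if ("STUDY" %in% names(out)) out$STUDY else ""
  trt <- if ("TRT" %in% names(out)) out$TRT else NA
  occ <- if ("OCC" %in% names(out)) out$OCC else 1L
  out$panel <- paste0(study, "/", out$ID, "/occ", occ,
                      ifelse(is.na(trt), "",
                             ifelse(trt == 1, "/treatment", "/placebo")))
  out
}

#' Plot per-subject fits as a trellis of panels
#'
#' @param fit An `htp_fit`.
#' @param x Time axis column (default `"CLOCK"` if present, else `"TAD"`).
#' @param data Optional alternative observation rows.
#' @return A ggplot: open circles are observations, solid line the
#'   population prediction, dashed line the individual prediction.
#' @export
plot_trellis <- function(fit, x = NULL, data = NULL) {
  d <- trellis_data(fit, data = data)
  if (is.null(x)) x <- if ("CLOCK" %in% names(d)) "CLOCK" else "TAD"
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]])) +
    ggplot2::geom_point(ggplot2::aes(y = .data$DV), shape = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred), linetype = "solid") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ipred), linetype = "dashed") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = x, y = "observation")
}

#' Basic goodness-of-fit plot for a population fit
#'
#' Observed versus population and individual predictions with the identity
#' line.
#'
#' @param object An `htp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.htp_fit <- function(object, ...) {
  g <- gof_table(object)
  long <- tidyr::pivot_longer(g, c("pred", "ipred"),
                              names_to = "kind", values_to = "prediction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$prediction, y = .data$DV)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(shape = 1, alpha = 0.6) +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::labs(x = "prediction", y = "observation")
}
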