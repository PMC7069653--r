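#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.htp_fit <- function(x, ...) {
  cat("<htp_fit>", x$stage, "model:",
      x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat("  OFV:", format(x$ofv, digits = 8),
      if (isTRUE(x$convergence$status)) "(converged)" else "(NOT converged)",
      "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a population fit into a parameter table
#'
#' One row per estimated quantity, in the layout of a population-model
#' parameter table: fixed effects, IIV variances (omega^2), IOV variances
#' and residual SDs, with standard errors and RSE% when available.
#'
#' @param x An `htp_fit`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `type`, `estimate`, `se`,
#'   `rse`.
#' @export
tidy.htp_fit <- function(x, ...) {
  # note: paste0() recycles zero-length input to "", so empty blocks
  # must be skipped explicitly
  tab <- tibble::tibble(
    parameter = c(names(x$theta),
                  if (length(x$omega2)) paste0("omega2_",
                                               names(x$omega2)),
                  if (length(x$iov2)) paste0("iov2_", names(x$iov2)),
                  c("sigma_prop", "sigma_add")[c(x$spec$sigma_prop > 0,
                                                 x$spec$sigma_add > 0)]),
    type = c(rep("theta", length(x$theta)),
             rep("omega2", length(x$omega2)),
             rep("iov2", length(x$iov2)),
             rep("sigma", (x$spec$sigma_prop > 0) + (x$spec$sigma_add > 0))),
    estimate = c(unname(x$theta), unname(x$omega2), unname(x$iov2),
                 unname(x$sigma[c("prop", "add")[c(x$spec$sigma_prop > 0,
                                                   x$spec$sigma_add > 0)]]))
  )
  if (!is.null(x$se_table)) {
    tab <- dplyr::left_join(
      tab, dplyr::select(x$se_table, "parameter", "se", "rse"),
      by = "parameter")
  } else {
    tab$se <- NA_real_
    tab$rse <- NA_real_
  }
  tab
}

#' One-line model summary
#'
#' @param x An `htp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `ofv`, `n_subjects`, `n_obs`, `n_params`,
#'   `converged`, `iterations`.
#' @export
glance.htp_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv,
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    n_params = length(x$theta) + length(x$omega2) + length(x$iov2) +
      (x$spec$sigma_prop > 0) + (x$spec$sigma_add > 0),
    converged = isTRUE(x$convergence$status),
    iterations = x$convergence$iterations
  )
}

#' Population and individual predictions from a fit
#'
#' Evaluates the fitted model at each row of `newdata` (default: the data
#' the model was fitted to) twice: at the population parameters (all random
#' effects zero, `pred`) and at each subject's empirical Bayes estimates
#' (`ipred`).
#'
#' @param fit An `htp_fit`.
#' @param newdata Optional rows with the same columns the model's
#'   prediction function uses (including `ID`, and `OCC` if the model has
#'   IOV). Subjects unseen at fit time get zero random effects.
#' @return `newdata` with `pred` and `ipred` columns appended, as a tibble.
#' @export
predict_individual <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "htp_fit"))
  data <- if (is.null(newdata)) fit$data else newdata
  if (!"DV" %in% names(data)) data$DV <- NA_real_
  spec <- fit$spec
  subjects <- engine_split(data, spec)
  plan <- engine_plan(spec)
  n_iiv <- length(spec$iiv)
  base <- as.list(fit$theta_all)
  out <- lapply(subjects, function(subj) {
    nb <- engine_b_dim(spec, subj$n_occ)
    b <- engine_lookup_b(fit$ebes, spec, subj)
    p0 <- engine_ind_params(base, plan, n_iiv, numeric(nb), subj)
    pi <- engine_ind_params(base, plan, n_iiv, b, subj)
    d <- tibble::as_tibble(subj$d)
    d$pred <- fit$pred_fn(p0, subj$d)
    d$ipred <- fit$pred_fn(pi, subj$d)
    d
  })
  dplyr::bind_rows(out)
}

# assemble a subject's b vector from the stored EBE table (zero if absent)
engine_lookup_b <- function(ebes, spec, subj) {
  nb <- engine_b_dim(spec, subj$n_occ)
  b <- numeric(nb)
  if (is.null(ebes) || nrow(ebes) == 0) return(b)
  e <- ebes[ebes$ID == subj$id, , drop = FALSE]
  if (nrow(e) == 0) return(b)
  n_iiv <- length(spec$iiv)
  for (j in seq_len(n_iiv)) {
    v <- e$value[e$type == "eta" & e$param == spec$iiv[j]]
    if (length(v) == 1) b[j] <- v
  }
  occ_levels <- sort(unique(subj$d$OCC))
  for (j in seq_along(spec$iov)) {
    for (k in seq_along(occ_levels)) {
      v <- e$value[e$type == "kappa" & e$param == spec$iov[j] &
                     e$OCC == occ_levels[k]]
      if (length(v) == 1) b[n_iiv + (j - 1L) * subj$n_occ + k] <- v
    }
  }
  b
}
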