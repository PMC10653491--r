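#' Ignore-censoring baseline
#'
#' Treats every censoring time as an actual event: the response is
#' `v2 - v1` for all samples regardless of the indicators, then the usual
#' screening battery is applied.
#'
#' @inheritParams screen_covariates
#' @param obs data frame with `v1`, `delta1`, `v2`, `delta2`.
#' @return screening data frame (see [screen_covariates()]).
#' @export
baseline_ignored <- function(obs, covariates, variable_types,
                             tests = c("anova", "permutation", "rank"),
                             n_perm = 1000L, seed = 1L) {
  screen_covariates(covariates, variable_types, obs$v2 - obs$v1,
                    tests = tests, n_perm = n_perm, seed = seed)
}

#' Complete-case (no-censor) baseline
#'
#' Restricts the analysis to samples with both events observed
#' (`delta1 = delta2 = 1`) and screens on `v2 - v1` within that subset.
#'
#' @inheritParams baseline_ignored
#' @return screening data frame with attribute `"n_complete"`.
#' @export
baseline_no_censor <- function(obs, covariates, variable_types,
                               tests = c("anova", "permutation", "rank"),
                               n_perm = 1000L, seed = 1L) {
  keep <- obs$delta1 == 1L & obs$delta2 == 1L
  if (sum(keep) < 3L) stop("fewer than 3 complete cases", call. = FALSE)
  res <- screen_covariates(covariates[keep, , drop = FALSE], variable_types,
                           obs$v2[keep] - obs$v1[keep],
                           tests = tests, n_perm = n_perm, seed = seed)
  attr(res, "n_complete") <- sum(keep)
  res
}

#' Univariate Cox regression per covariate for a single event
#'
#' Fits a univariate proportional-hazards model of the chosen event's
#' `(V, Delta)` on each covariate separately (Newton-Raphson on the partial
#' likelihood with the Breslow tie approximation, via
#' [survival::coxph.fit()]) and reports the Wald p-value on the
#' coefficient. The other event is ignored entirely. Non-convergent or
#' degenerate fits yield `NA` p-values.
#'
#' @param obs data frame with `v1`, `delta1`, `v2`, `delta2`.
#' @param covariates n x p numeric matrix.
#' @param event which event to model (1 or 2).
#' @return data frame with `variable`, `test`, `statistic` (Wald z) and
#'   `p_value`.
#' @export
cox_per_variable <- function(obs, covariates, event = 1L) {
  stopifnot(event %in% c(1L, 2L))
  v <- if (event == 1L) obs$v1 else obs$v2
  d <- if (event == 1L) obs$delta1 else obs$delta2
  y <- survival::Surv(as.numeric(v), as.numeric(d))
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  vnames <- colnames(x)
  if (is.null(vnames)) vnames <- sprintf("x%04d", seq_len(ncol(x)))
  ctrl <- survival::coxph.control()
  z <- vapply(seq_len(ncol(x)), function(j) {
    xj <- x[, j, drop = FALSE]
    if (stats::sd(xj) == 0) return(NA_real_)
    fit <- tryCatch(
      survival::coxph.fit(xj, y, strata = NULL, offset = NULL, init = 0,
                          control = ctrl, weights = NULL, method = "breslow",
                          rownames = NULL),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit) || !is.finite(fit$coefficients) || !is.finite(fit$var) ||
        fit$var <= 0) return(NA_real_)
    fit$coefficients / sqrt(fit$var)
  }, numeric(1))
  data.frame(variable = vnames,
             test = sprintf("cox_event%d", event),
             statistic = z,
             p_value = 2 * stats::pnorm(-abs(z)))
}
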