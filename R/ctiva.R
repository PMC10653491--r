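#' Censored time interval variable analysis
#'
#' Fits the full analysis to a doubly right-censored bivariate
#' time-to-event dataset: (1) estimates the joint density of the two event
#' times with the Optional Polya Tree expected-count iteration
#' ([opt_joint()]); (2) computes each sample's conditional expected interval
#' `E[T2 - T1 | observation]` by Monte Carlo ([estimate_intervals()]); and
#' (3) screens every covariate for association with the expected interval
#' ([screen_covariates()]).
#'
#' @param data either a data frame with columns `v1`, `delta1`, `v2`,
#'   `delta2`, or a simulated replicate from [make_replicate()] (whose
#'   covariates and types are then used automatically).
#' @param covariates optional n x p numeric covariate matrix.
#' @param variable_types optional `"categorical"`/`"continuous"` per column;
#'   inferred (at most 10 distinct integral values means categorical) when
#'   missing.
#' @param tests screening batteries to run.
#' @param max_depth,tol,max_iter density-fitting controls, see
#'   [opt_joint()].
#' @param n_mc Monte-Carlo draws per censored observation.
#' @param n_perm permutations for the permutation battery.
#' @param seed integer master seed for the Monte-Carlo and permutation
#'   stages.
#' @return object of class `"ctiva"`: list with `density` (the fitted
#'   `"opt_density"`), `intervals` (per-sample expected intervals),
#'   `results` (long screening data frame or `NULL`), `obs`, plus the call
#'   and settings.
#' @examples
#' rep <- make_replicate(sim_config(n_samples = 60, n_variables = 8,
#'   block_sizes = c(2, 2, 2, 2), seed = 3))
#' fit <- ctiva(rep, tests = "anova", max_depth = 5, n_mc = 200)
#' summary(fit)
#' @export
ctiva <- function(data, covariates = NULL, variable_types = NULL,
                  tests = c("anova", "permutation", "rank"),
                  max_depth = 8L, tol = 1e-3, max_iter = 20L,
                  n_mc = 1000L, n_perm = 1000L, seed = 1L) {
  cl <- match.call()
  if (inherits(data, "ctiva_sim")) {
    if (is.null(covariates)) covariates <- data$covariates
    if (is.null(variable_types)) variable_types <- data$variable_types
    obs <- data$observations
  } else {
    obs <- as.data.frame(data)
  }
  req <- c("v1", "delta1", "v2", "delta2")
  if (!all(req %in% names(obs))) {
    stop("`data` must provide columns v1, delta1, v2, delta2", call. = FALSE)
  }
  obs <- obs[req]
  density <- opt_joint(obs$v1, obs$delta1, obs$v2, obs$delta2,
                       max_depth = max_depth, tol = tol, max_iter = max_iter)
  intervals <- estimate_intervals(density, obs, n_mc = n_mc, seed = seed)
  results <- NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(variable_types)) {
      variable_types <- ifelse(apply(covariates, 2L, is_categorical_vec),
                               "categorical", "continuous")
    }
    results <- screen_covariates(covariates, variable_types, intervals$y,
                                 tests = tests, n_perm = n_perm, seed = seed)
  }
  structure(list(density = density, intervals = intervals, results = results,
                 obs = obs, tests = tests, n_mc = n_mc, n_perm = n_perm,
                 seed = seed, call = cl),
            class = "ctiva")
}

#' @export
print.ctiva <- function(x, ...) {
  cat("Censored time interval variable analysis\n")
  cat(sprintf("  %d samples; cases: %s\n", nrow(x$obs),
              paste(names(table(x$intervals$case)), table(x$intervals$case),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  density: %d iteration(s), %s\n", x$density$iterations,
              if (isTRUE(x$density$converged)) "converged" else "not converged"))
  if (!is.null(x$results)) {
    cat(sprintf("  screened %d covariates with: %s\n",
                length(unique(x$results$variable)),
                paste(x$tests, collapse = ", ")))
  }
  invisible(x)
}

#' Summarize a fitted analysis
#'
#' @param object a `"ctiva"` fit.
#' @param cutoff p-value cutoff used to count detections.
#' @param ... unused.
#' @return object of class `"summary.ctiva"` with the interval summary and,
#'   when covariates were screened, per-battery detection counts and the
#'   most significant variables.
#' @export
summary.ctiva <- function(object, cutoff = 0.05, ...) {
  out <- list(
    n = nrow(object$obs),
    cases = table(object$intervals$case),
    interval_summary = summary(object$intervals$y),
    mean_mc_se = mean(object$intervals$mc_se),
    cutoff = cutoff
  )
  if (!is.null(object$results)) {
    res <- object$results
    det <- stats::aggregate(p_value ~ test, data = res,
                            FUN = function(p) sum(p < cutoff, na.rm = TRUE))
    names(det)[2L] <- "n_detected"
    top <- res[order(res$p_value), ]
    out$detections <- det
    out$top <- utils::head(top, 10L)
  }
  class(out) <- "summary.ctiva"
  out
}

#' @export
print.summary.ctiva <- function(x, ...) {
  cat(sprintf("CTIVA fit on %d samples\n", x$n))
  cat("Censoring cases:\n"); print(x$cases)
  cat("Expected intervals E[T2 - T1 | obs]:\n"); print(x$interval_summary)
  cat(sprintf("Mean Monte-Carlo SE: %.4f\n", x$mean_mc_se))
  if (!is.null(x$detections)) {
    cat(sprintf("Detections at p < %g by test:\n", x$cutoff))
    print(x$detections, row.names = FALSE)
    cat("Most significant variables:\n")
    print(x$top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Expected intervals for new observations
#'
#' @param object a `"ctiva"` fit.
#' @param newdata data frame with `v1`, `delta1`, `v2`, `delta2`; defaults
#'   to the fitted observations.
#' @param n_mc,seed Monte-Carlo controls.
#' @param ... unused.
#' @return numeric vector of expected intervals.
#' @export
predict.ctiva <- function(object, newdata = NULL, n_mc = NULL, seed = NULL, ...) {
  if (is.null(newdata)) return(object$intervals$y)
  if (is.null(n_mc)) n_mc <- object$n_mc
  if (is.null(seed)) seed <- object$seed
  estimate_intervals(object$density, as.data.frame(newdata),
                     n_mc = n_mc, seed = seed)$y
}

#' @export
plot.ctiva <- function(x, ...) {
  plot(x$density, ...)
  both <- x$intervals$case == "both_observed"
  graphics::points(x$obs$v1[both], x$obs$v2[both], pch = 16, cex = 0.4)
  graphics::points(x$obs$v1[!both], x$obs$v2[!both], pch = 2, cex = 0.4)
  invisible(x)
}
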