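#' Write a censored dataset (and optional sidecar metadata) to CSV
#'
#' The CSV holds the observation columns `v1, delta1, v2, delta2` followed
#' by the covariate columns. The sidecar JSON records the variable types
#' and, for simulated data, the truth labels and generating configuration;
#' it is meant for evaluation only and is never read by the fitting
#' pipeline.
#'
#' @param x a `"ctiva_sim"` replicate or a list with `observations`,
#'   `covariates`, `variable_types` (and optionally `truth`, `config`).
#' @param path output CSV path.
#' @param sidecar optional JSON path for the metadata.
#' @return `path`, invisibly.
#' @export
write_ctiva_data <- function(x, path, sidecar = NULL) {
  df <- cbind(x$observations, as.data.frame(x$covariates))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(sidecar)) {
    meta <- list(variable_types = x$variable_types)
    if (!is.null(x$truth)) meta$truth <- x$truth
    if (!is.null(x$config)) meta$config <- unclass(x$config)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a censored dataset from CSV
#'
#' Validates the required columns (`v1, delta1, v2, delta2`): indicators
#' must be 0/1 and times finite and nonnegative, with offending row numbers
#' reported. Remaining columns are covariates; their types come from the
#' sidecar when present, otherwise a column with at most 10 distinct
#' integral values is inferred categorical (with a notice).
#'
#' @param path CSV path.
#' @param sidecar optional sidecar JSON path written by
#'   [write_ctiva_data()].
#' @return list with `observations`, `covariates` (matrix or `NULL`),
#'   `variable_types` and `meta` (sidecar contents or `NULL`).
#' @export
read_ctiva_data <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  req <- c("v1", "delta1", "v2", "delta2")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing required columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (dc in c("delta1", "delta2")) {
    bad <- which(!(df[[dc]] %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop(sprintf("non-binary %s in row(s) %s", dc,
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  for (vc in c("v1", "v2")) {
    bad <- which(!is.finite(df[[vc]]) | df[[vc]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("non-finite or negative %s in row(s) %s", vc,
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  obs <- df[req]
  covcols <- setdiff(names(df), req)
  covariates <- NULL
  types <- NULL
  meta <- NULL
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    types <- meta$variable_types
  }
  if (length(covcols) > 0L) {
    covariates <- as.matrix(df[covcols])
    if (is.null(types)) {
      types <- ifelse(apply(covariates, 2L, is_categorical_vec),
                      "categorical", "continuous")
      message(sprintf("no sidecar: inferred %d categorical / %d continuous covariates",
                      sum(types == "categorical"), sum(types == "continuous")))
    }
  }
  list(observations = obs, covariates = covariates,
       variable_types = types, meta = meta)
}

#' Export a fitted density to JSON
#'
#' Writes the leaf rectangles (`lo1, hi1, lo2, hi2, density`) and the
#' sample-space metadata, enough to reconstruct the piecewise-constant
#' density exactly.
#'
#' @param fit an `"opt_density"` object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
export_density <- function(fit, path) {
  stopifnot(inherits(fit, "opt_density"))
  leaves <- fit$leaves
  if (is.null(leaves)) stop("density has no leaf representation", call. = FALSE)
  jsonlite::write_json(list(
    omega = fit$omega, k = nrow(fit$grid), n = fit$n,
    leaves = leaves[, c("lo1", "hi1", "lo2", "hi2", "density")]
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a fitted density from JSON
#'
#' @param path JSON path written by [export_density()].
#' @return an `"opt_density"` object.
#' @export
import_density <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- d$k
  b1 <- seq(0, d$omega[1L], length.out = k + 1L)
  b2 <- seq(0, d$omega[2L], length.out = k + 1L)
  grid <- matrix(0, k, k)
  lv <- d$leaves
  for (r in seq_len(nrow(lv))) {
    rows <- (round(lv$lo1[r] / d$omega[1L] * k) + 1L):round(lv$hi1[r] / d$omega[1L] * k)
    cols <- (round(lv$lo2[r] / d$omega[2L] * k) + 1L):round(lv$hi2[r] / d$omega[2L] * k)
    grid[rows, cols] <- lv$density[r]
  }
  new_opt_density(grid, b1, b2, leaves = lv, n = d$n)
}

#' Run the full pipeline and persist its artifacts
#'
#' Fits the density, estimates the expected intervals, screens the
#' covariates (when present) and writes `density.json`, `intervals.csv`,
#' `results.csv`, `metrics.json` (when truth labels are available in the
#' sidecar) and `run.log` into `out_dir`.
#'
#' @param input path to a dataset CSV (see [read_ctiva_data()]) or a
#'   `"ctiva_sim"` replicate.
#' @param out_dir output directory (created if needed).
#' @param sidecar optional sidecar JSON accompanying a CSV input.
#' @param ... passed to [ctiva()].
#' @return the `"ctiva"` fit, invisibly.
#' @export
run_pipeline <- function(input, out_dir, sidecar = NULL, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  if (inherits(input, "ctiva_sim")) {
    ds <- list(observations = input$observations, covariates = input$covariates,
               variable_types = input$variable_types,
               meta = list(truth = input$truth))
  } else {
    ds <- read_ctiva_data(input, sidecar)
  }
  fit <- ctiva(ds$observations, ds$covariates, ds$variable_types, ...)
  export_density(fit$density, file.path(out_dir, "density.json"))
  utils::write.csv(fit$intervals, file.path(out_dir, "intervals.csv"),
                   row.names = FALSE)
  if (!is.null(fit$results)) {
    utils::write.csv(fit$results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(ds$meta$truth)) {
      truth <- ds$meta$truth == "interval"
      metrics <- lapply(intersect(fit$tests, c("anova", "permutation", "rank")),
                        function(b) {
        roc <- roc_auc(battery_pvalues(fit$results, b), truth)
        list(test = b, auc = roc$auc, operating = roc$operating)
      })
      jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  log_lines <- c(
    sprintf("ctiva version: %s", as.character(utils::packageVersion("ctiva"))),
    sprintf("started: %s", format(t0)),
    sprintf("samples: %d", nrow(ds$observations)),
    sprintf("covariates: %d", if (is.null(ds$covariates)) 0L else ncol(ds$covariates)),
    sprintf("density iterations: %d (converged: %s)",
            fit$density$iterations, fit$density$converged),
    sprintf("tv trace: %s", paste(signif(fit$density$tv_trace, 3), collapse = " ")),
    sprintf("zero-mass fallbacks: %d", fit$density$n_fallback),
    sprintf("seed: %d, n_mc: %d, n_perm: %d", fit$seed, fit$n_mc, fit$n_perm),
    sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(fit)
}
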