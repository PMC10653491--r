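battery_pvalues <- function(results, battery) {
  sub <- switch(battery,
    anova = results[results$test %in% c("anova", "linear"), ],
    permutation = results[results$test == "permutation", ],
    rank = results[results$test == "rank_correlation", ]
  )
  sub$p_value
}

#' Run the repeated-simulation experiment
#'
#' Generates `n_replicates` seeded replicates of a simulation configuration,
#' runs the requested methods (the OPT-based interval analysis and/or the
#' baselines) with the requested test batteries on each, and aggregates the
#' AUC and the sensitivity/specificity at the stated p-value cutoffs for
#' detecting the interval-correlated variables.
#'
#' @param config a [sim_config()] object (its `seed` field is ignored;
#'   replicate `r` uses `master_seed + r`).
#' @param methods subset of `c("ctiva", "ignored", "no_censor", "cox1",
#'   "cox2")`.
#' @param tests batteries for the screening-based methods (the Cox
#'   baselines have a single Wald-test column).
#' @param n_replicates number of replicates.
#' @param master_seed integer; replicate `r` is seeded with
#'   `master_seed + r`.
#' @param n_mc,n_perm Monte-Carlo and permutation sizes.
#' @param max_depth,tol,max_iter density-fitting controls.
#' @param cutoffs p-value cutoffs for sensitivity/specificity.
#' @return object of class `"ctiva_experiment"`: list with `raw` (one row
#'   per replicate x method x test) and `summary` (mean and SD of AUC and
#'   the operating characteristics per cell).
#' @export
run_experiment <- function(config,
                           methods = c("ctiva", "ignored", "no_censor", "cox1", "cox2"),
                           tests = c("anova", "permutation", "rank"),
                           n_replicates = 20L, master_seed = 1L,
                           n_mc = 1000L, n_perm = 1000L,
                           max_depth = 8L, tol = 1e-3, max_iter = 20L,
                           cutoffs = c(0.01, 0.05, 0.1)) {
  stopifnot(inherits(config, "ctiva_sim_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  tests <- match.arg(tests, several.ok = TRUE)
  rows <- list()
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- master_seed + r
    rep <- make_replicate(cfg)
    obs <- rep$observations
    truth <- rep$truth == "interval"
    add_row <- function(method, test, p) {
      roc <- roc_auc(p, truth, cutoffs = cutoffs)
      row <- data.frame(replicate = r, method = method, test = test,
                        auc = roc$auc)
      for (i in seq_along(cutoffs)) {
        row[[sprintf("sens_%g", cutoffs[i])]] <- roc$operating$sensitivity[i]
        row[[sprintf("spec_%g", cutoffs[i])]] <- roc$operating$specificity[i]
      }
      rows[[length(rows) + 1L]] <<- row
    }
    run_cell <- function(expr) {
      tryCatch(expr, error = function(e) {
        failures <<- failures + 1L
        warning(sprintf("replicate %d cell failed: %s", r, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    }
    if ("ctiva" %in% methods) {
      run_cell({
        fit <- ctiva(obs, rep$covariates, rep$variable_types, tests = tests,
                     max_depth = max_depth, tol = tol, max_iter = max_iter,
                     n_mc = n_mc, n_perm = n_perm, seed = master_seed + r)
        for (b in tests) add_row("ctiva", b, battery_pvalues(fit$results, b))
      })
    }
    if ("ignored" %in% methods) {
      run_cell({
        res <- baseline_ignored(obs, rep$covariates, rep$variable_types,
                                tests = tests, n_perm = n_perm,
                                seed = master_seed + r)
        for (b in tests) add_row("ignored", b, battery_pvalues(res, b))
      })
    }
    if ("no_censor" %in% methods) {
      run_cell({
        res <- baseline_no_censor(obs, rep$covariates, rep$variable_types,
                                  tests = tests, n_perm = n_perm,
                                  seed = master_seed + r)
        for (b in tests) add_row("no_censor", b, battery_pvalues(res, b))
      })
    }
    for (ev in 1:2) {
      m <- sprintf("cox%d", ev)
      if (m %in% methods) {
        run_cell({
          res <- cox_per_variable(obs, rep$covariates, event = ev)
          add_row(m, "wald", res$p_value)
        })
      }
    }
  }
  raw <- do.call(rbind, rows)
  agg_mean <- stats::aggregate(raw[, -(1:3)], by = raw[c("method", "test")], FUN = mean)
  agg_sd <- stats::aggregate(raw[, -(1:3)], by = raw[c("method", "test")],
                             FUN = stats::sd)
  names(agg_sd)[-(1:2)] <- paste0(names(agg_sd)[-(1:2)], "_sd")
  structure(list(raw = raw, summary = merge(agg_mean, agg_sd),
                 n_replicates = n_replicates, failures = failures,
                 master_seed = master_seed, config = config),
            class = "ctiva_experiment")
}

#' @export
print.ctiva_experiment <- function(x, ...) {
  cat(sprintf("Repeated-simulation experiment: %d replicates (%s model)\n",
              x$n_replicates, x$config$model))
  if (x$failures > 0L) cat(sprintf("  %d failed cells excluded\n", x$failures))
  cols <- c("method", "test", "auc", "auc_sd")
  print(x$summary[order(-x$summary$auc), cols], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-method AUC vectors for box plots
#'
#' @param experiment a [run_experiment()] result.
#' @return named list of per-replicate AUC vectors, one per method/test
#'   cell; empty cells are omitted with a warning.
#' @export
make_boxplot_data <- function(experiment) {
  raw <- experiment$raw
  cells <- split(raw$auc, paste(raw$method, raw$test, sep = "."))
  empty <- vapply(cells, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sprintf("omitting empty cells: %s",
                    paste(names(cells)[empty], collapse = ", ")), call. = FALSE)
    cells <- cells[!empty]
  }
  cells
}
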