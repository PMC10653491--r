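test_result <- function(test, statistic, p_value) {
  list(test = test, statistic = unname(statistic), p_value = unname(p_value))
}

is_categorical_vec <- function(x) {
  is.factor(x) || is.character(x) ||
    (length(unique(x)) <= 10L && all(x == round(x)))
}

#' One-way ANOVA p-value
#'
#' F-test of equality of the response means across the levels of a
#' categorical covariate.
#'
#' @param x categorical covariate (factor or discrete codes).
#' @param y numeric response.
#' @return list with `test`, `statistic` (F) and `p_value`.
#' @export
anova_p <- function(x, y) {
  g <- factor(x)
  ng <- table(g)
  if (nlevels(g) < 2L) stop("ANOVA needs at least 2 groups", call. = FALSE)
  if (any(ng < 2L)) stop("every group needs at least 2 members", call. = FALSE)
  n <- length(y)
  k <- nlevels(g)
  mu <- mean(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(ng * (gm - mu)^2)
  ssw <- sum((y - gm[g])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  test_result("anova", f, stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Linear-regression slope p-value
#'
#' Two-sided t-test on the slope of `y ~ x`; the t statistic equals
#' `r * sqrt((n - 2) / (1 - r^2))` with `r` the Pearson correlation.
#'
#' @param x numeric covariate (non-constant).
#' @param y numeric response.
#' @return list with `test`, `statistic` (t) and `p_value`.
#' @export
linear_p <- function(x, y) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant covariate", call. = FALSE)
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  test_result("linear", t, 2 * stats::pt(-abs(t), n - 2))
}

#' Spearman rank-correlation p-value
#'
#' Spearman correlation on midranks with the t-approximation p-value;
#' binary categorical covariates enter as 0/1 codes.
#'
#' @param x covariate (numeric or binary codes).
#' @param y numeric response.
#' @return list with `test`, `statistic` (rho) and `p_value`.
#' @export
rank_corr_p <- function(x, y) {
  n <- length(y)
  if (n < 5L) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(as.numeric(x)) == 0 || stats::sd(y) == 0) {
    stop("constant input", call. = FALSE)
  }
  rho <- stats::cor(rank(as.numeric(x)), rank(y))
  t <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  test_result("rank_correlation", rho, 2 * stats::pt(-abs(t), n - 2))
}

#' Permutation p-value
#'
#' Permutes the response while holding the covariate fixed; the statistic is
#' the one-way F for categorical covariates and the absolute Pearson
#' correlation for continuous ones. The p-value uses the add-one estimator
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @param x covariate.
#' @param y numeric response.
#' @param n_perm number of permutations (at least 100).
#' @param seed optional seed.
#' @param type `"auto"` infers categorical for <= 10 distinct integral
#'   values.
#' @return list with `test`, `statistic` and `p_value`.
#' @export
permutation_p <- function(x, y, n_perm = 1000L, seed = NULL,
                          type = c("auto", "categorical", "continuous")) {
  type <- match.arg(type)
  if (n_perm < 100L) stop("`n_perm` must be at least 100", call. = FALSE)
  if (type == "auto") type <- if (is_categorical_vec(x)) "categorical" else "continuous"
  n <- length(y)
  with_seed(seed, {
    if (type == "categorical") {
      g <- factor(x)
      k <- nlevels(g)
      if (k < 2L) stop("need at least 2 groups", call. = FALSE)
      gmat <- stats::model.matrix(~ g - 1)
      ng <- colSums(gmat)
      mu <- mean(y)
      sst <- sum((y - mu)^2)
      fstat <- function(ymat) {
        sg <- crossprod(gmat, ymat)              # k x B group sums
        ssb <- colSums(ng * (sg / ng - mu)^2)
        (ssb / (k - 1)) / ((sst - ssb) / (n - k))
      }
      obs <- fstat(matrix(y))
      perm <- fstat(vapply(seq_len(n_perm), function(b) y[sample.int(n)],
                           numeric(n)))
      test_result("permutation", obs, (1 + sum(perm >= obs)) / (n_perm + 1))
    } else {
      obs <- abs(stats::cor(x, y))
      perm <- abs(vapply(seq_len(n_perm),
                         function(b) stats::cor(x, y[sample.int(n)]),
                         numeric(1)))
      test_result("permutation", obs, (1 + sum(perm >= obs)) / (n_perm + 1))
    }
  })
}

# Pearson correlation of every column of X with y; constant columns -> NA
cor_with <- function(x, y) {
  suppressWarnings(as.vector(stats::cor(x, y)))
}

p_from_r <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), n - 2)
}

#' Screen covariates against the expected interval
#'
#' Computes one p-value per covariate for each requested test battery:
#' `"anova"` applies the one-way ANOVA to categorical covariates and the
#' linear-regression slope test to continuous ones (a single shared
#' threshold is used downstream); `"permutation"` permutes the response
#' (F statistic for categorical, |Pearson r| for continuous); `"rank"` is
#' the Spearman midrank test. Binary categorical and continuous covariates
#' are computed in vectorized form; categorical covariates with more than
#' two levels fall back to the per-variable tests.
#'
#' @param covariates n x p numeric matrix (binary 0/1 columns for
#'   categorical covariates).
#' @param variable_types `"categorical"`/`"continuous"` per column.
#' @param y expected-interval response (length n).
#' @param tests subset of `c("anova", "permutation", "rank")`.
#' @param n_perm permutations for the permutation battery.
#' @param seed seed for the permutation battery.
#' @return data frame with `variable`, `type`, `test`, `statistic`,
#'   `p_value` (one row per covariate per test).
#' @export
screen_covariates <- function(covariates, variable_types, y,
                              tests = c("anova", "permutation", "rank"),
                              n_perm = 1000L, seed = 1L) {
  tests <- match.arg(tests, several.ok = TRUE)
  x <- as.matrix(covariates)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("`y` length must match covariate rows", call. = FALSE)
  if (length(variable_types) != p) stop("one type per covariate required", call. = FALSE)
  vnames <- colnames(x)
  if (is.null(vnames)) vnames <- sprintf("x%04d", seq_len(p))
  cat_idx <- variable_types == "categorical"
  nlev <- apply(x, 2L, function(col) length(unique(col)))
  multi <- cat_idx & nlev > 2L
  r <- cor_with(x, y)
  out <- list()
  if ("anova" %in% tests) {
    pv <- p_from_r(r, n)
    stat <- ifelse(cat_idx, (n - 2) * r^2 / pmax(1 - r^2, .Machine$double.eps),
                   r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps)))
    for (j in which(multi)) {
      res <- anova_p(x[, j], y)
      stat[j] <- res$statistic; pv[j] <- res$p_value
    }
    out$anova <- data.frame(variable = vnames, type = variable_types,
                            test = ifelse(cat_idx, "anova", "linear"),
                            statistic = stat, p_value = pv)
  }
  if ("rank" %in% tests) {
    xr <- apply(x, 2L, rank)
    rr <- cor_with(xr, rank(y))
    out$rank <- data.frame(variable = vnames, type = variable_types,
                           test = "rank_correlation",
                           statistic = rr, p_value = p_from_r(rr, n))
  }
  if ("permutation" %in% tests) {
    pv <- rep(NA_real_, p)
    ok <- !is.na(r) & !multi
    with_seed(seed, {
      yp <- vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))
      rp <- abs(suppressWarnings(stats::cor(x[, ok, drop = FALSE], yp)))
      pv[ok] <- (1 + rowSums(rp >= abs(r[ok]))) / (n_perm + 1)
      for (j in which(multi)) {
        pv[j] <- permutation_p(x[, j], y, n_perm = n_perm, type = "categorical")$p_value
      }
    })
    out$permutation <- data.frame(variable = vnames, type = variable_types,
                                  test = "permutation",
                                  statistic = abs(r), p_value = pv)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ROC curve and AUC from screening p-values
#'
#' Scores each variable by `-p` and computes the area under the ROC curve
#' with the tie-corrected rank (Mann-Whitney) formula, the ROC points at
#' every distinct threshold, and sensitivity/specificity at the stated
#' p-value cutoffs (detection means `p < cutoff`).
#'
#' @param p_values per-variable p-values (NAs are dropped with a warning).
#' @param truth logical (or 0/1) labels: `TRUE` for true signal variables.
#' @param cutoffs p-value cutoffs at which to report sensitivity and
#'   specificity.
#' @return object of class `"ctiva_roc"`: list with `auc`, `roc` (data frame
#'   of `fpr`, `tpr`), `operating` (data frame of cutoff, sensitivity,
#'   specificity) and counts.
#' @export
roc_auc <- function(p_values, truth, cutoffs = c(0.01, 0.05, 0.1)) {
  truth <- as.logical(truth)
  keep <- !is.na(p_values)
  if (!all(keep)) {
    warning(sprintf("dropping %d NA p-values", sum(!keep)), call. = FALSE)
    p_values <- p_values[keep]; truth <- truth[keep]
  }
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L) {
    stop("truth needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(-p_values)  # midranks of the score -p
  auc <- (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
  th <- sort(unique(p_values))
  tpr <- vapply(th, function(t) mean(p_values[truth] <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(p_values[!truth] <= t), numeric(1))
  operating <- data.frame(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(t) mean(p_values[truth] < t), numeric(1)),
    specificity = vapply(cutoffs, function(t) mean(p_values[!truth] >= t), numeric(1))
  )
  structure(list(auc = auc,
                 roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)),
                 operating = operating, n_pos = npos, n_neg = nneg),
            class = "ctiva_roc")
}

#' @export
print.ctiva_roc <- function(x, ...) {
  cat(sprintf("ROC over %d positives / %d negatives: AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  print(x$operating, row.names = FALSE, digits = 3)
  invisible(x)
}
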