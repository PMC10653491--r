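#' Simulation configuration for bivariate censored time-to-event data
#'
#' Builds the configuration object consumed by [make_replicate()]. The
#' defaults reproduce the package's reference simulation: 500 samples, 1,000
#' binary covariates in blocks of 100 interval-correlated, 100 correlated
#' with the first event time, 100 with the second, and 700 null variables,
#' with event pairs from the additive-exponential model and independent
#' exponential censoring.
#'
#' @param model event-time generator: `"additive_exponential"` (T1 ~ exp,
#'   T2 = T1 + alpha with an independent exponential increment),
#'   `"log_normal"` (jointly log-normal pair) or `"clayton_oakes"` (Clayton
#'   survival copula with exponential margins).
#' @param n_samples number of samples per replicate.
#' @param n_variables total number of covariates.
#' @param block_sizes integer vector `c(interval, t1, t2, null)`; must sum to
#'   `n_variables`.
#' @param prop_categorical fraction of covariates (within every block) that
#'   are binary categorical; the remainder are continuous.
#' @param event_rate exponential rate of the event-time draws (rate `t`).
#' @param censor_rate exponential rate of the censoring draws (rate `c`).
#'   The default 0.35 yields roughly 26% censoring on event 1 and 45% on
#'   event 2 (about 35% overall) under the additive-exponential defaults.
#' @param exponent_power elementwise power applied to the exponential draws
#'   of the additive model (1 leaves the model untouched); the same power is
#'   applied to the censoring draws so the censoring fraction of event 1 is
#'   unchanged.
#' @param lognormal_params list with `mu_T`, `sigma_T`, `mu_C`, `sigma_C`
#'   for the log-normal model (2-vectors / 2x2 positive-definite matrices).
#' @param clayton_theta positive dependence parameter of the Clayton copula
#'   (Kendall's tau = theta / (theta + 2)).
#' @param signal_strength precision of the covariate noise: a signal
#'   covariate's latent score is the standardized target plus Gaussian noise
#'   with standard deviation `1 / sqrt(signal_strength)`.
#' @param group_structure optional list `list(n_groups, group_size,
#'   noise_sd)`; when set, that many disjoint random groups of covariates
#'   share an added per-sample Gaussian noise vector (see
#'   [correlate_groups()]).
#' @param seed integer master seed for the replicate.
#' @return a list of class `"ctiva_sim_config"`.
#' @seealso [make_replicate()]
#' @export
sim_config <- function(model = c("additive_exponential", "log_normal", "clayton_oakes"),
                       n_samples = 500L,
                       n_variables = 1000L,
                       block_sizes = c(interval = 100L, t1 = 100L, t2 = 100L, null = 700L),
                       prop_categorical = 1,
                       event_rate = 1,
                       censor_rate = 0.35,
                       exponent_power = 1,
                       lognormal_params = list(
                         mu_T = c(0, 0.5),
                         sigma_T = matrix(c(1, 0.5, 0.5, 1), 2L),
                         mu_C = c(0.55, 1.05),
                         sigma_C = matrix(c(1, 0.5, 0.5, 1), 2L)
                       ),
                       clayton_theta = 1,
                       signal_strength = 0.065,
                       group_structure = NULL,
                       seed = 1L) {
  model <- match.arg(model)
  n_samples <- as.integer(n_samples)
  n_variables <- as.integer(n_variables)
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) != 4L) {
    stop("`block_sizes` must have four entries (interval, t1, t2, null)", call. = FALSE)
  }
  names(block_sizes) <- c("interval", "t1", "t2", "null")
  if (sum(block_sizes) != n_variables) {
    stop("`block_sizes` must sum to `n_variables`", call. = FALSE)
  }
  if (n_samples < 2L) stop("`n_samples` must be at least 2", call. = FALSE)
  if (event_rate <= 0 || censor_rate <= 0 || exponent_power <= 0) {
    stop("rates and `exponent_power` must be positive", call. = FALSE)
  }
  if (clayton_theta <= 0) stop("`clayton_theta` must be positive", call. = FALSE)
  if (signal_strength <= 0) stop("`signal_strength` must be positive", call. = FALSE)
  if (prop_categorical < 0 || prop_categorical > 1) {
    stop("`prop_categorical` must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("sigma_T", "sigma_C")) {
    s <- lognormal_params[[nm]]
    if (!isSymmetric(unname(s)) || any(eigen(s, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop(sprintf("`lognormal_params$%s` must be symmetric positive-definite", nm), call. = FALSE)
    }
  }
  if (!is.null(group_structure)) {
    gs <- group_structure
    if (!all(c("n_groups", "group_size", "noise_sd") %in% names(gs))) {
      stop("`group_structure` needs n_groups, group_size, noise_sd", call. = FALSE)
    }
    if (gs$n_groups * gs$group_size > n_variables) {
      stop("group structure does not fit into `n_variables`", call. = FALSE)
    }
  }
  structure(list(
    model = model, n_samples = n_samples, n_variables = n_variables,
    block_sizes = block_sizes, prop_categorical = prop_categorical,
    event_rate = event_rate, censor_rate = censor_rate,
    exponent_power = exponent_power, lognormal_params = lognormal_params,
    clayton_theta = clayton_theta, signal_strength = signal_strength,
    group_structure = group_structure, seed = as.integer(seed)
  ), class = "ctiva_sim_config")
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Draw event-time pairs from the additive-exponential model
#'
#' T1 is an exponential draw raised elementwise to `power`, and
#' T2 = T1 + alpha with alpha an independent draw from the same family, so
#' T2 >= T1 always holds.
#'
#' @param n number of pairs.
#' @param rate exponential rate.
#' @param power elementwise power applied to the exponential draws.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return data frame with columns `t1`, `t2`.
#' @export
draw_additive_exponential <- function(n, rate = 1, power = 1, seed = NULL) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (rate <= 0 || power <= 0) stop("`rate` and `power` must be positive", call. = FALSE)
  with_seed(seed, {
    t1 <- stats::rexp(n, rate)^power
    alpha <- stats::rexp(n, rate)^power
    data.frame(t1 = t1, t2 = t1 + alpha)
  })
}

#' Draw event-time pairs from the bivariate log-normal model
#'
#' `(log T1, log T2)` is jointly Gaussian with the stated mean and
#' covariance.
#'
#' @param n number of pairs.
#' @param mu mean 2-vector of the log times.
#' @param sigma 2x2 positive-definite covariance of the log times.
#' @inheritParams draw_additive_exponential
#' @return data frame with columns `t1`, `t2`.
#' @export
draw_log_normal <- function(n, mu = c(0, 0.5), sigma = matrix(c(1, 0.5, 0.5, 1), 2L),
                            seed = NULL) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (!isSymmetric(unname(sigma)) || any(ev <= 0)) {
    stop("`sigma` must be symmetric positive-definite", call. = FALSE)
  }
  with_seed(seed, {
    z <- matrix(stats::rnorm(2L * n), n, 2L) %*% chol(sigma)
    z <- sweep(z, 2L, mu, "+")
    data.frame(t1 = exp(z[, 1L]), t2 = exp(z[, 2L]))
  })
}

#' Draw event-time pairs from the Clayton-Oakes model
#'
#' Joint survival `S(t1, t2) = (S1(t1)^-theta + S2(t2)^-theta - 1)^(-1/theta)`
#' with exponential margins, sampled by the conditional-inverse method on the
#' Clayton copula; Kendall's tau equals `theta / (theta + 2)`.
#'
#' @param n number of pairs.
#' @param theta positive dependence parameter.
#' @param margin_rate exponential rate of both margins.
#' @inheritParams draw_additive_exponential
#' @return data frame with columns `t1`, `t2`.
#' @export
draw_clayton_oakes <- function(n, theta = 1, margin_rate = 1, seed = NULL) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (theta <= 0) stop("`theta` must be positive", call. = FALSE)
  if (margin_rate <= 0) stop("`margin_rate` must be positive", call. = FALSE)
  with_seed(seed, {
    u1 <- stats::runif(n)
    w <- stats::runif(n)
    # conditional inverse of the Clayton copula given U1 = u1
    u2 <- (u1^(-theta) * (w^(-theta / (1 + theta)) - 1) + 1)^(-1 / theta)
    data.frame(
      t1 = stats::qexp(u1, margin_rate, lower.tail = FALSE),
      t2 = stats::qexp(u2, margin_rate, lower.tail = FALSE)
    )
  })
}

#' Draw independent censoring-time pairs
#'
#' Censoring is drawn independently of the event times: independent
#' exponential pairs for the additive-exponential and Clayton-Oakes models
#' (with the additive model's `power` applied so the event-1 censoring
#' fraction is scale-invariant), and a bivariate log-normal pair for the
#' log-normal model.
#'
#' @param n number of pairs.
#' @param censor_rate exponential censoring rate (rate `c`).
#' @param model event model the censoring accompanies.
#' @param lognormal_params list with `mu_C`, `sigma_C` (log-normal model).
#' @param power power transform matching [draw_additive_exponential()].
#' @inheritParams draw_additive_exponential
#' @return data frame with columns `c1`, `c2`.
#' @export
draw_censoring <- function(n, censor_rate = 0.35,
                           model = c("additive_exponential", "clayton_oakes", "log_normal"),
                           lognormal_params = NULL, power = 1, seed = NULL) {
  model <- match.arg(model)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (censor_rate <= 0) stop("`censor_rate` must be positive", call. = FALSE)
  with_seed(seed, {
    if (model == "log_normal") {
      lp <- lognormal_params
      if (is.null(lp)) stop("log-normal censoring needs `lognormal_params`", call. = FALSE)
      d <- draw_log_normal(n, lp$mu_C, lp$sigma_C)
      data.frame(c1 = d$t1, c2 = d$t2)
    } else {
      data.frame(c1 = stats::rexp(n, censor_rate)^power,
                 c2 = stats::rexp(n, censor_rate)^power)
    }
  })
}

#' Censor event pairs
#'
#' Applies the observation scheme V = min(T, C), Delta = I(T <= C) to each
#' event separately; ties T = C count as observed.
#'
#' @param events data frame with `t1`, `t2`.
#' @param censoring data frame with `c1`, `c2` of the same length.
#' @return data frame with columns `v1`, `delta1`, `v2`, `delta2`.
#' @export
apply_censoring <- function(events, censoring) {
  if (nrow(events) != nrow(censoring)) {
    stop("`events` and `censoring` must have the same length", call. = FALSE)
  }
  data.frame(
    v1 = pmin(events$t1, censoring$c1),
    delta1 = as.integer(events$t1 <= censoring$c1),
    v2 = pmin(events$t2, censoring$c2),
    delta2 = as.integer(events$t2 <= censoring$c2)
  )
}

block_labels <- function(block_sizes) {
  rep(c("interval", "t1_only", "t2_only", "null"), times = block_sizes)
}

#' Generate covariates tied to the latent event times
#'
#' Each signal covariate is built from a latent score `z + eps`, where `z`
#' is the standardized target quantity (the interval `t2 - t1`, `t1`, or
#' `t2`, taken from the true uncensored times) and `eps` is Gaussian noise
#' with standard deviation `1 / sqrt(signal_strength)`. Null covariates use
#' an independent standard-normal target. Continuous covariates are the
#' latent score itself; categorical covariates are the binary indicator
#' `I(latent > 0)`.
#'
#' @param events data frame with true times `t1`, `t2`.
#' @param config a [sim_config()] object.
#' @param seed optional seed.
#' @return list with `covariates` (n x p matrix), `variable_types`
#'   (`"categorical"`/`"continuous"`), `truth` (`"interval"`, `"t1_only"`,
#'   `"t2_only"`, `"null"`) and the pre-threshold `latent` matrix.
#' @export
generate_covariates <- function(events, config, seed = NULL) {
  n <- nrow(events)
  if (n != config$n_samples) {
    stop("`events` length inconsistent with `config$n_samples`", call. = FALSE)
  }
  bs <- config$block_sizes
  p <- config$n_variables
  truth <- block_labels(bs)
  # within each block the first ceil(prop * size) variables are categorical
  types <- unlist(lapply(bs, function(sz) {
    k <- round(config$prop_categorical * sz)
    rep(c("categorical", "continuous"), times = c(k, sz - k))
  }), use.names = FALSE)
  noise_sd <- 1 / sqrt(config$signal_strength)
  with_seed(seed, {
    z <- cbind(
      interval = as.numeric(scale(events$t2 - events$t1)),
      t1_only = as.numeric(scale(events$t1)),
      t2_only = as.numeric(scale(events$t2))
    )
    latent <- matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
    sig <- truth != "null"
    latent[, sig] <- latent[, sig] + z[, truth[sig]]
    latent[, !sig] <- latent[, !sig] + stats::rnorm(n * sum(!sig))
    colnames(latent) <- sprintf("x%04d", seq_len(p))
    list(
      covariates = finalize_covariates(latent, types),
      variable_types = types, truth = truth, latent = latent
    )
  })
}

finalize_covariates <- function(latent, types) {
  x <- latent
  cat <- types == "categorical"
  x[, cat] <- (latent[, cat] > 0) + 0
  x
}

#' Correlate random groups of covariates with shared noise
#'
#' Randomly selects disjoint groups of latent covariate scores and adds the
#' same per-sample white Gaussian noise vector to every member of a group;
#' truth labels are unaffected. Categorical covariates must be re-thresholded
#' afterwards, which [make_replicate()] does automatically.
#'
#' @param latent n x p matrix of latent covariate scores.
#' @param group_structure list with `n_groups`, `group_size`, `noise_sd`.
#' @param seed optional seed.
#' @return list with the modified `latent` matrix and `groups`, an integer
#'   vector mapping each variable to its group (`NA` if ungrouped).
#' @export
correlate_groups <- function(latent, group_structure, seed = NULL) {
  gs <- group_structure
  p <- ncol(latent)
  n <- nrow(latent)
  if (gs$n_groups * gs$group_size > p) {
    stop("group structure does not fit the covariate matrix", call. = FALSE)
  }
  with_seed(seed, {
    chosen <- sample.int(p, gs$n_groups * gs$group_size)
    groups <- rep(NA_integer_, p)
    groups[chosen] <- rep(seq_len(gs$n_groups), each = gs$group_size)
    if (gs$noise_sd > 0) {
      for (g in seq_len(gs$n_groups)) {
        shared <- stats::rnorm(n, sd = gs$noise_sd)
        members <- which(groups == g)
        latent[, members] <- latent[, members] + shared
      }
    }
    list(latent = latent, groups = groups)
  })
}

#' Generate one fully seeded simulation replicate
#'
#' Draws event pairs, independent censoring, the censored observations and
#' the covariate blocks from a single master seed, optionally applying the
#' correlated-group structure. The true event times are retained for
#' evaluation only; no fitting stage reads them.
#'
#' @param config a [sim_config()] object.
#' @return object of class `"ctiva_sim"`: a list with `observations`
#'   (`v1, delta1, v2, delta2`), `covariates`, `variable_types`, `truth`,
#'   `groups`, `latent_truth` (true `t1`, `t2`) and `config`.
#' @examples
#' rep <- make_replicate(sim_config(n_samples = 50, n_variables = 20,
#'   block_sizes = c(5, 5, 5, 5), seed = 7))
#' table(rep$observations$delta1, rep$observations$delta2)
#' @export
make_replicate <- function(config) {
  stopifnot(inherits(config, "ctiva_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  events <- switch(config$model,
    additive_exponential = draw_additive_exponential(n, config$event_rate,
                                                     config$exponent_power),
    log_normal = draw_log_normal(n, config$lognormal_params$mu_T,
                                 config$lognormal_params$sigma_T),
    clayton_oakes = draw_clayton_oakes(n, config$clayton_theta, config$event_rate)
  )
  cens <- draw_censoring(n, config$censor_rate, config$model,
                         config$lognormal_params,
                         power = if (config$model == "additive_exponential")
                           config$exponent_power else 1)
  obs <- apply_censoring(events, cens)
  cov <- generate_covariates(events, config)
  groups <- rep(NA_integer_, config$n_variables)
  if (!is.null(config$group_structure)) {
    cg <- correlate_groups(cov$latent, config$group_structure)
    cov$latent <- cg$latent
    groups <- cg$groups
    cov$covariates <- finalize_covariates(cov$latent, cov$variable_types)
  }
  structure(list(
    observations = obs,
    covariates = cov$covariates,
    variable_types = cov$variable_types,
    truth = cov$truth,
    groups = groups,
    latent_truth = events,
    config = config
  ), class = "ctiva_sim")
}

#' @export
print.ctiva_sim <- function(x, ...) {
  cat(sprintf("Simulated censored bivariate dataset (%s model)\n", x$config$model))
  cat(sprintf("  %d samples, %d covariates (%d categorical, %d continuous)\n",
              nrow(x$observations), ncol(x$covariates),
              sum(x$variable_types == "categorical"),
              sum(x$variable_types == "continuous")))
  cat(sprintf("  censored: event 1 %.0f%%, event 2 %.0f%%\n",
              100 * mean(x$observations$delta1 == 0),
              100 * mean(x$observations$delta2 == 0)))
  cat(sprintf("  truth blocks: %s\n",
              paste(names(table(x$truth)), table(x$truth), sep = "=", collapse = ", ")))
  invisible(x)
}
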