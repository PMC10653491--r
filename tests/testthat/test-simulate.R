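test_that("additive-exponential generator matches its closed-form moments", {
  d <- draw_additive_exponential(4, 1, seed = 1)
  expect_true(all(d$t2 > d$t1))

  d <- draw_additive_exponential(10000, 1, seed = 2)
  se <- 1 / sqrt(10000)  # sd of exp(1) is 1
  expect_lt(abs(mean(d$t1) - 1), 3 * se)
  expect_lt(abs(mean(d$t2 - d$t1) - 1), 3 * se)

  # E[X^0.5] = Gamma(1.5) for X ~ exp(1)
  d <- draw_additive_exponential(10000, 1, power = 0.5, seed = 3)
  sd_half <- sqrt(gamma(2) - gamma(1.5)^2)
  expect_lt(abs(mean(d$t1) - gamma(1.5)), 3 * sd_half / sqrt(10000))

  expect_error(draw_additive_exponential(0, 1), "at least 1")
  expect_error(draw_additive_exponential(5, -1), "positive")
})

test_that("log-normal generator has the stated median and correlation", {
  d <- draw_log_normal(10000, mu = c(0, 0), sigma = diag(2), seed = 4)
  # median of a log-normal is exp(mu); median SE ~ 1.2533 sd/sqrt(n) on logs
  expect_lt(abs(median(d$t1) - 1), 3 * 1.2533 / sqrt(10000))
  expect_lt(abs(cor(log(d$t1), log(d$t2))), 3 / sqrt(10000))

  d <- draw_log_normal(10000, mu = c(0, 0.5),
                       sigma = matrix(c(1, 0.5, 0.5, 1), 2), seed = 5)
  # SE of a correlation estimate is about (1 - rho^2)/sqrt(n)
  expect_lt(abs(cor(log(d$t1), log(d$t2)) - 0.5), 3 * 0.75 / sqrt(10000))

  expect_error(draw_log_normal(10, sigma = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("Clayton-Oakes generator has the copula's Kendall tau and margins", {
  d <- draw_clayton_oakes(4000, theta = 1e-6, seed = 6)
  se_tau <- sqrt(2 * (2 * 4000 + 5) / (9 * 4000 * 3999))
  expect_lt(abs(cor(d$t1, d$t2, method = "kendall")), 3 * se_tau)

  d <- draw_clayton_oakes(4000, theta = 2, seed = 7)
  expect_lt(abs(cor(d$t1, d$t2, method = "kendall") - 0.5), 3 * se_tau)

  d <- draw_clayton_oakes(5000, theta = 1, margin_rate = 1.5, seed = 8)
  expect_gt(ks.test(d$t1, pexp, 1.5)$p.value, 0.01)
  expect_gt(ks.test(d$t2, pexp, 1.5)$p.value, 0.01)

  expect_error(draw_clayton_oakes(10, theta = 0), "positive")
})

test_that("event-time margins match their closed forms by KS test", {
  d <- draw_additive_exponential(5000, 1, seed = 9)
  expect_gt(ks.test(d$t1, pexp, 1)$p.value, 0.01)
  d <- draw_log_normal(5000, mu = c(0, 0.5),
                       sigma = matrix(c(1, 0.5, 0.5, 1), 2), seed = 10)
  expect_gt(ks.test(log(d$t1), pnorm, 0, 1)$p.value, 0.01)
})

test_that("censoring draws are independent, seeded and calibrated", {
  cs <- draw_censoring(2, 0.35, seed = 11)
  expect_identical(cs, draw_censoring(2, 0.35, seed = 11))

  cs <- draw_censoring(10000, 0.35, seed = 12)
  expect_lt(abs(cor(cs$c1, cs$c2)), 3 / sqrt(10000))

  # default rate gives roughly 26% censoring on event 1 (= c/(1+c))
  ev <- draw_additive_exponential(10000, 1, seed = 13)
  frac <- mean(cs$c1 < ev$t1)
  expect_lt(abs(frac - 0.35 / 1.35), 3 * 0.5 / sqrt(10000))
})

test_that("censoring fraction is monotone in the censoring rate", {
  fracs <- vapply(c(0.2, 0.35, 0.5, 0.8), function(rate) {
    ev <- draw_additive_exponential(4000, 1, seed = 14)
    cs <- draw_censoring(4000, rate, seed = 15)
    mean(apply_censoring(ev, cs)$delta1 == 0)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("apply_censoring implements V = min(T, C), Delta = I(T <= C)", {
  obs <- apply_censoring(data.frame(t1 = 2, t2 = 5),
                         data.frame(c1 = 3, c2 = 4))
  expect_equal(obs$v1, 2); expect_equal(obs$delta1, 1L)
  expect_equal(obs$v2, 4); expect_equal(obs$delta2, 0L)
  # tie counts as observed
  tie <- apply_censoring(data.frame(t1 = 2, t2 = 3),
                         data.frame(c1 = 2, c2 = 9))
  expect_equal(tie$delta1, 1L)
  expect_error(apply_censoring(data.frame(t1 = 1:2, t2 = 2:3),
                               data.frame(c1 = 1, c2 = 1)), "same length")
})

test_that("covariates carry their labelled signal and nulls are independent", {
  set.seed(16)
  ev <- draw_additive_exponential(500, 1)
  cfg <- sim_config(n_samples = 500, n_variables = 8,
                    block_sizes = c(2, 2, 2, 2), signal_strength = 1e6)
  cov <- generate_covariates(ev, cfg, seed = 17)
  expect_equal(cov$truth, rep(c("interval", "t1_only", "t2_only", "null"), each = 2))
  # zero-noise limit: latent interval covariate is the standardized interval
  expect_gt(cor(cov$latent[, 1], ev$t2 - ev$t1), 0.999)

  # null variables stay below the 99% null quantile of |Spearman rho| in
  # at least 95% of replicates
  hits <- 0L
  crit <- qnorm(0.995) / sqrt(500 - 1)
  for (r in 1:50) {
    ev <- draw_additive_exponential(500, 1)
    x <- rnorm(500)  # null construction: independent of the events
    rho <- cor(rank(x), rank(ev$t2 - ev$t1))
    if (abs(rho) < crit) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("null variables reject at no more than twice the nominal rate", {
  set.seed(18)
  rej <- 0L; tot <- 0L
  for (r in 1:50) {
    cfg <- sim_config(n_samples = 100, n_variables = 20,
                      block_sizes = c(0, 0, 0, 20), seed = 500 + r)
    rep <- make_replicate(cfg)
    y <- rep$latent_truth$t2 - rep$latent_truth$t1
    res <- screen_covariates(rep$covariates, rep$variable_types, y,
                             tests = "anova")
    rej <- rej + sum(res$p_value < 0.05)
    tot <- tot + nrow(res)
  }
  expect_lte(rej / tot, 0.10)
})

test_that("correlated groups share noise without touching other variables", {
  set.seed(19)
  latent <- matrix(rnorm(500 * 40), 500, 40)
  gs <- list(n_groups = 2, group_size = 5, noise_sd = 0)
  out <- correlate_groups(latent, gs, seed = 20)
  expect_equal(out$latent, latent)

  gs$noise_sd <- 3
  out <- correlate_groups(latent, gs, seed = 21)
  g1 <- which(out$groups == 1)
  expect_gt(cor(out$latent[, g1[1]], out$latent[, g1[2]]), 0.5)
  g2 <- which(out$groups == 2)
  expect_lt(abs(cor(out$latent[, g1[1]], out$latent[, g2[1]])), 0.3)
  ungrouped <- which(is.na(out$groups))
  expect_equal(out$latent[, ungrouped], latent[, ungrouped])

  expect_error(correlate_groups(latent, list(n_groups = 10, group_size = 5,
                                             noise_sd = 1)), "fit")
})

test_that("replicates are reproducible and internally consistent", {
  cfg <- sim_config(n_samples = 120, n_variables = 12,
                    block_sizes = c(3, 3, 3, 3), seed = 22)
  r1 <- make_replicate(cfg)
  r2 <- make_replicate(cfg)
  expect_identical(r1, r2)

  # observed values agree with the latent truth and indicators
  obs <- r1$observations; tru <- r1$latent_truth
  obs1 <- obs$delta1 == 1L
  expect_equal(obs$v1[obs1], tru$t1[obs1])
  expect_true(all(obs$v1[!obs1] < tru$t1[!obs1]))
  expect_true(all(tru$t2 >= tru$t1))

  # mixed-type configuration splits every block evenly
  cfgm <- sim_config(n_samples = 60, n_variables = 12,
                     block_sizes = c(4, 4, 2, 2), prop_categorical = 0.5,
                     seed = 23)
  rm <- make_replicate(cfgm)
  tab <- table(rm$truth, rm$variable_types)
  expect_equal(unname(tab["interval", ]), c(2, 2))
  expect_true(all(rm$covariates[, rm$variable_types == "categorical"] %in% 0:1))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_variables = 10, block_sizes = c(1, 1, 1, 1)),
               "sum")
  expect_error(sim_config(event_rate = 0), "positive")
  expect_error(sim_config(group_structure = list(n_groups = 100,
                                                 group_size = 20,
                                                 noise_sd = 1)), "fit")
})
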