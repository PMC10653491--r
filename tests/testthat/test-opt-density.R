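test_that("Kaplan-Meier estimator reproduces hand-computed product limits", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_survival(km, c(1, 2, 3)), c(2/3, 1/3, 0))

  km <- km_fit(c(1, 2), c(0, 0))
  expect_equal(km_survival(km, c(0.5, 1, 2)), c(1, 1, 1))

  km <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_survival(km, 1), 2/3)
  expect_equal(km_survival(km, 3), 0)

  expect_equal(km_survival(km, 0), 1)
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
})

test_that("KM cell masses sum to one and keep residual mass in the last cell", {
  km <- km_fit(c(1, 2, 4), c(1, 1, 0))  # last observation censored
  breaks <- seq(0, 5, length.out = 11)
  m <- ctiva:::km_cell_mass(km, breaks)
  expect_equal(sum(m), 1)
  expect_equal(m[10], 1/3)  # S stays at 1/3 after t = 2; residual in last cell
})

test_that("initialization is the product measure of the KM marginals", {
  # 4 uncensored points at the corners of a square: equal marginal atoms
  obs <- data.frame(v1 = c(1, 1, 3, 3), delta1 = 1,
                    v2 = c(1, 3, 1, 3), delta2 = 1)
  f <- ctiva:::initial_joint(obs, omega = c(4, 4), k = 8)
  expect_equal(density_integral(f), 1, tolerance = 1e-9)
  mass <- f$grid * f$cell_area
  # each quadrant of [0,4]^2 holds 1/4 of the mass
  expect_equal(sum(mass[1:4, 1:4]), 0.25, tolerance = 1e-9)
  expect_equal(sum(mass[5:8, 5:8]), 0.25, tolerance = 1e-9)

  # independence: mass(A x B) = mass(A x Omega) * mass(Omega x B)
  sc <- small_censored_obs(60, seed = 24)
  f <- ctiva:::initial_joint(sc$obs, omega = c(1.05 * max(sc$obs$v1),
                                               1.05 * max(sc$obs$v2)), k = 16)
  mass <- f$grid * f$cell_area
  for (a in list(1:4, 3:9)) {
    for (b in list(2:5, 10:16)) {
      expect_equal(sum(mass[a, b]), sum(mass[a, ]) * sum(mass[, b]),
                   tolerance = 1e-6)
    }
  }
})

test_that("expected counts reduce to indicators and to analytic uniform masses", {
  # no censoring: plain counts
  obs <- data.frame(v1 = c(0.1, 0.6, 0.9), delta1 = 1,
                    v2 = c(0.2, 0.7, 0.4), delta2 = 1)
  f <- uniform_unit_density()
  expect_equal(expected_counts(f, obs, c(0.5, 1, 0, 1)), 2)
  expect_equal(expected_counts(f, obs, c(0, 0.5, 0, 0.5)), 1)

  # one doubly censored observation, region = the whole feasible quadrant
  cens <- data.frame(v1 = 0.3, delta1 = 0, v2 = 0.4, delta2 = 0)
  expect_equal(expected_counts(f, cens, c(0.3, 1, 0.4, 1)), 1, tolerance = 1e-9)

  # uniform density, censored at (0.5, 0.5): P([0.75,1)^2 | quadrant) = 0.25
  cens <- data.frame(v1 = 0.5, delta1 = 0, v2 = 0.5, delta2 = 0)
  expect_equal(expected_counts(f, cens, c(0.75, 1, 0.75, 1)), 0.25,
               tolerance = 1e-9)
})

test_that("expected counts are additive over partitions of the sample space", {
  sc <- small_censored_obs(50, seed = 25)
  fit <- opt_joint(sc$obs$v1, sc$obs$delta1, sc$obs$v2, sc$obs$delta2,
                   max_depth = 5)
  s1 <- fit$omega[1]; s2 <- fit$omega[2]
  quads <- list(c(0, s1/2, 0, s2/2), c(s1/2, s1, 0, s2/2),
                c(0, s1/2, s2/2, s2), c(s1/2, s1, s2/2, s2))
  total <- sum(vapply(quads, function(q) expected_counts(fit, sc$obs, q),
                      numeric(1)))
  expect_equal(total, nrow(sc$obs), tolerance = 1e-6)
})

test_that("log-space recursion matches direct-space arithmetic on tiny instances", {
  omega <- c(2, 2)
  # 2 points, single split level: hand-size instance of the recursion
  g <- point_count_grid(c(0.5, 1.5), c(0.5, 0.6), omega, max_depth = 1)
  tab <- ctiva:::opt_build(g, omega, max_depth = 1)
  expect_equal(tab$logphi[["0.0"]][1, 1],
               log(oracle_phi(g, omega, 1)), tolerance = 1e-12)

  # n <= 5 points at depth 2, several configurations
  set.seed(26)
  for (n in c(2, 3, 5)) {
    g <- point_count_grid(runif(n, 0, 2), runif(n, 0, 2), omega, max_depth = 2)
    tab <- ctiva:::opt_build(g, omega, max_depth = 2)
    direct <- log(oracle_phi(g, omega, 2))
    expect_equal(tab$logphi[["0.0"]][1, 1], direct,
                 tolerance = 1e-9 * max(1, abs(direct)))
  }
})

test_that("nodes with fewer than 2 points are terminal with Phi = Phi0", {
  omega <- c(2, 2)
  g <- point_count_grid(0.5, 0.5, omega, max_depth = 2)  # single point
  tab <- ctiva:::opt_build(g, omega, max_depth = 2)
  expect_equal(tab$logphi[["0.0"]][1, 1], -1 * log(4))  # Phi0 = area^-1
  expect_equal(ctiva:::decide_partition(tab, 0, 0, 0, 0), "uniform")
})

test_that("partition decisions follow the likelihood comparison", {
  omega <- c(1, 1)
  # all mass in the lower axis-1 half, spread along axis 2
  set.seed(27)
  g <- point_count_grid(runif(30, 0, 0.45), runif(30, 0, 1), omega, 3)
  tab <- ctiva:::opt_build(g, omega, 3)
  expect_equal(ctiva:::decide_partition(tab, 0, 0, 0, 0), "split_axis_1")

  # symmetric 4-point layout: uniform stop at the root
  g <- point_count_grid(c(0.25, 0.25, 0.75, 0.75), c(0.25, 0.75, 0.25, 0.75),
                        omega, 3)
  tab <- ctiva:::opt_build(g, omega, 3)
  expect_equal(ctiva:::decide_partition(tab, 0, 0, 0, 0), "uniform")
})

test_that("extracted densities follow N/(n|A|) and integrate to one", {
  sc <- small_censored_obs(60, seed = 28)
  fit <- opt_joint(sc$obs$v1, sc$obs$delta1, sc$obs$v2, sc$obs$delta2,
                   max_depth = 6)
  lv <- fit$leaves
  area <- (lv$hi1 - lv$lo1) * (lv$hi2 - lv$lo2)
  expect_equal(sum(lv$density * area), 1, tolerance = 1e-9)
  # density proportional to leaf count per unit area
  expect_equal(lv$density, (lv$n / sum(lv$n)) / area, tolerance = 1e-9)
  expect_equal(density_integral(fit), 1, tolerance = 1e-6)
})

test_that("without censoring the fit is the plain point-count partition", {
  set.seed(29)
  ev <- draw_additive_exponential(18, 1)
  fit <- opt_joint(ev$t1, rep(1, 18), ev$t2, rep(1, 18), max_depth = 3)
  expect_equal(fit$iterations, 1L)
  expect_true(fit$converged)

  omega <- fit$omega
  g <- point_count_grid(ev$t1, ev$t2, omega, 3)
  orc <- oracle_leaves(g, omega, 3)
  lv <- fit$leaves
  # same partition (same leaf count and counts per leaf) as the direct oracle
  expect_equal(nrow(lv), nrow(orc))
  expect_equal(sort(lv$n), sort(orc$n))
  # leaf masses equal empirical point counts
  inside <- mapply(function(lo1, hi1, lo2, hi2) {
    sum(ev$t1 >= lo1 & ev$t1 < hi1 & ev$t2 >= lo2 & ev$t2 < hi2)
  }, lv$lo1, lv$hi1, lv$lo2, lv$hi2)
  expect_equal(lv$n, inside, tolerance = 1e-9)
})

test_that("density normalization and count conservation hold across random fits", {
  set.seed(30)
  for (r in 1:8) {
    sc <- small_censored_obs(40, seed = 30 + r, censor_rate = runif(1, 0.2, 0.6))
    fit <- opt_joint(sc$obs$v1, sc$obs$delta1, sc$obs$v2, sc$obs$delta2,
                     max_depth = 5)
    expect_equal(density_integral(fit), 1, tolerance = 1e-6)
    ec <- ctiva:::expected_count_grid(fit$grid, fit$b1, fit$b2, sc$obs)
    expect_equal(sum(ec$grid), nrow(sc$obs), tolerance = 1e-6)
  }
})

test_that("the fitted density concentrates above the diagonal for additive pairs", {
  sc <- small_censored_obs(500, seed = 31)
  fit <- opt_joint(sc$obs$v1, sc$obs$delta1, sc$obs$v2, sc$obs$delta2,
                   max_depth = 8)
  mids1 <- (fit$b1[-1] + fit$b1[-length(fit$b1)]) / 2
  mids2 <- (fit$b2[-1] + fit$b2[-length(fit$b2)]) / 2
  above <- sum(fit$grid[outer(mids1, mids2, "<")]) * fit$cell_area
  f0 <- ctiva:::initial_joint(sc$obs, fit$omega, nrow(fit$grid))
  above0 <- sum(f0$grid[outer(mids1, mids2, "<")]) * f0$cell_area
  expect_gt(above, 0.85)   # nearly all mass where T2 > T1
  expect_gt(above, above0) # sharper than the independence initialization
})

test_that("fitted marginal survival tracks the Kaplan-Meier estimate", {
  sc <- small_censored_obs(500, seed = 32, censor_rate = 0.3)
  fit <- opt_joint(sc$obs$v1, sc$obs$delta1, sc$obs$v2, sc$obs$delta2,
                   max_depth = 8)
  km <- km_fit(sc$obs$v1, sc$obs$delta1)
  tt <- seq(0.05, max(sc$obs$v1) * 0.95, length.out = 50)
  mae <- mean(abs(marginal_survival(fit, tt, axis = 1) - km_survival(km, tt)))
  expect_lt(mae, 0.05)
})

test_that("successive density iterates approach a fixed point", {
  # the trace need not be strictly monotone (stop/split decisions are
  # discrete), but every seeded run must converge with an overall decrease
  for (r in 1:10) {
    sc <- small_censored_obs(150, seed = 40 + r)
    fit <- opt_joint(sc$obs$v1, sc$obs$delta1, sc$obs$v2, sc$obs$delta2,
                     max_depth = 6)
    tv <- fit$tv_trace
    expect_true(fit$converged)
    expect_lt(tv[length(tv)], 1e-3)
    if (length(tv) > 2) expect_lt(tv[length(tv)], tv[2])
  }
})

test_that("input validation rejects malformed observations", {
  expect_error(opt_joint(1, 1, 1, 1), "at least 2")
  expect_error(opt_joint(c(1, 2), c(1, 2), c(1, 2), c(1, 1)), "0 or 1")
  expect_error(opt_joint(c(1, -2), c(1, 1), c(1, 2), c(1, 1)), "nonnegative")
  expect_error(opt_joint(c(1, 2), c(1, 1), c(1, 2), c(1, 1), max_depth = 0),
               "max_depth")
  obs <- data.frame(v1 = c(1, 5), delta1 = 1, v2 = c(1, 2), delta2 = 1)
  expect_error(ctiva:::initial_joint(obs, omega = c(2, 3)), "contain")
})
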