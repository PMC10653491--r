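# Independent direct-space evaluation of the stop-vs-split likelihood
# recursion on a counts grid (k = 2^max_depth cells per axis). Uses plain
# products of beta() values, no log-space tricks, so it can cross-check the
# package's log-space recursion on tiny instances.
oracle_block_sum <- function(counts, i, j, k1, k2) {
  k <- nrow(counts)
  rows <- (k1 * k / 2^i + 1):((k1 + 1) * k / 2^i)
  cols <- (k2 * k / 2^j + 1):((k2 + 1) * k / 2^j)
  sum(counts[rows, cols, drop = FALSE])
}

oracle_phi <- function(counts, omega, max_depth, i = 0, j = 0, k1 = 0, k2 = 0) {
  n <- oracle_block_sum(counts, i, j, k1, k2)
  area <- omega[1] * omega[2] / 2^(i + j)
  phi0 <- area^(-n)
  if (n < 2 || (i >= max_depth && j >= max_depth)) return(phi0)
  can1 <- i < max_depth
  can2 <- j < max_depth
  w <- 0.5 / (can1 + can2)
  s <- 0
  if (can1) {
    s <- s + w *
      beta(oracle_block_sum(counts, i + 1, j, 2 * k1, k2) + 0.5,
           oracle_block_sum(counts, i + 1, j, 2 * k1 + 1, k2) + 0.5) / pi *
      oracle_phi(counts, omega, max_depth, i + 1, j, 2 * k1, k2) *
      oracle_phi(counts, omega, max_depth, i + 1, j, 2 * k1 + 1, k2)
  }
  if (can2) {
    s <- s + w *
      beta(oracle_block_sum(counts, i, j + 1, k1, 2 * k2) + 0.5,
           oracle_block_sum(counts, i, j + 1, k1, 2 * k2 + 1) + 0.5) / pi *
      oracle_phi(counts, omega, max_depth, i, j + 1, k1, 2 * k2) *
      oracle_phi(counts, omega, max_depth, i, j + 1, k1, 2 * k2 + 1)
  }
  0.5 * phi0 + s
}

# direct-space partition decision mirroring the published rule, again
# independent of the package's memoized tables
oracle_leaves <- function(counts, omega, max_depth, i = 0, j = 0, k1 = 0, k2 = 0) {
  n <- oracle_block_sum(counts, i, j, k1, k2)
  if (n < 2 || (i >= max_depth && j >= max_depth)) {
    return(data.frame(i = i, j = j, k1 = k1, k2 = k2, n = n))
  }
  can1 <- i < max_depth
  can2 <- j < max_depth
  w <- 0.5 / (can1 + can2)
  phi0 <- (omega[1] * omega[2] / 2^(i + j))^(-n)
  s1 <- if (can1) {
    w * beta(oracle_block_sum(counts, i + 1, j, 2 * k1, k2) + 0.5,
             oracle_block_sum(counts, i + 1, j, 2 * k1 + 1, k2) + 0.5) / pi *
      oracle_phi(counts, omega, max_depth, i + 1, j, 2 * k1, k2) *
      oracle_phi(counts, omega, max_depth, i + 1, j, 2 * k1 + 1, k2)
  } else 0
  s2 <- if (can2) {
    w * beta(oracle_block_sum(counts, i, j + 1, k1, 2 * k2) + 0.5,
             oracle_block_sum(counts, i, j + 1, k1, 2 * k2 + 1) + 0.5) / pi *
      oracle_phi(counts, omega, max_depth, i, j + 1, k1, 2 * k2) *
      oracle_phi(counts, omega, max_depth, i, j + 1, k1, 2 * k2 + 1)
  } else 0
  if (0.5 * phi0 > s1 + s2) {
    return(data.frame(i = i, j = j, k1 = k1, k2 = k2, n = n))
  }
  if (s1 >= s2) {
    rbind(oracle_leaves(counts, omega, max_depth, i + 1, j, 2 * k1, k2),
          oracle_leaves(counts, omega, max_depth, i + 1, j, 2 * k1 + 1, k2))
  } else {
    rbind(oracle_leaves(counts, omega, max_depth, i, j + 1, k1, 2 * k2),
          oracle_leaves(counts, omega, max_depth, i, j + 1, k1, 2 * k2 + 1))
  }
}

# count grid from exact points (no censoring)
point_count_grid <- function(t1, t2, omega, max_depth) {
  k <- 2^max_depth
  b1 <- seq(0, omega[1], length.out = k + 1)
  b2 <- seq(0, omega[2], length.out = k + 1)
  g <- matrix(0, k, k)
  i1 <- pmin(pmax(findInterval(t1, b1), 1), k)
  i2 <- pmin(pmax(findInterval(t2, b2), 1), k)
  for (r in seq_along(t1)) g[i1[r], i2[r]] <- g[i1[r], i2[r]] + 1
  g
}

# uniform density on the unit square as an opt_density object
uniform_unit_density <- function(k = 16) {
  b <- seq(0, 1, length.out = k + 1)
  ctiva:::new_opt_density(matrix(1, k, k), b, b,
                          leaves = data.frame(lo1 = 0, hi1 = 1, lo2 = 0,
                                              hi2 = 1, n = 1, density = 1),
                          n = 1)
}

# small censored dataset for smoke tests
small_censored_obs <- function(n = 80, seed = 11, censor_rate = 0.35) {
  set.seed(seed)
  ev <- draw_additive_exponential(n, 1)
  cs <- draw_censoring(n, censor_rate)
  list(events = ev, obs = apply_censoring(ev, cs))
}

density_integral <- function(fit) sum(fit$grid) * fit$cell_area
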