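#' Kaplan-Meier curve as a step function
#'
#' Product-limit estimator of a univariate survival function under right
#' censoring (computed by [survival::survfit()]), wrapped as a right-continuous
#' step function with S(0) = 1. Any residual mass after the last observed
#' time is treated as a point mass just beyond the largest time when the
#' curve is discretized onto a grid.
#'
#' @param times nonnegative observation times.
#' @param events 0/1 event indicators (1 = observed).
#' @return object of class `"km_curve"` with `time` and `surv` components.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (length(times) != length(events)) stop("length mismatch", call. = FALSE)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param curve a [km_fit()] result.
#' @param t times at which to evaluate the (right-continuous) survival.
#' @return survival probabilities.
#' @export
km_survival <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

# left-limit survival S(t-): proportion with T >= t
km_survival_left <- function(curve, t) {
  idx <- findInterval(t, curve$time, left.open = TRUE)
  c(1, curve$surv)[idx + 1L]
}

# distribution mass per grid cell [b_k, b_{k+1}); residual mass after the
# last time lands in the final cell (breaks are assumed to cover all times)
km_cell_mass <- function(curve, breaks) {
  s <- km_survival_left(curve, breaks)
  m <- -diff(c(s[-length(s)], 0))
  m
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d distinct times, S(max) = %.3f\n",
              length(x$time), min(x$surv)))
  invisible(x)
}

# ---- grid geometry -------------------------------------------------------

# overlap length of each cell [b_k, b_{k+1}) with the window [lo, hi)
overlap_len <- function(breaks, lo, hi = Inf) {
  pmax(0, pmin(breaks[-1L], hi) - pmax(breaks[-length(breaks)], lo))
}

cell_index <- function(v, breaks) {
  k <- length(breaks) - 1L
  pmin(pmax(findInterval(v, breaks), 1L), k)
}

new_opt_density <- function(grid, b1, b2, leaves, n, extra = list()) {
  h1 <- diff(b1)[1L]; h2 <- diff(b2)[1L]
  obj <- c(list(grid = grid, b1 = b1, b2 = b2, leaves = leaves, n = n,
                cell_area = h1 * h2,
                omega = c(max(b1), max(b2))), extra)
  class(obj) <- "opt_density"
  obj
}

#' Independence initialization of the joint density
#'
#' Product of the two Kaplan-Meier marginal distributions, discretized on
#' the fitting grid. Used to seed the expected-count iteration.
#'
#' @param obs data frame with `v1`, `delta1`, `v2`, `delta2`.
#' @param omega upper bounds `c(s1, s2)` of the sample-space rectangle
#'   `[0, s1] x [0, s2]`.
#' @param k number of grid cells per axis.
#' @return an `"opt_density"` object.
#' @keywords internal
initial_joint <- function(obs, omega, k = 256L) {
  if (any(omega <= 0) || max(obs$v1) > omega[1L] || max(obs$v2) > omega[2L]) {
    stop("`omega` must contain all observed values", call. = FALSE)
  }
  b1 <- seq(0, omega[1L], length.out = k + 1L)
  b2 <- seq(0, omega[2L], length.out = k + 1L)
  m1 <- km_cell_mass(km_fit(obs$v1, obs$delta1), b1)
  m2 <- km_cell_mass(km_fit(obs$v2, obs$delta2), b2)
  p <- outer(m1, m2)
  p <- p / sum(p)
  new_opt_density(p / (diff(b1)[1L] * diff(b2)[1L]), b1, b2,
                  leaves = NULL, n = nrow(obs))
}

# ---- expected counts under a working density -----------------------------

# per-observation posterior mass over grid cells, accumulated into a count
# grid; each observation contributes total mass exactly 1
expected_count_grid <- function(fgrid, b1, b2, obs) {
  k1 <- nrow(fgrid); k2 <- ncol(fgrid)
  cnt <- matrix(0, k1, k2)
  nz <- NULL
  n_fallback <- 0L
  fallback <- function(j1, j2) {
    if (is.null(nz)) nz <<- which(fgrid > 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) {
      cnt[j1, j2] <<- cnt[j1, j2] + 1
    } else {
      d <- (nz[, 1L] - j1)^2 + (nz[, 2L] - j2)^2
      # prefer cells in the feasible (upper-right) quadrant
      d <- d + ifelse(nz[, 1L] < j1 | nz[, 2L] < j2, (k1 + k2)^2, 0)
      b <- nz[which.min(d), ]
      cnt[b[1L], b[2L]] <<- cnt[b[1L], b[2L]] + 1
    }
    n_fallback <<- n_fallback + 1L
  }
  j1v <- cell_index(obs$v1, b1)
  j2v <- cell_index(obs$v2, b2)
  for (i in seq_len(nrow(obs))) {
    d1 <- obs$delta1[i]; d2 <- obs$delta2[i]
    j1 <- j1v[i]; j2 <- j2v[i]
    if (d1 == 1L && d2 == 1L) {
      cnt[j1, j2] <- cnt[j1, j2] + 1
    } else if (d1 == 1L && d2 == 0L) {
      w <- fgrid[j1, ] * overlap_len(b2, obs$v2[i])
      s <- sum(w)
      if (s > 0) cnt[j1, ] <- cnt[j1, ] + w / s else fallback(j1, j2)
    } else if (d1 == 0L && d2 == 1L) {
      w <- fgrid[, j2] * overlap_len(b1, obs$v1[i])
      s <- sum(w)
      if (s > 0) cnt[, j2] <- cnt[, j2] + w / s else fallback(j1, j2)
    } else {
      w <- fgrid * (overlap_len(b1, obs$v1[i]) %o% overlap_len(b2, obs$v2[i]))
      s <- sum(w)
      if (s > 0) cnt <- cnt + w / s else fallback(j1, j2)
    }
  }
  list(grid = cnt, n_fallback = n_fallback)
}

#' Expected number of observations in a region
#'
#' Each observation contributes its posterior probability of lying in
#' `region` given its feasible set under the fitted density: fully observed
#' samples contribute an indicator; a sample censored on one event fixes the
#' observed coordinate (at the resolution of the density's grid column) and
#' conditions the other on exceeding its censoring time; a doubly censored
#' sample conditions on the upper-right quadrant beyond `(v1, v2)`.
#'
#' @param fit an `"opt_density"` object.
#' @param obs data frame with `v1`, `delta1`, `v2`, `delta2`.
#' @param region numeric `c(lo1, hi1, lo2, hi2)`, a half-open rectangle.
#' @return expected count (nonnegative real).
#' @export
expected_counts <- function(fit, obs, region) {
  stopifnot(inherits(fit, "opt_density"), length(region) == 4L)
  lo1 <- region[1L]; hi1 <- region[2L]; lo2 <- region[3L]; hi2 <- region[4L]
  f <- fit$grid; b1 <- fit$b1; b2 <- fit$b2
  total <- 0
  j1v <- cell_index(obs$v1, b1)
  j2v <- cell_index(obs$v2, b2)
  for (i in seq_len(nrow(obs))) {
    d1 <- obs$delta1[i]; d2 <- obs$delta2[i]
    v1 <- obs$v1[i]; v2 <- obs$v2[i]
    p <- if (d1 == 1L && d2 == 1L) {
      (v1 >= lo1 && v1 < hi1 && v2 >= lo2 && v2 < hi2) + 0
    } else if (d1 == 1L && d2 == 0L) {
      if (v1 < lo1 || v1 >= hi1) 0 else {
        den <- sum(f[j1v[i], ] * overlap_len(b2, v2))
        if (den > 0) sum(f[j1v[i], ] * overlap_len(b2, max(lo2, v2), hi2)) / den else 0
      }
    } else if (d1 == 0L && d2 == 1L) {
      if (v2 < lo2 || v2 >= hi2) 0 else {
        den <- sum(f[, j2v[i]] * overlap_len(b1, v1))
        if (den > 0) sum(f[, j2v[i]] * overlap_len(b1, max(lo1, v1), hi1)) / den else 0
      }
    } else {
      den <- sum(f * (overlap_len(b1, v1) %o% overlap_len(b2, v2)))
      if (den > 0) {
        sum(f * (overlap_len(b1, max(lo1, v1), hi1) %o%
                 overlap_len(b2, max(lo2, v2), hi2))) / den
      } else 0
    }
    total <- total + p
  }
  total
}

# ---- Optional Polya Tree recursion ---------------------------------------

# elementwise log(exp(a) + exp(b)) that tolerates -Inf
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# block sums of `grid` for the dyadic shape (i splits on axis 1, j on axis 2)
shape_counts <- function(sat, k, i, j) {
  rb <- seq(0L, k, by = k %/% (2L^i)) + 1L
  cb <- seq(0L, k, by = k %/% (2L^j)) + 1L
  m <- sat[rb, cb, drop = FALSE]
  nr <- length(rb); nc <- length(cb)
  m[-1L, -1L, drop = FALSE] - m[-nr, -1L, drop = FALSE] -
    m[-1L, -nc, drop = FALSE] + m[-nr, -nc, drop = FALSE]
}

#' Evaluate the OPT likelihood recursion on a count grid
#'
#' Computes, for every dyadic rectangle of the sample space with at most
#' `max_depth` midpoint splits per axis, the log marginal likelihood `Phi`
#' of the stop-vs-split recursion: a region stops (is uniform) with prior
#' weight 1/2 and splits at the midpoint of an available axis with the
#' remaining 1/2 shared equally between axes (1/4 each while both are
#' available), the split term weighting the two children by a
#' Beta(1/2, 1/2) factor on their counts. Regions with fewer than 2
#' expected points, or with both axes at maximal resolution, are terminal
#' with `Phi = Phi0`, the uniform baseline. All values are kept in log
#' space.
#'
#' @param countgrid k x k matrix of (expected) counts, with
#'   `k = 2^max_depth`.
#' @param omega sample-space upper bounds `c(s1, s2)`.
#' @param max_depth maximum number of splits per axis.
#' @return list of per-shape matrices (`n`, `logphi`, `logstop`,
#'   `logsplit1`, `logsplit2`) keyed by `"i.j"`.
#' @keywords internal
opt_build <- function(countgrid, omega, max_depth) {
  if (max_depth < 1L) stop("`max_depth` must be at least 1", call. = FALSE)
  k <- nrow(countgrid)
  stopifnot(k == ncol(countgrid), k == 2L^max_depth)
  cs <- apply(countgrid, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  sat <- rbind(0, cbind(0, cs))
  area0 <- omega[1L] * omega[2L]
  lb_half <- lbeta(0.5, 0.5)  # log pi
  tab <- list(n = list(), logphi = list(), logstop = list(),
              logsplit1 = list(), logsplit2 = list(),
              max_depth = max_depth, omega = omega, k = k)
  key <- function(i, j) paste(i, j, sep = ".")
  for (d in (2L * max_depth):0) {
    for (i in max(0L, d - max_depth):min(d, max_depth)) {
      j <- d - i
      kk <- key(i, j)
      n_ij <- shape_counts(sat, k, i, j)
      tab$n[[kk]] <- n_ij
      logphi0 <- -n_ij * log(area0 / 2^d)
      can1 <- i < max_depth
      can2 <- j < max_depth
      if (!can1 && !can2) {
        tab$logphi[[kk]] <- logphi0
        next
      }
      lw <- log(0.5 / (can1 + can2))  # split weight per available axis
      t1 <- t2 <- NULL
      if (can1) {
        # children along axis 1: shape (i+1, j), odd/even row blocks
        pc1 <- tab$logphi[[key(i + 1L, j)]]
        nc1 <- tab$n[[key(i + 1L, j)]]
        odd <- seq(1L, 2L^(i + 1L), by = 2L)
        t1 <- lbeta(nc1[odd, , drop = FALSE] + 0.5, nc1[odd + 1L, , drop = FALSE] + 0.5) -
          lb_half + pc1[odd, , drop = FALSE] + pc1[odd + 1L, , drop = FALSE]
      }
      if (can2) {
        # children along axis 2: shape (i, j+1), odd/even column blocks
        pc2 <- tab$logphi[[key(i, j + 1L)]]
        nc2 <- tab$n[[key(i, j + 1L)]]
        odd2 <- seq(1L, 2L^(j + 1L), by = 2L)
        t2 <- lbeta(nc2[, odd2, drop = FALSE] + 0.5, nc2[, odd2 + 1L, drop = FALSE] + 0.5) -
          lb_half + pc2[, odd2, drop = FALSE] + pc2[, odd2 + 1L, drop = FALSE]
      }
      logstop <- log(0.5) + logphi0
      logsplit <- if (can1 && can2) lw + lse2(t1, t2)
                  else lw + (if (can1) t1 else t2)
      logphi <- lse2(logstop, logsplit)
      small <- n_ij < 2
      logphi[small] <- logphi0[small]
      tab$logphi[[kk]] <- logphi
      tab$logstop[[kk]] <- logstop
      if (can1) tab$logsplit1[[kk]] <- lw + t1
      if (can2) tab$logsplit2[[kk]] <- lw + t2
    }
  }
  tab
}

#' Stop-or-split decision for one node
#'
#' A node is declared uniform when half its uniform-baseline likelihood
#' exceeds the summed split term of the recursion (or when it holds fewer
#' than 2 expected points or sits at maximal resolution on both axes);
#' otherwise it splits along the axis with the larger weighted child
#' product, ties broken toward axis 1.
#'
#' @param tab an [opt_build()] table.
#' @param i,j number of splits already taken along each axis.
#' @param k1,k2 zero-based dyadic position of the node within shape (i, j).
#' @return `"uniform"`, `"split_axis_1"` or `"split_axis_2"`.
#' @keywords internal
decide_partition <- function(tab, i, j, k1, k2) {
  kk <- paste(i, j, sep = ".")
  n <- tab$n[[kk]][k1 + 1L, k2 + 1L]
  if (n < 2 || (i >= tab$max_depth && j >= tab$max_depth)) return("uniform")
  stop_l <- tab$logstop[[kk]][k1 + 1L, k2 + 1L]
  s1 <- if (i < tab$max_depth) tab$logsplit1[[kk]][k1 + 1L, k2 + 1L] else -Inf
  s2 <- if (j < tab$max_depth) tab$logsplit2[[kk]][k1 + 1L, k2 + 1L] else -Inf
  if (stop_l > lse2(s1, s2)) return("uniform")
  if (s1 >= s2) "split_axis_1" else "split_axis_2"
}

# walk the decided tree and collect leaf rectangles
opt_leaves <- function(tab) {
  leaves <- list()
  recurse <- function(i, j, k1, k2) {
    dec <- decide_partition(tab, i, j, k1, k2)
    if (dec == "uniform") {
      leaves[[length(leaves) + 1L]] <<- c(i, j, k1, k2,
                                          tab$n[[paste(i, j, sep = ".")]][k1 + 1L, k2 + 1L])
    } else if (dec == "split_axis_1") {
      recurse(i + 1L, j, 2L * k1, k2)
      recurse(i + 1L, j, 2L * k1 + 1L, k2)
    } else {
      recurse(i, j + 1L, k1, 2L * k2)
      recurse(i, j + 1L, k1, 2L * k2 + 1L)
    }
  }
  recurse(0L, 0L, 0L, 0L)
  m <- do.call(rbind, leaves)
  colnames(m) <- c("i", "j", "k1", "k2", "n")
  as.data.frame(m)
}

#' Piecewise-constant density from a decided partition
#'
#' Leaf density is `N(leaf) / (n_total * area(leaf))`, renormalized so the
#' density integrates to exactly 1 over the sample space.
#'
#' @param tab an [opt_build()] table.
#' @param n_total total number of observations.
#' @return an `"opt_density"` object.
#' @keywords internal
extract_density <- function(tab, n_total) {
  if (n_total <= 0) stop("zero total mass", call. = FALSE)
  lv <- opt_leaves(tab)
  s1 <- tab$omega[1L]; s2 <- tab$omega[2L]
  lv$lo1 <- lv$k1 * s1 / 2^lv$i
  lv$hi1 <- (lv$k1 + 1) * s1 / 2^lv$i
  lv$lo2 <- lv$k2 * s2 / 2^lv$j
  lv$hi2 <- (lv$k2 + 1) * s2 / 2^lv$j
  area <- (lv$hi1 - lv$lo1) * (lv$hi2 - lv$lo2)
  mass <- lv$n / n_total
  tot <- sum(mass)
  if (tot <= 0) stop("zero total mass", call. = FALSE)
  mass <- mass / tot
  lv$density <- mass / area
  k <- tab$k
  grid <- matrix(0, k, k)
  for (r in seq_len(nrow(lv))) {
    rows <- (lv$k1[r] * k / 2^lv$i[r] + 1L):((lv$k1[r] + 1L) * k / 2^lv$i[r])
    cols <- (lv$k2[r] * k / 2^lv$j[r] + 1L):((lv$k2[r] + 1L) * k / 2^lv$j[r])
    grid[rows, cols] <- lv$density[r]
  }
  b1 <- seq(0, s1, length.out = k + 1L)
  b2 <- seq(0, s2, length.out = k + 1L)
  new_opt_density(grid, b1, b2,
                  leaves = lv[, c("lo1", "hi1", "lo2", "hi2", "n", "density")],
                  n = n_total)
}

#' Fit the joint density of two censored event times
#'
#' Estimates the joint density of `(T1, T2)` from doubly right-censored
#' observations by an Optional Polya Tree recursion iterated on expected
#' counts: starting from the product of the two Kaplan-Meier marginals, each
#' iteration distributes every (partially) censored observation over its
#' feasible region under the current density, re-evaluates the stop-or-split
#' recursion on the resulting expected counts, and extracts the
#' piecewise-constant density, until the total-variation distance between
#' successive densities falls below `tol`.
#'
#' @param v1,delta1,v2,delta2 observed times and event indicators of the
#'   two events (`delta = 1` means observed).
#' @param max_depth maximum number of binary splits along a branch (the grid
#'   resolution is `2^max_depth` cells per axis).
#' @param tol total-variation convergence tolerance between successive
#'   density iterates.
#' @param max_iter maximum number of expected-count iterations; a warning is
#'   issued and the last iterate returned if not converged.
#' @param omega optional sample-space upper bounds `c(s1, s2)`; defaults to
#'   1.05 times the largest observed value on each axis.
#' @return an object of class `"opt_density"` with the density grid, leaf
#'   rectangles, the iteration trace (`tv_trace`), a `converged` flag and
#'   the number of zero-mass fallbacks encountered (`n_fallback`).
#' @examples
#' set.seed(1)
#' ev <- draw_additive_exponential(150, 1)
#' cs <- draw_censoring(150, 0.35)
#' obs <- apply_censoring(ev, cs)
#' fit <- opt_joint(obs$v1, obs$delta1, obs$v2, obs$delta2, max_depth = 6)
#' fit
#' @export
opt_joint <- function(v1, delta1, v2, delta2, max_depth = 8L, tol = 1e-3,
                      max_iter = 20L, omega = NULL) {
  obs <- data.frame(v1 = v1, delta1 = as.integer(delta1),
                    v2 = v2, delta2 = as.integer(delta2))
  if (nrow(obs) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!all(obs$delta1 %in% 0:1) || !all(obs$delta2 %in% 0:1)) {
    stop("indicators must be 0 or 1", call. = FALSE)
  }
  if (any(obs$v1 < 0) || any(obs$v2 < 0)) stop("times must be nonnegative", call. = FALSE)
  if (max_depth < 1L) stop("`max_depth` must be at least 1", call. = FALSE)
  if (is.null(omega)) omega <- c(1.05 * max(obs$v1), 1.05 * max(obs$v2))
  k <- 2L^max_depth
  n <- nrow(obs)
  uncensored <- all(obs$delta1 == 1L & obs$delta2 == 1L)
  f <- initial_joint(obs, omega, k)
  tv_trace <- numeric(0)
  n_fallback <- 0L
  converged <- FALSE
  iters <- 0L
  cell_area <- f$cell_area
  repeat {
    iters <- iters + 1L
    ec <- expected_count_grid(f$grid, f$b1, f$b2, obs)
    n_fallback <- n_fallback + ec$n_fallback
    tab <- opt_build(ec$grid, omega, max_depth)
    f_new <- extract_density(tab, n)
    tv <- 0.5 * sum(abs(f_new$grid - f$grid)) * cell_area
    tv_trace <- c(tv_trace, tv)
    f <- f_new
    if (uncensored) { converged <- TRUE; break }  # counts are exact
    if (iters > 1L && tv < tol) { converged <- TRUE; break }
    if (iters >= max_iter) break
  }
  if (!converged) {
    warning(sprintf("density iteration did not converge in %d iterations (last TV = %.2e)",
                    max_iter, tv_trace[length(tv_trace)]), call. = FALSE)
  }
  f$iterations <- iters
  f$tv_trace <- tv_trace
  f$converged <- converged
  f$n_fallback <- n_fallback
  f$max_depth <- max_depth
  f
}

#' @export
print.opt_density <- function(x, ...) {
  cat("Bivariate piecewise-constant joint density (Optional Polya Tree)\n")
  cat(sprintf("  sample space [0, %.3g] x [0, %.3g], %d x %d grid\n",
              x$omega[1L], x$omega[2L], nrow(x$grid), ncol(x$grid)))
  if (!is.null(x$leaves)) cat(sprintf("  %d leaf rectangles\n", nrow(x$leaves)))
  if (!is.null(x$iterations)) {
    cat(sprintf("  %d iteration(s), %s (final TV %.2e)\n", x$iterations,
                if (isTRUE(x$converged)) "converged" else "NOT converged",
                x$tv_trace[length(x$tv_trace)]))
  }
  invisible(x)
}

#' @export
plot.opt_density <- function(x, ...) {
  mids1 <- (x$b1[-1L] + x$b1[-length(x$b1)]) / 2
  mids2 <- (x$b2[-1L] + x$b2[-length(x$b2)]) / 2
  graphics::image(mids1, mids2, x$grid, xlab = "T1", ylab = "T2",
                  main = "Estimated joint density", ...)
  invisible(x)
}

#' Density values at points
#'
#' @param object an `"opt_density"` object.
#' @param newdata data frame (or matrix) with columns `t1`, `t2`.
#' @param ... unused.
#' @return density values (0 outside the sample space).
#' @export
predict.opt_density <- function(object, newdata, ...) {
  t1 <- newdata[, 1L]; t2 <- newdata[, 2L]
  out <- numeric(length(t1))
  inside <- t1 >= 0 & t1 < object$omega[1L] & t2 >= 0 & t2 < object$omega[2L]
  out[inside] <- object$grid[cbind(cell_index(t1[inside], object$b1),
                                   cell_index(t2[inside], object$b2))]
  out
}

#' Marginal survival function implied by a fitted joint density
#'
#' @param fit an `"opt_density"` object.
#' @param t evaluation times.
#' @param axis 1 for `T1`, 2 for `T2`.
#' @return `P(T > t)` under the fitted density.
#' @export
marginal_survival <- function(fit, t, axis = 1L) {
  b <- if (axis == 1L) fit$b1 else fit$b2
  m <- if (axis == 1L) rowSums(fit$grid) else colSums(fit$grid)
  m <- m * fit$cell_area  # mass per cell along this axis
  w <- diff(b)
  vapply(t, function(tt) sum(m * overlap_len(b, tt) / w), numeric(1))
}
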