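# Independent oracles used by the recovery tests. Each reimplements the
# quantity it checks by a different route (closed form, exhaustive grid
# search, permutation) and must stay independent of the package fit code.

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2,
       adjusted_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# Coarse grid search for the sigmoid (t_half, slope_width), profiling out
# the two linear parameters (offset + amplitude) at every grid node.
boltzmann_grid_oracle <- function(temp, r, t_half_grid, width_grid) {
  best <- list(sse = Inf)
  for (th in t_half_grid) {
    for (w in width_grid) {
      basis <- 1 / (1 + exp((temp - th) / w))
      fit <- stats::lm.fit(cbind(1, basis), r)
      sse <- sum(fit$residuals^2)
      if (sse < best$sse) best <- list(sse = sse, t_half = th, slope_width = w)
    }
  }
  best
}

# Grid search over the decay rate k, profiling out the linear parameters of
# F(t) = a exp(-k t) + c.
decay_grid_oracle <- function(t, f, k_grid) {
  sse <- vapply(k_grid, function(k) {
    fit <- stats::lm.fit(cbind(exp(-k * t), 1), f)
    sum(fit$residuals^2)
  }, numeric(1))
  k_grid[which.min(sse)]
}

# Permutation reference for Tukey-style all-pairs comparisons: the max
# studentized-range statistic over label permutations gives familywise
# p-values for each pair.
tukey_permutation_oracle <- function(values, groups, n_perm = 1e5, seed = 99) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  counts <- as.vector(table(groups))
  G <- outer(as.integer(groups), seq_len(k), "==") * 1  # n x k indicator
  pairs <- utils::combn(k, 2)
  q_stat <- function(vals) {
    s1 <- crossprod(G, vals)           # group sums
    s2 <- crossprod(G, vals^2)
    means <- s1 / counts
    mse <- sum(s2 - s1^2 / counts) / (n - k)
    apply(pairs, 2, function(pr) {
      i <- pr[1]; j <- pr[2]
      abs(means[i] - means[j]) /
        sqrt(mse / 2 * (1 / counts[i] + 1 / counts[j]))
    })
  }
  q_obs <- q_stat(values)
  withr::with_seed(seed, {
    exceed <- numeric(ncol(pairs))
    for (b in seq_len(n_perm)) {
      q_max <- max(q_stat(values[sample.int(n)]))
      exceed <- exceed + (q_max >= q_obs)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  data.frame(group1 = levels(groups)[pairs[1, ]],
             group2 = levels(groups)[pairs[2, ]], p_perm = p)
}

# Replicate melting curves from a simulation, one anisotropy_curve each.
replicate_curves <- function(sim) {
  lapply(split(sim$readings, sim$readings$replicate),
         anisotropy_curve_from_readings)
}
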