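# Independent oracles used across the suite.
#
# bf10_oracle: brute-force 2-D quadrature over (delta, log sigma^2) of the
# full two-group Gaussian likelihood with the group means at mu +/- sigma *
# delta / 2, Jeffreys prior 1/sigma^2 on the variance (flat on log sigma^2)
# and a Cauchy(0, r) prior on delta. The location mu is integrated out in
# closed form; everything else is numeric. It never touches the
# noncentral-t sufficiency reduction the package uses, so agreement is a
# genuine dual-route check.

oracle_log_int_mu <- function(x, y, delta, sigma) {
  N <- length(x) + length(y)
  z <- c(x - sigma * delta / 2, y + sigma * delta / 2)
  S <- sum((z - mean(z))^2)
  -N / 2 * log(2 * pi * sigma^2) + 0.5 * log(2 * pi * sigma^2 / N) -
    S / (2 * sigma^2)
}

# marginal likelihood of the data given delta (mu and sigma^2 integrated out)
oracle_inner <- function(x, y, delta) {
  f <- function(u) vapply(u, function(ui)
    exp(oracle_log_int_mu(x, y, delta, exp(ui / 2))), numeric(1))
  stats::integrate(f, -30, 30, rel.tol = 1e-10, abs.tol = 0)$value
}

bf10_oracle <- function(x, y, r) {
  m1 <- stats::integrate(
    Vectorize(function(d) oracle_inner(x, y, d) * stats::dcauchy(d, 0, r)),
    -Inf, Inf, rel.tol = 1e-8)$value
  m0 <- oracle_inner(x, y, 0)
  list(bf10 = m1 / m0, m1 = m1)
}

# normalized marginal posterior density of delta at the requested points
delta_density_oracle <- function(x, y, r, at) {
  m1 <- bf10_oracle(x, y, r)$m1
  vapply(at, function(d)
    oracle_inner(x, y, d) * stats::dcauchy(d, 0, r) / m1, numeric(1))
}

# A grid "posterior" holding an arbitrary constructed density, for feeding
# the index operations densities with known closed forms.
grid_posterior <- function(grid, density, prior = prior_spec("wide")) {
  structure(list(grid = grid, density = density, prior = prior,
                 t_summary = NULL),
            class = "delta_posterior")
}

gaussian_grid_posterior <- function(mean, sd, half_width = 10,
                                    n = 4001L, prior = prior_spec("wide")) {
  g <- seq(mean - half_width * sd, mean + half_width * sd, length.out = n)
  grid_posterior(g, stats::dnorm(g, mean, sd), prior)
}

# Proportion of significant calls for one index over a fixed-seed cell,
# without going through run_cell (used where only one index is needed).
welch_rejection_rate <- function(setting, n, reps, base_seed, alpha = 0.05) {
  hits <- 0
  for (k in seq_len(reps)) {
    seed <- derive_seed(base_seed, setting$name, n, 0, "wide", k)
    pair <- generate_pair(setting, n, 0, seed)
    hits <- hits + (welch_p_value(pair$x, pair$y) < alpha)
  }
  hits / reps
}
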