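# Shared fixtures: the two experimental conditions, generator curves and a
# fine-grid quadrature oracle independent of the package's default grid.

cond1 <- part1_condition()
cond2 <- part2_condition()

# canonical generator curves are deterministic; compute once per test run
gen_curves <- canonical_response_curves(cond1, cond2, beta = 1)

# independent trapezoidal oracle on a 10x finer grid, written directly
# against closed-form densities (no package quadrature helpers)
oracle_evidence <- function(cond, model, d, step = 5e-4) {
  n <- round(12 / step)
  s <- seq(-n, n) * step
  prior <- if (model == "M1") cond$prior_m1 else cond$prior_m2
  dens <- rep(0, length(s))
  for (k in seq_along(prior$weights))
    dens <- dens + prior$weights[k] * dnorm(s, prior$means[k],
                                            sqrt(prior$vars[k]))
  denom <- cond$d_max / 2 - abs(s)
  lik <- ifelse(d >= 2 * abs(s) & d <= cond$d_max & denom > 0, 1 / denom, 0)
  keep <- abs(s) <= d / 2 + 1e-12   # integrate over the likelihood support
  y <- (lik * dens)[keep]
  sum((y[-1] + y[-length(y)]) / 2) * step
}

# Monte-Carlo evidence estimate: E_{s~prior}[P(d|s)]; returns mean and SE
mc_evidence <- function(cond, model, d, n = 1e6, seed = 1) {
  prior <- if (model == "M1") cond$prior_m1 else cond$prior_m2
  s <- prior_sample(prior, n, seed = seed)
  v <- obs_likelihood(s, d, cond$d_max)
  list(mean = mean(v), se = sd(v) / sqrt(n))
}

# build a binned_responses object from exact frequencies (100 trials/bin)
make_binned <- function(edges, freq, n = 100) {
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 n_m1 = round(freq * n), n_total = rep(n, length(freq)),
                 freq = freq),
            class = "binned_responses")
}
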