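# Shared fixtures and independent oracles, built in code at test time.

# Naive per-point Bayes computation: plain density products, no log-space
# tricks. Independent of evaluate_posterior()'s vectorized log-space path.
brute_force_posterior <- function(obs, grid) {
  post <- array(0, dim = dim(grid$prior))
  for (ni in seq_along(grid$n_values)) {
    n <- grid$n_values[ni]
    for (qi in seq_along(grid$q)) {
      q <- grid$q[qi]
      p <- obs$means / (n * q)
      for (gi in seq_along(grid$gamma)) {
        g <- grid$gamma[gi]
        lam <- q / g
        if (any(p > 1)) next
        lik <- 1
        for (i in seq_len(obs$n_conditions)) {
          for (x in obs$amplitudes[[i]]) {
            dens <- dbinom(0, n, p[i]) * dnorm(x, 0, obs$noise_sd)
            for (j in seq_len(n)) {
              dens <- dens + dbinom(j, n, p[i]) *
                (if (x > 0) dgamma(x, shape = j * g, scale = lam) else 0)
            }
            lik <- lik * dens
          }
        }
        post[ni, qi, gi] <- grid$prior[ni, qi, gi] * lik
      }
    }
  }
  post / sum(post)
}

# total mass of the composite density by adaptive quadrature, with
# breakpoints anchored at the mixture-component means so narrow components
# cannot be stepped over
composite_mass <- function(pars, p, eps) {
  f <- function(x) composite_amplitude_density(x, pars, p, eps)
  brk <- c(-Inf, 0, (1:pars$n) * pars$q, Inf)
  sum(vapply(seq_len(length(brk) - 1L), function(i)
    integrate(f, brk[i], brk[i + 1L], rel.tol = 1e-10,
              abs.tol = 1e-12)$value, numeric(1)))
}

# small simulated observation set used across inference tests
small_sim_obs <- function(seed = 7, n = 3, q = 0.2, cv = 0.3,
                          ps = c(0.3, 0.7), sweeps = 25, eps = 0.05) {
  simulate_observations(simulation_design(
    quantal_params(n = n, q = q, cv = cv), ps, sweeps, eps, seed = seed))
}

# instantaneous-rise, exponential-decay response starting at t0
exp_decay_trace <- function(amp = 8, tau_s = 0.003, t0 = 0.01,
                            dur = 0.05, dt = 1 / 50000, offset = 0) {
  t <- seq(0, dur, by = dt)
  sweep_trace(ifelse(t >= t0, amp * exp(-(t - t0) / tau_s), 0) + offset, dt)
}

# balanced one-way table with MS_between = 30, MS_within = 6, k = 4
icc_toy_table <- function() {
  means <- c(10 - sqrt(7.5), 10, 10 + sqrt(7.5))
  within <- c(0, 0, 3, -3)       # per-unit variance exactly 6
  group_sample(values = rep(means, each = 4) + rep(within, times = 3),
               group = "WT", unit_id = rep(c("u1", "u2", "u3"), each = 4))
}

# planted mini fixture: 3 conforming events, 1 sub-threshold, 1 with an
# effectively instantaneous rise; near-zero injected noise but a declared
# baseline noise SD of 1 so detection is deterministic
mini_fixture <- function(noise_seed = 1) {
  dt <- 1 / 50000
  t <- seq(0, 0.5, by = dt)
  kern <- function(tt, rise = 0.3, decay = 3)
    synquant:::event_kernel(tt, rise, decay)
  y <- numeric(length(t))
  for (tp in c(0.05, 0.15, 0.25)) y <- y + 5 * kern(t - tp)
  y <- y + 0.8 * kern(t - 0.35)                      # below 1.5 x noise SD
  y <- y + 5 * kern(t - 0.45, rise = 0.011)          # rise ~ one sample
  set.seed(noise_seed)
  y <- y + rnorm(length(y), 0, 0.05)
  list(trace = sweep_trace(y, dt), noise_sd = 1,
       conforming_times = c(0.05, 0.15, 0.25), amplitude = 5)
}
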