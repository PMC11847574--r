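test_that("quantal_params derives latent scale and CV consistently", {
  p <- quantal_params(n = 5, q = 0.1, cv = 0.3)
  expect_equal(p$gamma_shape, 1 / 0.09)
  expect_equal(p$lambda_scale * p$gamma_shape, p$q)
  expect_equal(p$cv, 1 / sqrt(p$gamma_shape))
  p2 <- quantal_params(n = 2, q = 1, gamma_shape = 4)
  expect_equal(p2$cv, 0.5)
  expect_error(quantal_params(0, 1, cv = 0.3), "positive integer")
  expect_error(quantal_params(2, 1), "exactly one")
  expect_error(quantal_params(2, 1, gamma_shape = 2, cv = 0.5), "exactly one")
})

test_that("binomial_pmf matches the factorial formula and normalizes", {
  expect_identical(binomial_pmf(0, 5, 0), 1)
  expect_equal(binomial_pmf(1, 2, 0.5), 0.5)
  expect_equal(binomial_pmf(2, 4, 0.3), 6 * 0.3^2 * 0.7^2)  # 0.2646
  for (case in list(c(3, 0.2), c(7, 0.55), c(12, 0.96))) {
    n <- case[1]
    expect_equal(sum(binomial_pmf(0:n, n, case[2])), 1)
  }
  expect_error(binomial_pmf(5, 4, 0.5), "exceed")
  expect_error(binomial_pmf(1, 2, 1.2), "0, 1")
})

test_that("gamma_pdf evaluates the uniquantal density with mean gamma*lambda", {
  # shape 1 is the exponential: density 1/lambda at the origin limit
  expect_equal(gamma_pdf(1e-12, 1, 2), 0.5, tolerance = 1e-9)
  expect_equal(gamma_pdf(2, 2, 1), 2 * exp(-2))
  # quadrature mean equals gamma * lambda
  m <- integrate(function(x) x * gamma_pdf(x, 4, 0.05), 0, Inf)$value
  expect_equal(m, 0.2, tolerance = 1e-8)
  expect_equal(integrate(function(x) gamma_pdf(x, 3.5, 0.2), 0, Inf)$value,
               1, tolerance = 1e-8)
  expect_identical(gamma_pdf(c(-1, 0), 2, 1), c(0, 0))
  expect_error(gamma_pdf(1, -1, 1), "positive")
})

test_that("noise_pdf is the zero-mean Gaussian and is symmetric", {
  expect_equal(noise_pdf(0, 1), 1 / sqrt(2 * pi))
  eps <- 0.37
  expect_equal(noise_pdf(eps, eps), exp(-0.5) / (eps * sqrt(2 * pi)))
  set.seed(42)
  x <- rnorm(100, sd = 3)
  expect_equal(noise_pdf(x, 0.8), noise_pdf(-x, 0.8))
  expect_error(noise_pdf(0, 0), "positive")
})

test_that("composite density reduces to pure noise at p = 0", {
  pars <- quantal_params(n = 4, q = 0.1, cv = 0.3)
  x <- seq(-0.1, 0.5, length.out = 101)
  expect_equal(composite_amplitude_density(x, pars, p = 0, noise_sd = 0.02),
               noise_pdf(x, 0.02), tolerance = 1e-14)
})

test_that("composite density integrates to 1 and is a two-term mixture at n = 1", {
  set.seed(11)
  for (rep in 1:5) {
    pars <- quantal_params(n = sample(1:8, 1), q = runif(1, 0.05, 2),
                           cv = runif(1, 0.1, 0.9))
    p <- runif(1, 0.05, 0.95)
    eps <- runif(1, 0.005, 0.1)
    expect_equal(composite_mass(pars, p, eps), 1, tolerance = 1e-6)
  }
  # n = 1, q >> eps: density is 0.5 N + 0.5 G pointwise
  pars1 <- quantal_params(n = 1, q = 1, cv = 0.3)
  x <- seq(-0.05, 3, length.out = 200)
  expect_equal(
    composite_amplitude_density(x, pars1, 0.5, 0.01),
    0.5 * noise_pdf(x, 0.01) +
      0.5 * gamma_pdf(x, pars1$gamma_shape, pars1$lambda_scale),
    tolerance = 1e-12)
})

test_that("composite moments obey mu = npq and the total-variance identity", {
  pars <- quantal_params(n = 5, q = 0.2, cv = 0.4)
  eps <- 0.03
  means <- c()
  for (p in c(0.2, 0.5, 0.8)) {
    mu <- integrate(function(x)
      x * composite_amplitude_density(x, pars, p, eps),
      -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(mu, pars$n * p * pars$q, tolerance = 1e-6)
    # model variance: noise contributes only through the failure component
    v <- integrate(function(x)
      (x - mu)^2 * composite_amplitude_density(x, pars, p, eps),
      -Inf, Inf, rel.tol = 1e-10)$value
    v_expect <- pars$n * p * pars$gamma_shape * pars$lambda_scale^2 +
      pars$n * p * (1 - p) * pars$q^2 + (1 - p)^pars$n * eps^2
    expect_equal(v, v_expect, tolerance = 1e-6)
    means <- c(means, mu)
  }
  expect_true(all(diff(means) > 0))   # mean strictly increases with p
})

test_that("log-likelihood matches a direct product-of-densities oracle", {
  obs <- small_sim_obs(seed = 3, sweeps = 5)
  pars <- quantal_params(n = 3, q = 0.2, cv = 0.3)
  # independent computation: per-condition weight times density product
  p_i <- obs$means / (pars$n * pars$q)
  direct <- sum(-log(obs$ses * sqrt(2 * pi)))
  for (i in 1:obs$n_conditions) {
    for (x in obs$amplitudes[[i]]) {
      d <- dbinom(0, 3, p_i[i]) * dnorm(x, 0, obs$noise_sd)
      for (j in 1:3) d <- d + dbinom(j, 3, p_i[i]) *
          (if (x > 0) dgamma(x, shape = j * pars$gamma_shape,
                             scale = pars$lambda_scale) else 0)
      direct <- direct + log(d)
    }
  }
  expect_equal(quantal_log_likelihood(obs, pars), direct,
               tolerance = 1e-12)
})

test_that("log-likelihood is order-invariant and -Inf at infeasible p", {
  obs <- small_sim_obs(seed = 9, sweeps = 12)
  pars <- quantal_params(n = 3, q = 0.2, cv = 0.3)
  ll <- quantal_log_likelihood(obs, pars)
  shuffled <- observation_set(lapply(obs$amplitudes, rev),
                              noise_sd = obs$noise_sd)
  expect_equal(quantal_log_likelihood(shuffled, pars), ll)
  # q so small that implied p exceeds 1
  tiny_q <- quantal_params(n = 3, q = min(obs$means) / 10, cv = 0.3)
  expect_identical(quantal_log_likelihood(obs, tiny_q), -Inf)
})

test_that("observation_set validates input and applies the sign convention", {
  expect_error(observation_set(list(c(1)), 0.1), "at least 2")
  expect_error(observation_set(list(c(1, 2)), 0), "positive")
  flipped <- observation_set(list(c(-1, -2, -3)), 0.1, sign = -1)
  expect_equal(flipped$means, 2)
  expect_equal(flipped$ses, sd(1:3) / sqrt(3))
})
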