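#' Quantal parameter set
#'
#' Bundles one point in quantal parameter space: the number of independent
#' release sites `n`, the quantal size `q` (mean of the uniquantal amplitude
#' distribution), and the gamma shape parameter `gamma_shape`. The gamma
#' scale `lambda_scale = q / gamma_shape` and the uniquantal coefficient of
#' variation `cv = 1 / sqrt(gamma_shape)` are latent quantities derived from
#' these and stored alongside.
#'
#' Exactly one of `gamma_shape` or `cv` must be supplied; they are related by
#' `gamma_shape = 1 / cv^2`.
#'
#' @param n Number of release sites (positive integer).
#' @param q Quantal size, in response units (positive).
#' @param gamma_shape Shape parameter of the gamma uniquantal distribution
#'   (positive). Mutually exclusive with `cv`.
#' @param cv Coefficient of variation of the uniquantal distribution
#'   (positive). Mutually exclusive with `gamma_shape`.
#' @return An object of class `quantal_params`: a list with fields `n`, `q`,
#'   `gamma_shape`, `lambda_scale`, `cv`.
#' @examples
#' quantal_params(n = 5, q = 0.1, cv = 0.3)
#' @export
quantal_params <- function(n, q, gamma_shape = NULL, cv = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a single positive integer")
  if (length(q) != 1L || !is.finite(q) || q <= 0)
    stop("'q' must be a single positive number")
  if (is.null(gamma_shape) == is.null(cv))
    stop("supply exactly one of 'gamma_shape' or 'cv'")
  if (is.null(gamma_shape)) {
    if (!is.finite(cv) || cv <= 0) stop("'cv' must be positive")
    gamma_shape <- 1 / cv^2
  } else {
    if (!is.finite(gamma_shape) || gamma_shape <= 0)
      stop("'gamma_shape' must be positive")
    cv <- 1 / sqrt(gamma_shape)
  }
  structure(
    list(n = as.integer(n), q = q, gamma_shape = gamma_shape,
         lambda_scale = q / gamma_shape, cv = cv),
    class = "quantal_params"
  )
}

#' @export
print.quantal_params <- function(x, ...) {
  cat("Quantal parameters\n")
  cat(sprintf("  release sites n : %d\n", x$n))
  cat(sprintf("  quantal size q  : %g\n", x$q))
  cat(sprintf("  gamma shape     : %g  (CV %.3g, scale lambda %.4g)\n",
              x$gamma_shape, x$cv, x$lambda_scale))
  invisible(x)
}

#' Observed amplitude set for quantal analysis
#'
#' Collects the evoked response amplitudes for one synaptic connection,
#' grouped by release-probability condition (e.g. extracellular Ca2+ level),
#' together with the baseline noise standard deviation measured directly from
#' the raw recordings. Per-condition arithmetic means and standard errors are
#' computed on construction; these drive both the implicit quantal-size grid
#' limits and the per-condition weight terms of the likelihood.
#'
#' Amplitudes are analyzed as positive magnitudes (the gamma uniquantal
#' density has support on the positive axis); set `sign = -1` to flip
#' inward currents or hyperpolarizing potentials on input. Individual sweeps
#' may still be negative after flipping - baseline noise has full support.
#'
#' @param amplitudes A list of numeric vectors, one per condition, or a
#'   single numeric vector (one condition). Each condition needs >= 2 sweeps.
#' @param noise_sd Baseline noise standard deviation, response units (> 0).
#' @param condition_labels Optional labels, one per condition.
#' @param sign Either `1` (store as-is) or `-1` (flip sign on input).
#' @param condition_means,condition_ses Optional explicit per-condition means
#'   and standard errors. Normally computed from `amplitudes`; supplying them
#'   (with empty amplitude vectors) constructs a summary-only observation set
#'   carrying weight terms but no sweep data, which is useful for
#'   prior-predictive checks.
#' @return An object of class `observation_set` with fields `amplitudes`
#'   (list), `noise_sd`, `n_conditions`, `condition_labels`, `means`, `ses`,
#'   `counts`.
#' @examples
#' obs <- observation_set(list(c(0.1, 0.3, 0.2), c(0.5, 0.4, 0.6)),
#'                        noise_sd = 0.05)
#' obs$means
#' @export
observation_set <- function(amplitudes, noise_sd,
                            condition_labels = NULL, sign = 1,
                            condition_means = NULL, condition_ses = NULL) {
  if (is.numeric(amplitudes)) amplitudes <- list(amplitudes)
  if (!is.list(amplitudes) || length(amplitudes) == 0L)
    stop("'amplitudes' must be a non-empty list of numeric vectors")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
      !is.finite(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be a single positive number")
  if (!sign %in% c(1, -1)) stop("'sign' must be 1 or -1")
  amplitudes <- lapply(amplitudes, function(x) as.numeric(x) * sign)
  c_n <- length(amplitudes)
  if (is.null(condition_labels)) condition_labels <- as.character(seq_len(c_n))
  if (length(condition_labels) != c_n)
    stop("'condition_labels' length must match the number of conditions")

  counts <- unname(vapply(amplitudes, length, integer(1)))
  summary_only <- all(counts == 0L)
  if (summary_only) {
    if (is.null(condition_means) || is.null(condition_ses))
      stop("summary-only observation sets need 'condition_means' and 'condition_ses'")
    means <- as.numeric(condition_means)
    ses <- as.numeric(condition_ses)
    if (length(means) != c_n || length(ses) != c_n)
      stop("'condition_means'/'condition_ses' length must match conditions")
  } else {
    if (any(counts < 2L))
      stop("every condition needs at least 2 amplitudes (standard error undefined)")
    if (!is.null(condition_means) || !is.null(condition_ses))
      stop("explicit means/ses are only allowed with empty amplitude vectors")
    means <- unname(vapply(amplitudes, mean, numeric(1)))
    ses <- unname(vapply(amplitudes, function(x) stats::sd(x) / sqrt(length(x)),
                         numeric(1)))
  }
  if (any(!is.finite(means)) || any(!is.finite(ses)) || any(ses < 0))
    stop("condition means/standard errors must be finite (ses non-negative)")

  structure(
    list(amplitudes = amplitudes, noise_sd = noise_sd, n_conditions = c_n,
         condition_labels = condition_labels, means = means, ses = ses,
         counts = counts),
    class = "observation_set"
  )
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d condition(s), noise SD %.4g\n",
              x$n_conditions, x$noise_sd))
  df <- data.frame(condition = x$condition_labels, sweeps = x$counts,
                   mean = signif(x$means, 4), se = signif(x$ses, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Binomial release probability mass
#'
#' Probability of observing `j` successful vesicle releases from `n`
#' independent sites, each releasing with probability `p` on a given
#' stimulus.
#'
#' @param j Number of successful releases, `0 <= j <= n`.
#' @param n Number of release sites (positive integer).
#' @param p Per-site release probability in `[0, 1]`.
#' @return The binomial probability `choose(n, j) p^j (1-p)^(n-j)`.
#' @export
binomial_pmf <- function(j, n, p) {
  if (any(!is.finite(j)) || any(j < 0) || any(j != round(j)))
    stop("'j' must be a non-negative integer")
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
    stop("'n' must be a positive integer")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1]")
  if (any(j > n)) stop("'j' cannot exceed 'n'")
  stats::dbinom(j, n, p)
}

#' Gamma uniquantal amplitude density
#'
#' Density of the single-site (uniquantal) response amplitude, modeled as a
#' gamma distribution with shape `gamma_shape` and scale `lambda_scale`; its
#' mean is the quantal size `q = gamma_shape * lambda_scale`. The density is
#' defined as 0 for `x <= 0` (the noise component of the composite model
#' carries all mass there).
#'
#' @param x Amplitude(s), response units.
#' @param gamma_shape Shape parameter (> 0).
#' @param lambda_scale Scale parameter, response units (> 0).
#' @return Density value(s).
#' @export
gamma_pdf <- function(x, gamma_shape, lambda_scale) {
  if (!is.finite(gamma_shape) || gamma_shape <= 0)
    stop("'gamma_shape' must be positive")
  if (!is.finite(lambda_scale) || lambda_scale <= 0)
    stop("'lambda_scale' must be positive")
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- stats::dgamma(x[pos], shape = gamma_shape, scale = lambda_scale)
  out
}

#' Baseline noise density
#'
#' Zero-mean Gaussian density modeling the baseline noise of the recording,
#' with standard deviation measured from failure sweeps.
#'
#' @param x Amplitude(s).
#' @param noise_sd Baseline noise SD (> 0).
#' @return Density value(s).
#' @export
noise_pdf <- function(x, noise_sd) {
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be positive")
  stats::dnorm(x, mean = 0, sd = noise_sd)
}

#' Composite quantal amplitude density
#'
#' Mixture density of an evoked response under the binomial-gamma quantal
#' model. A sweep with `j` successful releases contributes the sum of `j` iid
#' gamma uniquantal amplitudes - itself gamma with shape `j * gamma_shape` and
#' the same scale - while the failure component (`j = 0`) is the zero-mean
#' baseline-noise Gaussian:
#'
#' \deqn{Q(x \mid k) = B(0; n, p_k)\,N(x \mid 0, \epsilon) +
#'       \sum_{j=1}^{n} B(j; n, p_k)\,G(x \mid j\gamma, \lambda)}
#'
#' @param x Amplitude(s) at which to evaluate the density; may be negative
#'   (the noise component has full support).
#' @param params A [quantal_params()] object.
#' @param p Release probability for the condition, in `[0, 1]`.
#' @param noise_sd Baseline noise SD (> 0).
#' @return Density value(s).
#' @examples
#' pars <- quantal_params(n = 4, q = 0.1, cv = 0.3)
#' composite_amplitude_density(seq(-0.05, 0.6, by = 0.05), pars,
#'                             p = 0.5, noise_sd = 0.02)
#' @export
composite_amplitude_density <- function(x, params, p, noise_sd) {
  stopifnot(inherits(params, "quantal_params"))
  if (!is.finite(p) || p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be positive")
  n <- params$n
  w <- stats::dbinom(0:n, n, p)
  out <- w[1L] * noise_pdf(x, noise_sd)
  for (j in seq_len(n)) {
    out <- out + w[j + 1L] *
      gamma_pdf(x, gamma_shape = j * params$gamma_shape,
                lambda_scale = params$lambda_scale)
  }
  out
}

#' Quantal model log-likelihood of an observation set
#'
#' Log-likelihood of the binomial-gamma quantal model at one parameter point,
#' with the per-site release probability of each condition tied to its
#' observed mean response through `p_i = mu_i / (n q)`. Each condition
#' contributes a mean-response Gaussian weight term
#' `-log(se_i * sqrt(2 pi))` - conferring greater weight to conditions with
#' more sweeps - plus the sum of `log Q(x | k)` over its amplitudes. The
#' grid-wide numerical offset used during posterior evaluation is *not*
#' included here.
#'
#' Returns `-Inf` (rather than raising) when any implied `p_i` for a
#' condition with amplitudes falls outside `[0, 1]`, or when any composite
#' density evaluates to exactly zero: such parameter points simply carry no
#' posterior mass.
#'
#' @param obs An [observation_set()].
#' @param params A [quantal_params()] object.
#' @return A single log-likelihood value (possibly `-Inf`).
#' @export
quantal_log_likelihood <- function(obs, params) {
  stopifnot(inherits(obs, "observation_set"),
            inherits(params, "quantal_params"))
  p_i <- obs$means / (params$n * params$q)
  weight <- sum(-log(obs$ses * sqrt(2 * pi)))
  ll <- weight
  for (i in seq_len(obs$n_conditions)) {
    x <- obs$amplitudes[[i]]
    if (length(x) == 0L) next
    if (p_i[i] < 0 || p_i[i] > 1) return(-Inf)
    q_dens <- composite_amplitude_density(x, params, p_i[i], obs$noise_sd)
    if (any(q_dens == 0)) return(-Inf)
    ll <- ll + sum(log(q_dens))
  }
  ll
}
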