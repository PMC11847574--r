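#' Simulation design for the binomial-gamma quantal model
#'
#' Describes a forward-simulation experiment: the true quantal parameters, a
#' per-site release probability for each simulated condition (emulating, for
#' example, different extracellular Ca2+ concentrations), the number of
#' sweeps per condition, and the baseline noise SD.
#'
#' @param params A [quantal_params()] object (the ground truth).
#' @param condition_ps Release probability per condition, each in (0, 1).
#' @param sweeps_per_condition Sweeps per condition (recycled if scalar),
#'   each >= 2.
#' @param noise_sd Baseline noise SD (> 0).
#' @param seed Integer seed; simulation is bit-reproducible given the seed.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(params, condition_ps, sweeps_per_condition,
                              noise_sd, seed = 1L) {
  stopifnot(inherits(params, "quantal_params"))
  if (length(condition_ps) == 0L || any(!is.finite(condition_ps)) ||
      any(condition_ps <= 0) || any(condition_ps >= 1))
    stop("'condition_ps' must all lie strictly in (0, 1)")
  sweeps <- rep_len(as.integer(sweeps_per_condition), length(condition_ps))
  if (any(sweeps < 2L)) stop("'sweeps_per_condition' must be >= 2")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be non-negative")
  structure(
    list(params = params, condition_ps = as.numeric(condition_ps),
         sweeps_per_condition = sweeps, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' Simulate evoked amplitudes from the quantal model
#'
#' Forward-samples the composite quantal model: per sweep, the number of
#' successful releases is binomial `(n, p)`, the evoked amplitude is the sum
#' of that many iid gamma uniquantal draws, and zero-mean Gaussian baseline
#' noise is added. With `noise_mode = "known"` the returned observation set
#' carries the true noise SD; with `"estimated"` it carries the sample SD of
#' `noise_sweeps` additional simulated failure (noise-only) sweeps, emulating
#' measurement of the baseline noise from the raw data.
#'
#' @param design A [simulation_design()].
#' @param noise_mode `"known"` (default) or `"estimated"`.
#' @param noise_sweeps Number of failure sweeps used in estimated-noise mode.
#' @return An [observation_set()]; the true per-sweep release counts are
#'   attached as attribute `"release_counts"`.
#' @export
simulate_observations <- function(design, noise_mode = c("known", "estimated"),
                                  noise_sweeps = 200L) {
  stopifnot(inherits(design, "simulation_design"))
  noise_mode <- match.arg(noise_mode)
  pars <- design$params
  withr::with_seed(design$seed, {
    amps <- vector("list", length(design$condition_ps))
    counts <- vector("list", length(design$condition_ps))
    for (i in seq_along(design$condition_ps)) {
      m <- design$sweeps_per_condition[i]
      j <- stats::rbinom(m, pars$n, design$condition_ps[i])
      quantal <- vapply(j, function(jj) {
        if (jj == 0L) 0 else
          sum(stats::rgamma(jj, shape = pars$gamma_shape,
                            scale = pars$lambda_scale))
      }, numeric(1))
      amps[[i]] <- quantal + stats::rnorm(m, 0, design$noise_sd)
      counts[[i]] <- j
    }
    eps <- if (noise_mode == "known") design$noise_sd else
      stats::sd(stats::rnorm(noise_sweeps, 0, design$noise_sd))
    obs <- observation_set(amps, noise_sd = eps)
  })
  attr(obs, "release_counts") <- counts
  obs
}

#' Simulate a sweep trace containing random synaptic events
#'
#' Generates a time-sampled trace as a sum of template synaptic events
#' (difference-of-exponentials kernels) occurring at inhomogeneous-Poisson
#' times, plus Gaussian baseline noise. Used as a ground-truth fixture
#' generator for the miniature/asynchronous event detector and the kinetics
#' code; the planted event times and amplitudes are returned alongside.
#'
#' The default kernel time constants (0.3 ms rise, 3 ms decay) are on the
#' scale of glycinergic IPSCs. The kernel is normalized to unit peak so the
#' drawn amplitude is the event's peak amplitude.
#'
#' @param rate Event rate in Hz: a single number (homogeneous) or a function
#'   of time in seconds returning a rate (inhomogeneous, thinned against its
#'   maximum over the trace, supplied as `rate_max`).
#' @param amplitude_params A [quantal_params()] whose uniquantal gamma
#'   (shape, scale) is used to draw event amplitudes; or a single positive
#'   number for fixed amplitudes.
#' @param duration Trace duration, seconds.
#' @param noise_sd Baseline noise SD in trace units.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate, Hz (default 50000, i.e. 50 kHz).
#' @param rise_ms,decay_ms Kernel time constants, ms.
#' @param rate_max Upper bound on `rate` when it is a function.
#' @return A [sweep_trace()] with attributes `"event_times"` (seconds) and
#'   `"event_amplitudes"` (trace units, positive-going).
#' @export
simulate_event_train <- function(rate, amplitude_params, duration, noise_sd,
                                 seed = 1L, sample_rate = 50000,
                                 rise_ms = 0.3, decay_ms = 3,
                                 rate_max = NULL) {
  if (!is.function(rate) && (!is.finite(rate) || rate < 0))
    stop("'rate' must be non-negative (or a rate function of time)")
  n_samp <- max(2L, round(duration * sample_rate))
  dt <- 1 / sample_rate
  withr::with_seed(seed, {
    # event times: homogeneous Poisson, thinned if rate is a function
    if (is.function(rate)) {
      if (is.null(rate_max)) stop("'rate_max' required for a rate function")
      n_cand <- stats::rpois(1, rate_max * duration)
      t_cand <- sort(stats::runif(n_cand, 0, duration))
      keep <- stats::runif(n_cand) < vapply(t_cand, rate, numeric(1)) / rate_max
      ev_t <- t_cand[keep]
    } else {
      n_ev <- stats::rpois(1, rate * duration)
      ev_t <- sort(stats::runif(n_ev, 0, duration))
    }
    ev_a <- if (inherits(amplitude_params, "quantal_params")) {
      stats::rgamma(length(ev_t), shape = amplitude_params$gamma_shape,
                    scale = amplitude_params$lambda_scale)
    } else {
      rep(as.numeric(amplitude_params), length(ev_t))
    }
    noise <- stats::rnorm(n_samp, 0, noise_sd)
  })
  tvec <- (seq_len(n_samp) - 1L) * dt
  samples <- noise
  for (k in seq_along(ev_t)) {
    samples <- samples + ev_a[k] * event_kernel(tvec - ev_t[k],
                                                rise_ms, decay_ms)
  }
  tr <- sweep_trace(samples, sample_interval = dt)
  attr(tr, "event_times") <- ev_t
  attr(tr, "event_amplitudes") <- ev_a
  tr
}

# unit-peak difference-of-exponentials synaptic kernel; t in seconds
event_kernel <- function(t, rise_ms = 0.3, decay_ms = 3) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  if (tr >= td) stop("rise constant must be shorter than decay constant")
  k <- numeric(length(t))
  pos <- t >= 0
  k[pos] <- exp(-t[pos] / td) - exp(-t[pos] / tr)
  t_peak <- tr * td / (td - tr) * log(td / tr)
  k / (exp(-t_peak / td) - exp(-t_peak / tr))
}
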