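#' Time-sampled recording sweep
#'
#' A regularly sampled voltage (mV) or current (pA) trace, with optional
#' stimulus times and a baseline window preceding the first stimulus.
#'
#' @param samples Numeric vector of sampled values.
#' @param sample_interval Sampling interval, seconds (> 0).
#' @param stimulus_times Optional stimulus times, seconds, inside the trace.
#' @param baseline_window Optional `c(start, end)` in seconds, preceding the
#'   first stimulus.
#' @param units Trace units, metadata only (e.g. `"mV"`, `"pA"`).
#' @return An object of class `sweep_trace`.
#' @export
sweep_trace <- function(samples, sample_interval, stimulus_times = numeric(),
                        baseline_window = NULL, units = NA_character_) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("'samples' must be a numeric vector with at least 2 points")
  if (!is.finite(sample_interval) || sample_interval <= 0)
    stop("'sample_interval' must be positive")
  dur <- (length(samples) - 1L) * sample_interval
  if (length(stimulus_times) &&
      (any(stimulus_times < 0) || any(stimulus_times > dur)))
    stop("'stimulus_times' must lie within the trace")
  if (!is.null(baseline_window)) {
    if (length(baseline_window) != 2L || baseline_window[1] >= baseline_window[2])
      stop("'baseline_window' must be an ordered pair c(start, end)")
    if (length(stimulus_times) && baseline_window[2] > min(stimulus_times))
      stop("'baseline_window' must precede the first stimulus")
  }
  structure(
    list(samples = as.numeric(samples), sample_interval = sample_interval,
         stimulus_times = as.numeric(stimulus_times),
         baseline_window = baseline_window, units = units),
    class = "sweep_trace"
  )
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf("Sweep trace: %d samples at %.6g s (%.4g s total)%s\n",
              length(x$samples), x$sample_interval,
              (length(x$samples) - 1L) * x$sample_interval,
              if (is.na(x$units)) "" else paste0(", ", x$units)))
  if (length(x$stimulus_times))
    cat("  stimuli at:", paste(signif(x$stimulus_times, 4), collapse = ", "),
        "s\n")
  invisible(x)
}

trace_times <- function(trace) {
  (seq_along(trace$samples) - 1L) * trace$sample_interval
}

window_index <- function(trace, window) {
  t <- trace_times(trace)
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) < 2L) stop("window contains fewer than 2 samples")
  idx
}

#' Recording voltage context
#'
#' Holding/membrane and reversal potentials used by the conductance and
#' IPSP-correction computations. Defaults reflect common conventions: a
#' resting potential of -60 mV, reversal of 0 mV for excitation and -75 mV
#' for Cl--mediated inhibition (set `v_reversal` as appropriate).
#'
#' @param v_cell Holding/membrane voltage during the current measurement, mV.
#' @param v_reversal Assumed synaptic reversal potential, mV.
#' @param v_rest Resting potential, mV (default -60).
#' @param v_membrane Actual membrane potential during an IPSP sweep, mV.
#' @return An object of class `voltages_context`.
#' @export
voltages_context <- function(v_cell = NA_real_, v_reversal = NA_real_,
                             v_rest = -60, v_membrane = NA_real_) {
  structure(list(v_cell = v_cell, v_reversal = v_reversal, v_rest = v_rest,
                 v_membrane = v_membrane),
            class = "voltages_context")
}

#' Synaptic conductance from current and driving force
#'
#' `sigma = I / (V_reversal - V_cell)`: the synaptic conductance implied by a
#' measured postsynaptic current and the driving force at the holding
#' voltage. Units must be consistent: current in pA and voltages in mV give
#' conductance in nS.
#'
#' @param current Measured synaptic current, pA (signed).
#' @param context A [voltages_context()] with `v_cell` and `v_reversal` set.
#' @return A list with `conductance` (signed, nS) and `magnitude` (nS),
#'   the latter used for group comparisons.
#' @examples
#' synaptic_conductance(-600, voltages_context(v_cell = -60, v_reversal = 0))
#' @export
synaptic_conductance <- function(current, context) {
  stopifnot(inherits(context, "voltages_context"))
  dv <- context$v_reversal - context$v_cell
  if (!is.finite(dv) || dv == 0)
    stop("v_reversal equals v_cell: zero driving force, conductance undefined ",
         "(units: pA / mV -> nS)")
  sigma <- current / dv
  list(conductance = sigma, magnitude = abs(sigma))
}

#' Conductance scaled to the cell's resting conductance
#'
#' Expresses a synaptic conductance as a percentage of the recorded cell's
#' resting conductance, `sigma * 100 / sigma_cell`, removing the dependence
#' of absolute synaptic conductance on cell size.
#'
#' @param sigma Synaptic conductance, nS.
#' @param sigma_cell Resting cell conductance, nS (> 0).
#' @return Percentage of resting conductance.
#' @export
scaled_conductance <- function(sigma, sigma_cell) {
  if (!is.finite(sigma_cell) || sigma_cell <= 0)
    stop("'sigma_cell' must be positive")
  sigma * 100 / sigma_cell
}

#' Driving-force correction of IPSP amplitudes
#'
#' Corrects an IPSP amplitude recorded at membrane potential `v_membrane`
#' to the amplitude it would have at the resting potential, assuming a
#' linear driving-force model:
#' `IPSP * (V_rest - V_reversal) / (V_membrane - V_reversal)`.
#'
#' @param ipsp IPSP amplitude, mV.
#' @param context A [voltages_context()] with `v_rest`, `v_reversal`,
#'   `v_membrane` set.
#' @return Corrected IPSP amplitude, mV.
#' @examples
#' corrected_ipsp(2, voltages_context(v_rest = -60, v_reversal = -75,
#'                                    v_membrane = -50))
#' @export
corrected_ipsp <- function(ipsp, context) {
  stopifnot(inherits(context, "voltages_context"))
  denom <- context$v_membrane - context$v_reversal
  if (!is.finite(denom) || denom == 0)
    stop("v_membrane equals v_reversal: zero driving force, correction undefined")
  ipsp * (context$v_rest - context$v_reversal) / denom
}

#' Slope conductance from a current-voltage relationship
#'
#' Least-squares slope of injected current against the resulting voltage
#' deflection (dI/dV). With pA and mV inputs the result is in nS.
#'
#' @param current_steps Injected current steps, pA (>= 2 distinct values).
#' @param voltage_deflections Measured voltage deflections, mV.
#' @return Slope conductance, nS.
#' @export
iv_conductance <- function(current_steps, voltage_deflections) {
  if (length(current_steps) != length(voltage_deflections))
    stop("current and voltage vectors must have equal length")
  if (length(unique(current_steps)) < 2L)
    stop("need at least 2 distinct current steps")
  if (length(unique(voltage_deflections)) < 2L)
    stop("degenerate I-V: all voltage deflections identical")
  fit <- stats::lm(current_steps ~ voltage_deflections)
  unname(stats::coef(fit)[2L])
}

#' Recurrent-inhibition conductance from paired I-V relationships
#'
#' Difference between the slope conductance measured during a high-frequency
#' stimulus train (when recurrent inhibition is at steady state) and the
#' resting slope conductance. A negative difference is physiologically
#' unexpected and is flagged with a warning, not suppressed.
#'
#' @param rest_iv,train_iv Lists with elements `current` (pA) and `voltage`
#'   (mV) for the resting and during-train I-V relationships.
#' @return Conductance difference, nS.
#' @export
recurrent_inhibition_conductance <- function(rest_iv, train_iv) {
  s_rest <- iv_conductance(rest_iv$current, rest_iv$voltage)
  s_train <- iv_conductance(train_iv$current, train_iv$voltage)
  d <- s_train - s_rest
  if (d < 0)
    warning("train conductance below resting conductance: ",
            "negative recurrent-inhibition estimate")
  d
}

#' Subtract a stimulation-artifact exponential tail
#'
#' Fits the tail of a stimulation artifact within `fit_window` with a single
#' or double exponential decay (plus offset), extrapolates the fit forward to
#' the end of the trace, and subtracts it, uncovering the synaptic response
#' that the artifact tail contaminates. The input trace is not modified; a
#' corrected copy is returned.
#'
#' The double-exponential fit is initialized from a single-exponential fit
#' with bounded positive time constants.
#'
#' @param trace A [sweep_trace()].
#' @param fit_window `c(start, end)` seconds: after the stimulus, before the
#'   response onset region.
#' @param model `"single"` or `"double"`.
#' @return A new `sweep_trace` with the fitted artifact subtracted from
#'   `fit_window[1]` onward; the fit is attached as attribute
#'   `"artifact_fit"`.
#' @export
subtract_artifact <- function(trace, fit_window,
                              model = c("single", "double")) {
  stopifnot(inherits(trace, "sweep_trace"))
  model <- match.arg(model)
  idx <- window_index(trace, fit_window)
  t0 <- fit_window[1]
  tt <- trace_times(trace)[idx] - t0
  y <- trace$samples[idx]

  if (all(y == 0)) {            # nothing to fit: zero trace stays zero
    out <- trace
    attr(out, "artifact_fit") <- list(model = "none", coef = NULL)
    return(out)
  }

  span <- max(tt[length(tt)], trace$sample_interval)
  a0 <- y[1L] - y[length(y)]
  if (a0 == 0) a0 <- max(abs(y))
  start1 <- list(A = a0, tau = span / 3, C = y[length(y)])
  df <- data.frame(tt = tt, y = y)
  fit1 <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-tt / tau) + C, data = df, start = start1,
                      lower = c(-Inf, trace$sample_interval / 100, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("artifact fit failed (single exponential): ",
                             conditionMessage(e)))
  fit <- fit1
  if (model == "double") {
    cf <- stats::coef(fit1)
    start2 <- list(A1 = cf[["A"]] * 0.7, tau1 = cf[["tau"]] * 0.5,
                   A2 = cf[["A"]] * 0.3, tau2 = cf[["tau"]] * 2,
                   C = cf[["C"]])
    fit2 <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-tt / tau1) + A2 * exp(-tt / tau2) + C,
                        data = df, start = start2,
                        lower = c(-Inf, trace$sample_interval / 100,
                                  -Inf, trace$sample_interval / 100, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit2)) fit <- fit2
  }

  t_all <- trace_times(trace)
  after <- t_all >= t0
  pred <- stats::predict(fit, newdata = data.frame(tt = t_all[after] - t0))
  out <- trace
  out$samples[after] <- out$samples[after] - pred
  attr(out, "artifact_fit") <- list(model = model, coef = stats::coef(fit))
  out
}

# linear-interpolated time at which y crosses 'level' between samples i, i+1
cross_time <- function(t, y, level, from, to) {
  ii <- seq(from, to - 1L)
  for (i in ii) {
    y0 <- y[i]; y1 <- y[i + 1L]
    if ((y0 - level) * (y1 - level) <= 0 && y0 != y1) {
      return(t[i] + (level - y0) / (y1 - y0) * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}

#' Rise/decay kinetics and amplitude of a response
#'
#' Measures the amplitude of the extremum inside `event_window` relative to a
#' local baseline, and the rise and decay times between the `lo_frac` and
#' `hi_frac` fractional amplitude levels (10-90% is standard for evoked
#' responses; 20-80% is more robust for small spontaneous events). Crossing
#' times are linearly interpolated between samples.
#'
#' @param trace A [sweep_trace()].
#' @param event_window `c(start, end)`, seconds, containing the response.
#' @param lo_frac,hi_frac Fractional amplitude levels, `0 < lo < hi < 1`.
#' @param direction `"positive"` or `"negative"`: the expected deflection
#'   direction of the response.
#' @param baseline_ms Length (ms) of the pre-window segment, ending at
#'   `event_window[1]`, whose mean defines the local baseline.
#' @param min_amplitude Minimum acceptable amplitude above baseline; below
#'   this a detection error is raised.
#' @return A list with `amplitude` (positive magnitude), `rise_time_ms`,
#'   `decay_time_ms`, `peak_time` (s), `baseline`.
#' @export
response_kinetics <- function(trace, event_window, lo_frac = 0.1,
                              hi_frac = 0.9, direction = c("positive",
                                                           "negative"),
                              baseline_ms = 2, min_amplitude = 0) {
  stopifnot(inherits(trace, "sweep_trace"))
  direction <- match.arg(direction)
  if (!(lo_frac > 0 && lo_frac < hi_frac && hi_frac < 1))
    stop("need 0 < lo_frac < hi_frac < 1")
  t <- trace_times(trace)
  y <- trace$samples
  if (direction == "negative") y <- -y
  idx <- window_index(trace, event_window)

  bl_idx <- which(t >= event_window[1] - baseline_ms / 1000 &
                  t < event_window[1])
  baseline <- if (length(bl_idx)) mean(y[bl_idx]) else y[idx[1L]]

  rel <- y[idx] - baseline
  pk <- which.max(rel)
  amp <- rel[pk]
  if (!is.finite(amp) || amp <= min_amplitude)
    stop("no detectable extremum above baseline in the event window")
  pk_i <- idx[pk]

  lo_lev <- baseline + lo_frac * amp
  hi_lev <- baseline + hi_frac * amp
  # rising limb: last crossings before the peak
  t_lo_rise <- cross_time(t, y, lo_lev, idx[1L], pk_i)
  t_hi_rise <- cross_time(t, y, hi_lev, idx[1L], pk_i)
  rise <- if (is.na(t_lo_rise) || is.na(t_hi_rise)) {
    trace$sample_interval            # sharper than one sample
  } else {
    t_hi_rise - t_lo_rise
  }
  # falling limb: first crossings after the peak (search to end of trace so
  # slow decays extending past the window are still measured)
  t_hi_fall <- cross_time(t, y, hi_lev, pk_i, length(y))
  t_lo_fall <- cross_time(t, y, lo_lev, pk_i, length(y))
  decay <- if (is.na(t_hi_fall) || is.na(t_lo_fall)) NA_real_ else
    t_lo_fall - t_hi_fall

  list(amplitude = amp, rise_time_ms = rise * 1000,
       decay_time_ms = decay * 1000, peak_time = t[pk_i],
       baseline = baseline)
}

#' Response onset latency from the derivative threshold
#'
#' Onset is the first post-stimulus time point at which the absolute trace
#' derivative exceeds 5 times the standard deviation of the derivative over
#' the baseline window. Returns `NA` (a no-response signal, not an error)
#' when the threshold is never crossed. Jitter across sweeps is the SD of
#' the per-sweep onsets; compare within cells only.
#'
#' @param trace A [sweep_trace()].
#' @param stimulus_time Stimulus time, seconds.
#' @param baseline_window `c(start, end)` preceding the stimulus.
#' @param threshold_mult Derivative threshold in baseline-derivative SDs
#'   (default 5).
#' @return Latency in seconds from `stimulus_time`, or `NA_real_`.
#' @export
onset_latency <- function(trace, stimulus_time, baseline_window,
                          threshold_mult = 5) {
  stopifnot(inherits(trace, "sweep_trace"))
  if (baseline_window[2] > stimulus_time)
    stop("'baseline_window' must precede the stimulus")
  t <- trace_times(trace)
  d <- diff(trace$samples) / trace$sample_interval
  td <- t[-1L]
  base_sd <- stats::sd(d[td >= baseline_window[1] & td <= baseline_window[2]])
  if (!is.finite(base_sd) || base_sd == 0) base_sd <- .Machine$double.eps
  post <- which(td > stimulus_time)
  hit <- post[abs(d[post]) > threshold_mult * base_sd]
  if (!length(hit)) return(NA_real_)
  td[hit[1L]] - stimulus_time
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first response amplitude for two closely
#' spaced stimuli (e.g. 33 Hz); a classical probe of release probability.
#'
#' @param amp1 First response amplitude (> 0).
#' @param amp2 Second response amplitude.
#' @return `amp2 / amp1`.
#' @export
paired_pulse_ratio <- function(amp1, amp2) {
  if (any(!is.finite(amp1)) || any(amp1 <= 0))
    stop("'amp1' must be positive")
  amp2 / amp1
}

#' Detect miniature/asynchronous synaptic events
#'
#' Scans a trace for spontaneous events: candidate peaks at least
#' `threshold_mult` (default 1.5) times the baseline noise SD above a local
#' pre-event baseline are retained only if their waveform is characteristic
#' of a synaptic event - 20-80% rise time longer than `min_rise_ms` and
#' decay longer than `min_decay_ms`. The baseline noise SD must be measured
#' by the caller from an event-free window; the detector does not search for
#' one (its threshold would otherwise depend on its own output).
#'
#' @param trace A [sweep_trace()]; events are assumed positive-going (flip
#'   the trace for inward currents before calling).
#' @param noise_sd Baseline noise SD, trace units (> 0).
#' @param threshold_mult Amplitude threshold in noise SDs (default 1.5).
#' @param min_rise_ms Minimum 20-80% rise time, ms (default 0.1).
#' @param min_decay_ms Minimum 80-20% decay time, ms (default 0.5).
#' @param baseline_ms Pre-event window (ms) whose mean defines the local
#'   baseline (default 2).
#' @param refractory_ms Minimum separation between detected peaks, ms.
#' @return A data frame of class `synaptic_events` with columns `time`,
#'   `amplitude`, `rise_time_ms`, `decay_time_ms`, `inter_event_interval_ms`,
#'   sorted by time. Zero rows when nothing qualifies.
#' @export
detect_minis <- function(trace, noise_sd, threshold_mult = 1.5,
                         min_rise_ms = 0.1, min_decay_ms = 0.5,
                         baseline_ms = 2, refractory_ms = 2) {
  stopifnot(inherits(trace, "sweep_trace"))
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be positive (measure it from an event-free window)")
  t <- trace_times(trace)
  y <- trace$samples
  dt <- trace$sample_interval
  thr <- threshold_mult * noise_sd
  bl_n <- max(1L, round(baseline_ms / 1000 / dt))

  # candidate peaks: local maxima of supra-threshold excursions
  above <- y > thr
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)

  rows <- list()
  last_peak_t <- -Inf
  for (k in runs) {
    seg <- starts[k]:ends[k]
    pk_i <- seg[which.max(y[seg])]
    if (t[pk_i] - last_peak_t < refractory_ms / 1000) next
    bl_i <- max(1L, starts[k] - bl_n):max(1L, starts[k] - 1L)
    baseline <- mean(y[bl_i])
    amp <- y[pk_i] - baseline
    if (amp < thr) next

    lo_lev <- baseline + 0.2 * amp
    hi_lev <- baseline + 0.8 * amp
    on_i <- max(1L, starts[k] - bl_n)
    t_lo_r <- cross_time(t, y, lo_lev, on_i, pk_i)
    t_hi_r <- cross_time(t, y, hi_lev, on_i, pk_i)
    rise_ms <- if (is.na(t_lo_r) || is.na(t_hi_r)) dt * 1000 else
      (t_hi_r - t_lo_r) * 1000
    end_i <- min(length(y), pk_i + 20L * bl_n)
    t_hi_f <- cross_time(t, y, hi_lev, pk_i, end_i)
    t_lo_f <- cross_time(t, y, lo_lev, pk_i, end_i)
    decay_ms <- if (is.na(t_hi_f) || is.na(t_lo_f)) NA_real_ else
      (t_lo_f - t_hi_f) * 1000
    if (rise_ms <= min_rise_ms) next
    if (is.na(decay_ms) || decay_ms <= min_decay_ms) next

    last_peak_t <- t[pk_i]
    rows[[length(rows) + 1L]] <- data.frame(
      time = t[pk_i], amplitude = amp, rise_time_ms = rise_ms,
      decay_time_ms = decay_ms)
  }
  if (!length(rows)) return(empty_events())
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time), , drop = FALSE]
  ev$inter_event_interval_ms <- c(NA_real_, diff(ev$time) * 1000)
  rownames(ev) <- NULL
  class(ev) <- c("synaptic_events", "data.frame")
  ev
}

empty_events <- function() {
  ev <- data.frame(time = numeric(), amplitude = numeric(),
                   rise_time_ms = numeric(), decay_time_ms = numeric(),
                   inter_event_interval_ms = numeric())
  class(ev) <- c("synaptic_events", "data.frame")
  ev
}
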