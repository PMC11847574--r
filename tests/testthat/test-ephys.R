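test_that("synaptic conductance follows the driving-force relation", {
  ctx <- voltages_context(v_cell = -60, v_reversal = 0)
  r <- synaptic_conductance(-600, ctx)
  expect_equal(r$magnitude, 10)
  expect_equal(r$conductance, -10)
  expect_equal(synaptic_conductance(0, ctx)$conductance, 0)
  half <- voltages_context(v_cell = -30, v_reversal = 0)
  expect_equal(synaptic_conductance(-600, half)$magnitude, 20)
  # linearity in the current argument
  expect_equal(synaptic_conductance(-1200, ctx)$conductance,
               2 * synaptic_conductance(-600, ctx)$conductance)
  expect_error(synaptic_conductance(
    10, voltages_context(v_cell = 0, v_reversal = 0)), "driving force")
})

test_that("scaled conductance is a percentage of resting conductance", {
  expect_equal(scaled_conductance(10, 100), 10)
  expect_equal(scaled_conductance(55, 55), 100)
  expect_equal(scaled_conductance(3 * 10, 3 * 100),
               scaled_conductance(10, 100))
  expect_error(scaled_conductance(10, 0), "positive")
})

test_that("IPSP correction rescales by the driving-force ratio", {
  at_rest <- voltages_context(v_rest = -60, v_reversal = -75,
                              v_membrane = -60)
  expect_equal(corrected_ipsp(2.4, at_rest), 2.4)
  ctx <- voltages_context(v_rest = -60, v_reversal = -75, v_membrane = -50)
  expect_equal(corrected_ipsp(2, ctx), 2 * 15 / 25)   # 1.2 mV
  expect_equal(corrected_ipsp(0, ctx), 0)
  expect_equal(corrected_ipsp(4, ctx), 2 * corrected_ipsp(2, ctx))
  expect_error(corrected_ipsp(
    1, voltages_context(v_rest = -60, v_reversal = -75, v_membrane = -75)),
    "driving force")
})

test_that("I-V slope conductance is exact on a line and robust to noise", {
  expect_equal(iv_conductance(c(-200, -100, 0, 100), c(-20, -10, 0, 10)), 10)
  expect_equal(iv_conductance(c(-200, -100, 0, 100),
                              c(-20, -10, 0, 10) + 3.7), 10)
  set.seed(5)
  v <- seq(-20, 10, length.out = 1000)
  i <- 12 * v + rnorm(1000, 0, 2)
  expect_lt(abs(iv_conductance(i, v) - 12) / 12, 0.01)
  expect_error(iv_conductance(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("recurrent inhibition is the train-rest conductance difference", {
  v <- c(-10, -5, 0, 5, 10)
  rest <- list(current = 100 * v, voltage = v)      # 100 nS
  train <- list(current = 150 * v, voltage = v)     # 150 nS
  expect_equal(recurrent_inhibition_conductance(rest, rest), 0)
  d <- recurrent_inhibition_conductance(rest, train)
  expect_equal(d, 50)
  expect_equal(scaled_conductance(d, 100), 50)
  expect_warning(recurrent_inhibition_conductance(train, rest), "negative")
})

test_that("artifact subtraction recovers a response under an exponential tail", {
  dt <- 1 / 50000
  t <- seq(0, 0.05, by = dt)
  # a trace that IS a pure exponential fits itself to numerical precision
  pure <- sweep_trace(100 * exp(-t / 0.002) + 3, dt)
  resid <- subtract_artifact(pure, c(0.001, 0.004), "single")
  expect_lt(max(abs(resid$samples[t >= 0.001])) / 100, 1e-6)
  expect_equal(pure$samples[1], 103)     # input untouched

  # double-exponential artifact plus a delayed synaptic response
  art <- 200 * exp(-t / 0.0005) + 50 * exp(-t / 0.003)
  epsc <- 20 * synquant:::event_kernel(t - 0.010)
  corrected <- subtract_artifact(sweep_trace(art + epsc, dt),
                                 c(0.002, 0.008), "double")
  k <- response_kinetics(corrected, c(0.009, 0.03), baseline_ms = 1)
  expect_lt(abs(k$amplitude - 20) / 20, 0.02)

  zero <- sweep_trace(numeric(100), dt)
  expect_equal(subtract_artifact(zero, c(0.0002, 0.001))$samples,
               numeric(100))
})

test_that("rise/decay kinetics match the exponential closed form", {
  tr <- exp_decay_trace(amp = 8, tau_s = 0.003)
  k <- response_kinetics(tr, c(0.005, 0.045))
  expect_equal(k$decay_time_ms, 3 * log(0.9 / 0.1), tolerance = 1e-3)
  expect_equal(k$amplitude, 8, tolerance = 1e-3)
  k2 <- response_kinetics(tr, c(0.005, 0.045), lo_frac = 0.2, hi_frac = 0.8)
  expect_equal(k2$decay_time_ms, 3 * log(0.8 / 0.2), tolerance = 1e-3)
  # amplitude scaling leaves times unchanged; DC offset leaves all unchanged
  big <- response_kinetics(exp_decay_trace(amp = 16), c(0.005, 0.045))
  expect_equal(big$decay_time_ms, k$decay_time_ms)
  expect_equal(big$rise_time_ms, k$rise_time_ms)
  shifted <- response_kinetics(exp_decay_trace(amp = 8, offset = -62),
                               c(0.005, 0.045))
  expect_equal(shifted$amplitude, 8, tolerance = 1e-3)
  expect_equal(shifted$decay_time_ms, k$decay_time_ms)
  flat <- sweep_trace(rep(0, 1000), 1 / 50000)
  expect_error(response_kinetics(flat, c(0.005, 0.015), min_amplitude = 0),
               "extremum")
})

test_that("onset latency crosses at the 5x baseline-derivative threshold", {
  dt <- 1 / 50000
  t <- seq(0, 0.05, by = dt)
  mk <- function(offset = 0) {
    y <- ifelse(t >= 0.012, (t - 0.012) * 5000, 0) +
      0.001 * sin(t * 1000) + offset
    sweep_trace(y, dt)
  }
  lat <- onset_latency(mk(), stimulus_time = 0.010,
                       baseline_window = c(0, 0.009))
  expect_equal(lat, 0.002, tolerance = dt / 0.002)
  expect_equal(onset_latency(mk(-70), 0.010, c(0, 0.009)), lat)
  flat <- sweep_trace(0.001 * sin(t * 1000), dt)
  expect_true(is.na(onset_latency(flat, 0.010, c(0, 0.009))))
})

test_that("paired-pulse ratio is amp2/amp1 and scale-invariant", {
  expect_equal(paired_pulse_ratio(5, 5), 1)
  expect_equal(paired_pulse_ratio(10, 4), 0.4)
  expect_equal(paired_pulse_ratio(3 * 10, 3 * 4), paired_pulse_ratio(10, 4))
  expect_error(paired_pulse_ratio(0, 4), "positive")
})

test_that("mini detection applies amplitude and waveform criteria", {
  fx <- mini_fixture()
  ev <- detect_minis(fx$trace, noise_sd = fx$noise_sd)
  expect_identical(nrow(ev), 3L)
  expect_equal(ev$time, fx$conforming_times, tolerance = 0.01)
  expect_true(all(abs(ev$amplitude - fx$amplitude) < fx$noise_sd))
  expect_true(all(ev$rise_time_ms > 0.1))
  expect_true(all(ev$decay_time_ms > 0.5))
  # sorted with strictly positive inter-event intervals
  expect_true(all(diff(ev$time) > 0))
  expect_true(all(ev$inter_event_interval_ms[-1] > 0))
})

test_that("pure noise yields essentially no false positives", {
  set.seed(3)
  noise <- sweep_trace(rnorm(500000, 0, 1), 1 / 50000)   # 10 s at 50 kHz
  expect_lt(nrow(detect_minis(noise, noise_sd = 1)), 1)
})
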