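test_that("escape-noise probability matches the calibrated prefactor", {
  p <- neuron_params()
  # reference calibration value for the default parameter set
  expect_equal(escape_spike_prob(-54, p), 0.00594, tolerance = 1e-4 / 0.00594)
  # at rest the parameterization forces the resting rate: f_rest * dt
  expect_identical(escape_spike_prob(p$v_rest, p), p$f_rest * p$dt * 1e-3)
  # far above threshold the probability clips at 1
  expect_identical(escape_spike_prob(-54 + 100 * p$b, p), 1)
  expect_error(escape_spike_prob(NaN, p), "finite")
  expect_error(escape_spike_prob(Inf, p), "finite")
  # vectorized and always a probability
  v <- seq(-120, 40, by = 0.5)
  pr <- escape_spike_prob(v, p)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(diff(pr) >= 0))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(neuron_params(dt = 0), "dt")
  expect_error(neuron_params(U = 0), "U")
  expect_error(neuron_params(U = 1.2), "U")
  expect_error(neuron_params(v_rest = -54, v_th = -74), "v_rest")
  expect_error(neuron_params(tau_m = -1), "tau_m")
  expect_error(stdp_params(A_E = 0), "A_E")
  # inhibitory window validity: tau_I1/tau_I2 < min(1/beta_I, 1)
  expect_error(stdp_params(beta_I = 2.5), "tau_I1/tau_I2")
  expect_silent(stdp_params(beta_I = 1.9))
  expect_equal(stdp_params(preset = "sub")$beta_E, 1.2)
})

test_that("subthreshold dynamics relax to the closed-form exponentials", {
  st <- build_network(3, 1, seed = 1)
  p <- st$params
  # fixed point: at rest with no conductance nothing moves
  st$v[] <- p$v_rest
  st$g_exc[] <- 0; st$g_inh[] <- 0
  st1 <- step_subthreshold(st)
  expect_equal(st1$v, st$v)
  expect_equal(st1$t, p$dt)

  # membrane decay from -54 mV over 30 ms: v -> -74 + 20/e
  st$v[] <- -54
  for (i in 1:300) st <- step_subthreshold(st)
  expect_equal(st$v[1], v_closed_form(-54, 30, p), tolerance = 0.05 / 66)
  expect_equal(st$t, 30)

  # conductance decay is exact per step: g_exc(2 ms) = 1/e
  st2 <- build_network(3, 1, seed = 1)
  st2$g_exc[] <- 1
  st2$v[] <- p$v_rest  # keep v interactions out of the comparison
  for (i in 1:20) st2 <- step_subthreshold(st2)
  expect_equal(st2$g_exc[1], exp(-1), tolerance = 1e-6)

  # resource recovery: x0 = 0.6, 150 ms quiet -> 1 - 0.4/e
  st3 <- build_network(3, 1, seed = 1)
  st3$x[] <- 0.6
  for (i in 1:1500) st3 <- step_subthreshold(st3)
  expect_equal(st3$x[1], 1 - 0.4 / exp(1), tolerance = 1e-4)
})

test_that("Euler error shrinks with dt (convergence to the closed form)", {
  err <- vapply(c(0.1, 0.01), function(dt) {
    st <- build_network(2, 1, params = neuron_params(dt = dt), seed = 1)
    st$v[] <- -54
    for (i in seq_len(round(30 / dt))) st <- step_subthreshold(st)
    abs(st$v[1] - v_closed_form(-54, 30, st$params))
  }, 0)
  expect_lt(err[1], 0.05)
  expect_lt(err[2], err[1] / 5)
})

test_that("fire_and_deliver implements reset, STP depletion and delayed release", {
  st <- build_network(2, 1, seed = 1)
  p <- st$params
  st$w[1, 2] <- 1
  st$v[] <- p$v_rest
  st0 <- st
  st <- fire_and_deliver(st, 1L)
  # Tsodyks-Markram depletion with U = 0.4
  expect_equal(st$x[1], 0.6)
  # reset and refractory (excitatory: 3 ms)
  expect_equal(st$v[1], p$v_rest)
  expect_equal(st$refrac_until[1], st$t + p$T_ref_exc)
  # queued release U*x*w*g_max = 0.4*1*1*4 = 1.6 at the EE delay (1.5 ms)
  d_ee <- round(p$delay_EE / p$dt)
  expect_equal(st$pend_exc[d_ee, 2], 1.6)
  expect_equal(sum(st$pend_exc) + sum(st$pend_inh), 1.6)  # w elsewhere is 0
  # delivered exactly d_ee steps later (then decayed once within the step)
  for (i in seq_len(d_ee - 1)) st <- step_subthreshold(st)
  expect_equal(max(st$g_exc), 0)
  st <- step_subthreshold(st)
  expect_equal(st$g_exc[2], 1.6 * exp(-p$dt / p$tau_AMPA))
  expect_error(fire_and_deliver(st0, 99L), "unknown unit")
  # refractory units cannot spike again immediately
  expect_error(fire_and_deliver(st, 1L), "refractory")
})

test_that("external stimulation adds the amplitude to excitatory targets only", {
  st <- build_network(3, 1, seed = 1)
  st$v[] <- -74
  pat <- stimulus_pattern(c(1, 3), amplitude = 30)
  st1 <- apply_external_stimulus(st, pat)
  expect_equal(st1$v, c(-44, -74, -44, -74))
  # amplitude 0 leaves the state unchanged
  st2 <- apply_external_stimulus(st, stimulus_pattern(1, amplitude = 0))
  expect_equal(st2$v, st$v)
  # inhibitory targets are rejected (unit 4 is inhibitory)
  expect_error(apply_external_stimulus(st, stimulus_pattern(4)),
               "excitatory")
  expect_error(stimulus_pattern(integer()), "nonempty")
  expect_error(stimulus_pattern(c(2, 2)), "repeat")
})

test_that("an isolated neuron fires at f_rest (binomial 99% CI)", {
  # 10 neurons x 100 s = 1,000 neuron-seconds at 0.4 Hz -> ~400 spikes
  st <- build_network(9, 1, seed = 7)
  res <- run_free(st, 100, plasticity = FALSE)
  k <- nrow(res$spikes)
  expected <- 10 * 100 * 0.4
  margin <- qnorm(0.995) * sqrt(expected)
  expect_gt(k, expected - margin)
  expect_lt(k, expected + margin)
  # weights stayed zero: no synaptic coupling existed
  expect_equal(sum(res$state$w), 0)
})
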