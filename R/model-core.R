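#' Escape-noise spike probability for one timestep
#'
#' Probability that a neuron at membrane potential `v` emits a spike within
#' one timestep under the escape-noise rule
#' `min((dt/tau) * exp((v - v_th)/b), 1)`, where the prefactor
#' `dt/tau = f_rest * dt * exp((v_th - v_rest)/b)` is calibrated so that a
#' neuron sitting at `v_rest` fires at `f_rest`. With the default parameters
#' the prefactor is ~0.00594 per 0.1-ms step.
#'
#' @param v membrane potential(s), mV
#' @param params a [neuron_params()] object
#' @return spike probability per step, same length as `v`, in \[0, 1\]
#' @export
#' @examples
#' escape_spike_prob(-54, neuron_params())  # ~0.00594
escape_spike_prob <- function(v, params = neuron_params()) {
  if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)))
    stop("v must be finite numeric")
  pmin(escape_prefactor(params) * exp((v - params$v_th) / params$b), 1)
}

#' @rdname escape_spike_prob
#' @export
escape_prefactor <- function(params = neuron_params()) {
  # f_rest is in Hz, dt in ms
  params$f_rest * params$dt * 1e-3 *
    exp((params$v_th - params$v_rest) / params$b)
}

# --- pure-R reference single-step operations --------------------------------
# These implement exactly the same per-step phases as the compiled engine
# (see cpp_run in src/engine.cpp) and exist so the update rules can be read,
# unit-tested and cross-checked against closed forms without touching C++.
# They cover membrane/synapse/STP dynamics; STDP lives in R/plasticity.R.

#' Advance the subthreshold dynamics by one timestep
#'
#' Delivers delayed synaptic events due this step, then performs one forward
#' Euler step of the membrane equation
#' `tau_m dv/dt = (v_rest - v) g_rest + (E_exc - v) g_exc + (E_inh - v) g_inh`
#' (refractory neurons hold `v = v_rest`), decays `g_exc`/`g_inh` with their
#' exact per-step exponential factors, and relaxes the presynaptic resource
#' `x` toward 1 with time constant `tau_rec`. The clock advances by `dt`.
#'
#' @param state a network state from [build_network()]
#' @param params neuron parameters; defaults to those stored in the state
#' @return the updated state
#' @seealso [fire_and_deliver()], [apply_external_stimulus()]
#' @export
step_subthreshold <- function(state, params = state$params) {
  stopifnot(inherits(state, "network_state"))
  ts <- state$t + params$dt

  # phase 1: delayed deliveries due this step
  state$g_exc <- state$g_exc + state$pend_exc[1L, ]
  state$g_inh <- state$g_inh + state$pend_inh[1L, ]
  state$pend_exc <- rbind(state$pend_exc[-1L, , drop = FALSE], 0)
  state$pend_inh <- rbind(state$pend_inh[-1L, , drop = FALSE], 0)

  # phase 2: Euler step for v, exact decay for g and x
  blocked <- ts < state$refrac_until - 1e-9
  dv <- params$dt / params$tau_m *
    ((params$v_rest - state$v) * params$g_rest +
     (params$E_exc - state$v) * state$g_exc +
     (params$E_inh - state$v) * state$g_inh)
  state$v <- ifelse(blocked, params$v_rest, state$v + dv)
  state$g_exc <- state$g_exc * exp(-params$dt / params$tau_AMPA)
  state$g_inh <- state$g_inh * exp(-params$dt / params$tau_GABA)
  state$x <- 1 - (1 - state$x) * exp(-params$dt / params$tau_rec)

  state$t <- ts
  state
}

#' Process spikes: resets, refractoriness, resource depletion, delayed release
#'
#' For each spiking unit `i` the membrane potential is reset to `v_rest`, the
#' refractory timer is set (`T_ref_exc` for excitatory, `T_ref_inh` for
#' inhibitory units), and for every postsynaptic unit `j` a delayed event
#' carrying `U * x[i] * w[i, j] * g_max` (with `x` taken before depletion) is
#' queued for delivery `delay_EE` ms later on excitatory-to-excitatory
#' synapses and `delay_other` ms later on all other synapses. Finally the
#' presynaptic resource is depleted, `x[i] <- x[i] - U * x[i]`. Queued events
#' are delivered by [step_subthreshold()] when due.
#'
#' @param state a network state
#' @param spiking integer vector of spiking unit ids (1-based)
#' @param params neuron parameters
#' @return the updated state
#' @export
fire_and_deliver <- function(state, spiking, params = state$params) {
  stopifnot(inherits(state, "network_state"))
  if (length(spiking) == 0L) return(state)
  spiking <- as.integer(spiking)
  if (any(is.na(spiking)) || any(spiking < 1L) || any(spiking > state$n))
    stop("unknown unit id in 'spiking'")
  if (any(state$t < state$refrac_until[spiking] - 1e-9))
    stop("refractory units cannot spike")

  d_ee <- as.integer(round(params$delay_EE / params$dt))
  d_oo <- as.integer(round(params$delay_other / params$dt))
  for (i in spiking) {
    q <- params$U * state$x[i]
    gmax <- if (state$is_exc[i]) params$g_max_exc else params$g_max_inh
    amt <- q * state$w[i, ] * gmax
    amt[i] <- 0
    d <- if (state$is_exc[i]) ifelse(state$is_exc, d_ee, d_oo) else d_oo
    for (j in which(amt > 0)) {
      if (state$is_exc[i])
        state$pend_exc[d[j], j] <- state$pend_exc[d[j], j] + amt[j]
      else
        state$pend_inh[d[j], j] <- state$pend_inh[d[j], j] + amt[j]
    }
    state$x[i] <- state$x[i] - q
    state$v[i] <- params$v_rest
    state$refrac_until[i] <- state$t +
      (if (state$is_exc[i]) params$T_ref_exc else params$T_ref_inh)
  }
  state
}

#' Build a stimulus pattern
#'
#' A stimulus pattern is a labeled set of excitatory target units whose
#' membrane potentials are stepped up by `amplitude` mV when the pattern is
#' applied.
#'
#' @param targets integer vector of excitatory unit ids (no duplicates)
#' @param amplitude stimulation amplitude, mV
#' @param id pattern label
#' @return an object of class `stimulus_pattern`
#' @export
stimulus_pattern <- function(targets, amplitude = 30, id = "p1") {
  targets <- as.integer(targets)
  if (length(targets) == 0L) stop("pattern targets must be nonempty")
  if (anyDuplicated(targets)) stop("pattern targets must not repeat")
  structure(list(id = id, targets = targets, amplitude = amplitude),
            class = "stimulus_pattern")
}

#' Apply an external stimulus pulse
#'
#' Adds the pattern amplitude to the membrane potential of every target unit.
#' Spiking is still decided by the stochastic escape-noise rule on the next
#' step; there is no forced deterministic spike.
#'
#' @param state a network state
#' @param pattern a [stimulus_pattern()]
#' @return the updated state
#' @export
apply_external_stimulus <- function(state, pattern) {
  stopifnot(inherits(state, "network_state"),
            inherits(pattern, "stimulus_pattern"))
  tg <- pattern$targets
  if (any(tg < 1L) || any(tg > state$n)) stop("unknown unit id in pattern")
  if (any(!state$is_exc[tg]))
    stop("stimulus patterns may target excitatory units only")
  state$v[tg] <- state$v[tg] + pattern$amplitude
  state
}
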