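#' Neuron and synapse parameters
#'
#' Constructs the parameter set of the escape-noise leaky integrate-and-fire
#' neuron with conductance-based synapses and short-term depression. The
#' defaults are the reference values used throughout the package; they place
#' the model in the regime of a cortical pyramidal neuron (membrane time
#' constant 30 ms, resting rate 0.4 Hz, AMPA/GABA decay 2/4 ms,
#' Tsodyks-Markram depression with U = 0.4 and 150 ms recovery).
#'
#' All potentials are in mV, all times in ms, conductances are dimensionless
#' (normalized by the resting conductance `g_rest = 1`), and `f_rest` is in
#' Hz. `delay_EE` applies to excitatory-to-excitatory synapses, `delay_other`
#' to every other synapse class.
#'
#' @param dt integration timestep (ms)
#' @param tau_m membrane time constant (ms)
#' @param v_rest,v_th resting and threshold potential (mV)
#' @param E_exc,E_inh excitatory and inhibitory reversal potentials (mV)
#' @param g_rest resting conductance (dimensionless, fixed at 1)
#' @param f_rest resting firing rate of an isolated neuron (Hz)
#' @param b escape-noise sharpness (mV)
#' @param tau_AMPA,tau_GABA conductance decay time constants (ms)
#' @param T_ref_exc,T_ref_inh refractory periods (ms)
#' @param U fraction of the presynaptic resource consumed per spike
#' @param tau_rec recovery time constant of the presynaptic resource (ms)
#' @param g_max_exc,g_max_inh maximal synaptic conductances (dimensionless)
#' @param delay_EE,delay_other synaptic delays (ms)
#' @return an object of class `neuron_params` (a validated named list)
#' @export
#' @examples
#' p <- neuron_params()
#' escape_spike_prob(-54, p)
neuron_params <- function(dt = 0.1, tau_m = 30, v_rest = -74, v_th = -54,
                          E_exc = 0, E_inh = -80, g_rest = 1, f_rest = 0.4,
                          b = 4, tau_AMPA = 2, tau_GABA = 4,
                          T_ref_exc = 3, T_ref_inh = 2,
                          U = 0.4, tau_rec = 150,
                          g_max_exc = 4, g_max_inh = 4,
                          delay_EE = 1.5, delay_other = 0.8) {
  p <- list(dt = dt, tau_m = tau_m, v_rest = v_rest, v_th = v_th,
            E_exc = E_exc, E_inh = E_inh, g_rest = g_rest, f_rest = f_rest,
            b = b, tau_AMPA = tau_AMPA, tau_GABA = tau_GABA,
            T_ref_exc = T_ref_exc, T_ref_inh = T_ref_inh,
            U = U, tau_rec = tau_rec,
            g_max_exc = g_max_exc, g_max_inh = g_max_inh,
            delay_EE = delay_EE, delay_other = delay_other)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (dt <= 0) stop("dt must be > 0")
  for (nm in c("tau_m", "tau_AMPA", "tau_GABA", "tau_rec", "b"))
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0")
  if (U <= 0 || U > 1) stop("U must be in (0, 1]")
  if (v_rest >= v_th) stop("v_rest must be below v_th")
  if (T_ref_exc < 0 || T_ref_inh < 0) stop("refractory periods must be >= 0")
  if (delay_EE <= 0 || delay_other <= 0) stop("synaptic delays must be > 0")
  if (f_rest < 0) stop("f_rest must be >= 0")
  structure(p, class = "neuron_params")
}

#' Plasticity (STDP) parameters
#'
#' Parameters of the two spike-timing-dependent plasticity windows: the
#' temporally asymmetric excitatory window (potentiation for post-after-pre,
#' depression scaled by `beta_E` for pre-after-post) and the temporally
#' symmetric difference-of-exponentials inhibitory window whose
#' depression/potentiation balance is set by `beta_I`. Validity requires
#' `tau_I1/tau_I2 < min(1/beta_I, 1)` so that the inhibitory window's
#' normalizing prefactor is positive and the window is potentiating at lag 0.
#'
#' Three named presets select the depression/potentiation balance that drives
#' the developed network to a critical (`"crt"`: beta_E = 1, beta_I = 1.15),
#' subcritical (`"sub"`: beta_E = 1.2, beta_I = 1.2) or supercritical
#' (`"sup"`: beta_E = 1, beta_I = 1) state.
#'
#' @param A_E,A_I learning-rate amplitudes (> 0, dimensionless)
#' @param tau_E excitatory window time constant (ms)
#' @param tau_I1,tau_I2 inhibitory window time constants (ms)
#' @param beta_E,beta_I depression/potentiation balance factors
#' @param preset optional preset name (`"crt"`, `"sub"` or `"sup"`);
#'   overrides `beta_E` and `beta_I`
#' @return an object of class `stdp_params`
#' @export
#' @examples
#' stdp_params(preset = "sub")
stdp_params <- function(A_E = 0.02, A_I = 0.02, tau_E = 20,
                        tau_I1 = 10, tau_I2 = 20,
                        beta_E = 1, beta_I = 1.15, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(stdp_presets))
    beta_E <- stdp_presets[[preset]][["beta_E"]]
    beta_I <- stdp_presets[[preset]][["beta_I"]]
  }
  p <- list(A_E = A_E, A_I = A_I, tau_E = tau_E,
            tau_I1 = tau_I1, tau_I2 = tau_I2,
            beta_E = beta_E, beta_I = beta_I)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (A_E <= 0 || A_I <= 0) stop("A_E and A_I must be > 0")
  if (tau_E <= 0 || tau_I1 <= 0 || tau_I2 <= 0)
    stop("window time constants must be > 0")
  if (tau_I1 / tau_I2 >= min(1 / beta_I, 1))
    stop("invalid inhibitory window: tau_I1/tau_I2 = ",
         format(tau_I1 / tau_I2),
         " must be < min(1/beta_I, 1) = ", format(min(1 / beta_I, 1)))
  structure(p, class = "stdp_params")
}

#' Named STDP presets for the three network regimes
#'
#' `beta_E`/`beta_I` pairs that drive the developed network to the critical,
#' subcritical, and supercritical regimes.
#' @format a named list of `beta_E`/`beta_I` pairs
#' @export
stdp_presets <- list(
  crt = c(beta_E = 1,   beta_I = 1.15),
  sub = c(beta_E = 1.2, beta_I = 1.2),
  sup = c(beta_E = 1,   beta_I = 1)
)

#' @exportS3Method base::print
print.neuron_params <- function(x, ...) {
  cat("escape-noise LIF neuron parameters\n")
  cat(sprintf("  dt = %g ms, tau_m = %g ms, v_rest = %g mV, v_th = %g mV\n",
              x$dt, x$tau_m, x$v_rest, x$v_th))
  cat(sprintf("  f_rest = %g Hz, b = %g mV (escape prefactor dt/tau = %.5g)\n",
              x$f_rest, x$b, escape_prefactor(x)))
  cat(sprintf("  tau_AMPA/GABA = %g/%g ms, U = %g, tau_rec = %g ms\n",
              x$tau_AMPA, x$tau_GABA, x$U, x$tau_rec))
  invisible(x)
}

#' @exportS3Method base::print
print.stdp_params <- function(x, ...) {
  cat("STDP parameters\n")
  cat(sprintf("  excitatory: A_E = %g, tau_E = %g ms, beta_E = %g\n",
              x$A_E, x$tau_E, x$beta_E))
  cat(sprintf("  inhibitory: A_I = %g, tau_I1/I2 = %g/%g ms, beta_I = %g\n",
              x$A_I, x$tau_I1, x$tau_I2, x$beta_I))
  invisible(x)
}
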