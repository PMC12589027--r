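#' Spike train container
#'
#' A spike train is a data frame of `(time_s, unit)` events sorted by time,
#' with the per-unit excitatory/inhibitory flags attached as the `is_exc`
#' attribute (a logical vector indexed by unit id, or `NULL` when unknown).
#'
#' @param time_s event times in seconds
#' @param unit 1-based unit ids
#' @param is_exc optional logical vector of per-unit class flags
#' @return an object of class `spike_train` (also a data frame)
#' @export
spike_train <- function(time_s = numeric(), unit = integer(), is_exc = NULL) {
  if (length(time_s) != length(unit)) stop("time_s and unit lengths differ")
  if (any(time_s < 0)) stop("spike times must be >= 0")
  o <- order(time_s, unit)
  st <- data.frame(time_s = as.numeric(time_s)[o], unit = as.integer(unit)[o])
  attr(st, "is_exc") <- is_exc
  class(st) <- c("spike_train", "data.frame")
  st
}

#' @exportS3Method base::print
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes", nrow(x)))
  if (nrow(x) > 0)
    cat(sprintf(" over [%.4g, %.4g] s, %d active units",
                min(x$time_s), max(x$time_s), length(unique(x$unit))))
  cat("\n")
  invisible(x)
}

#' Build a fully connected network state
#'
#' Creates the mutable simulation state: `n_exc` excitatory followed by
#' `n_inh` inhibitory units, all-to-all connectivity excluding
#' self-connections, every synaptic weight initialized to 0, membrane
#' potentials drawn uniformly between `v_rest` and `v_th` from the state's
#' seeded random stream, full resources (`x = 1`) and empty delayed-event
#' queues. The state carries its own random-stream words so that a
#' checkpointed run continues identically.
#'
#' @param n_exc,n_inh numbers of excitatory and inhibitory units
#' @param params a [neuron_params()] object (stored in the state)
#' @param stdp an [stdp_params()] object (stored in the state)
#' @param seed integer seed for the state's random stream
#' @return an object of class `network_state`
#' @export
#' @examples
#' st <- build_network(8, 2, seed = 1)
#' sum(st$w)  # all weights start at 0
build_network <- function(n_exc = 80, n_inh = 20,
                          params = neuron_params(), stdp = stdp_params(),
                          seed = 1L) {
  stopifnot(n_exc > 0, n_inh > 0)
  n <- n_exc + n_inh
  rng <- cpp_rng_seed(as.double(seed))
  draw <- cpp_rng_uniform(rng, n)
  v0 <- params$v_rest + draw$values * (params$v_th - params$v_rest)
  max_d <- max(as.integer(round(params$delay_EE / params$dt)),
               as.integer(round(params$delay_other / params$dt)))
  state <- list(
    t = 0, n = n,
    is_exc = rep(c(TRUE, FALSE), c(n_exc, n_inh)),
    v = v0,
    g_exc = numeric(n), g_inh = numeric(n),
    x = rep(1, n),
    w = matrix(0, n, n),
    refrac_until = rep(-Inf, n),
    tr_e = numeric(n), tr_i1 = numeric(n), tr_i2 = numeric(n),
    pend_exc = matrix(0, max_d, n), pend_inh = matrix(0, max_d, n),
    rng = draw$state,
    params = params, stdp = stdp)
  class(state) <- "network_state"
  state
}

#' @exportS3Method base::print
print.network_state <- function(x, ...) {
  cat(sprintf("network state: %d units (%d exc / %d inh), t = %.4g s\n",
              x$n, sum(x$is_exc), sum(!x$is_exc), x$t / 1000))
  cat(sprintf("  nonzero weights: %d of %d; mean v = %.2f mV\n",
              sum(x$w > 0), x$n * (x$n - 1L), mean(x$v)))
  invisible(x)
}

# shared wrapper around the compiled stepping loop
run_engine <- function(state, duration_s, stim_times_s = numeric(),
                       stim_targets = list(), stim_amp = 30,
                       plasticity = TRUE, record_spikes = TRUE,
                       record_currents = FALSE, weight_stride_s = 0) {
  stopifnot(inherits(state, "network_state"), duration_s >= 0)
  if (duration_s == 0)
    return(list(state = state,
                spikes = spike_train(is_exc = state$is_exc)))
  stride_steps <- if (weight_stride_s > 0)
    as.integer(round(weight_stride_s * 1000 / state$params$dt)) else 0L
  res <- cpp_run(state, state$params, state$stdp,
                 duration_ms = duration_s * 1000,
                 stim_times_ms = stim_times_s * 1000,
                 stim_targets = stim_targets, stim_amp = stim_amp,
                 plasticity = plasticity, record_spikes = record_spikes,
                 record_currents = record_currents,
                 weight_stride = stride_steps)
  new_state <- res$state
  class(new_state) <- "network_state"
  out <- list(
    state = new_state,
    spikes = spike_train(res$spike_t_ms / 1000, res$spike_unit,
                         is_exc = state$is_exc))
  if (record_currents)
    out$currents <- current_traces(state$params$dt, res$cur_E, res$cur_I)
  if (stride_steps > 0L) {
    out$w_snapshots <- res$w_snapshots
    out$w_snapshot_t_s <- res$w_snapshot_t_ms / 1000
  }
  out
}

#' Run noise-driven spontaneous activity
#'
#' Advances the network for `duration_s` seconds of purely noise-driven
#' dynamics (no external stimulation), with short- and long-term plasticity
#' enabled unless `plasticity = FALSE`. Optionally records per-neuron
#' excitatory and inhibitory synaptic currents at timestep resolution
#' (memory scales as `2 * n * duration/dt`; intended for windows of a few
#' seconds) and periodic weight-matrix snapshots.
#'
#' @param state a network state
#' @param duration_s simulated duration in seconds (>= 0)
#' @param plasticity enable STDP weight updates
#' @param record_currents record synaptic-current traces at dt resolution
#' @param weight_stride_s interval between weight snapshots (0 = none)
#' @return a list with the advanced `state`, the recorded `spikes`
#'   ([spike_train()]), and optionally `currents` and `w_snapshots`
#' @export
run_free <- function(state, duration_s, plasticity = TRUE,
                     record_currents = FALSE, weight_stride_s = 0) {
  run_engine(state, duration_s, plasticity = plasticity,
             record_currents = record_currents,
             weight_stride_s = weight_stride_s)
}

#' Draw disjoint stimulus patterns
#'
#' Samples `n_patterns` mutually disjoint sets of `size` excitatory units
#' (without replacement across patterns) from the network, mirroring
#' spatially separated stimulation electrodes.
#'
#' @param state a network state
#' @param n_patterns number of patterns
#' @param size targets per pattern
#' @param amplitude stimulation amplitude, mV
#' @param seed integer seed for the sampling stream
#' @return a list of [stimulus_pattern()] objects
#' @export
make_patterns <- function(state, n_patterns = 4, size = 6, amplitude = 30,
                          seed = 1L) {
  stopifnot(inherits(state, "network_state"), n_patterns >= 1)
  if (size < 1) stop("pattern size must be >= 1")
  exc <- which(state$is_exc)
  if (n_patterns * size > length(exc))
    stop("not enough excitatory units for ", n_patterns, " x ", size,
         " disjoint patterns")
  u <- cpp_rng_uniform(cpp_rng_seed(as.double(seed)), length(exc))$values
  chosen <- exc[order(u)][seq_len(n_patterns * size)]
  lapply(seq_len(n_patterns), function(k) {
    stimulus_pattern(chosen[((k - 1) * size + 1):(k * size)],
                     amplitude = amplitude, id = paste0("p", k))
  })
}

#' Repetitive stimulation protocol
#'
#' Delivers every pattern exactly `n_per_pattern` times at `rate_hz`, in a
#' seeded random order (a random permutation of the balanced multiset drawn
#' from the state's own random stream), with plasticity enabled. The first
#' stimulus is delivered at the current clock; the run ends one
#' inter-stimulus interval after the last stimulus.
#'
#' @param state a network state
#' @param patterns list of [stimulus_pattern()] (from [make_patterns()])
#' @param n_per_pattern stimuli per pattern
#' @param rate_hz stimulation rate (stimuli per second)
#' @param plasticity enable STDP during stimulation
#' @return a list with the advanced `state`, recorded `spikes`, and the
#'   stimulation `log` (data frame of `time_s`, `pattern`)
#' @export
run_repetitive_stimulation <- function(state, patterns, n_per_pattern = 900,
                                       rate_hz = 1, plasticity = TRUE) {
  stopifnot(inherits(state, "network_state"), length(patterns) >= 1)
  isi <- 1 / rate_hz
  if (isi * 1000 <= max(state$params$delay_EE, state$params$delay_other))
    stop("stimulation interval must exceed the longest synaptic delay")
  m <- length(patterns) * n_per_pattern
  if (m == 0)
    return(list(state = state, spikes = spike_train(is_exc = state$is_exc),
                log = data.frame(time_s = numeric(), pattern = character())))
  seq_ids <- rep(seq_along(patterns), each = n_per_pattern)
  draw <- cpp_rng_uniform(state$rng, m)
  state$rng <- draw$state
  seq_ids <- seq_ids[order(draw$values)]
  times_s <- state$t / 1000 + (seq_len(m) - 1) * isi
  amp <- patterns[[1]]$amplitude
  for (p in patterns) {
    if (any(!state$is_exc[p$targets]))
      stop("stimulus patterns may target excitatory units only")
  }
  res <- run_engine(state, duration_s = m * isi,
                    stim_times_s = times_s,
                    stim_targets = lapply(seq_ids,
                                          function(k) patterns[[k]]$targets),
                    stim_amp = amp, plasticity = plasticity)
  res$log <- data.frame(time_s = times_s,
                        pattern = vapply(patterns, function(p) p$id,
                                         "")[seq_ids])
  res
}

#' Measure evoked responses over repeated seeded trials
#'
#' For every pattern and trial, clones the base state, reseeds its noise
#' stream with a trial-specific seed, lets the clone run freely for
#' `pre_run_s` seconds (so the membrane potentials and conductances at the
#' moment of stimulation differ across trials), applies one stimulus, and
#' records spikes in the `window_s`-second post-stimulus window. Plasticity
#' is frozen for the whole trial so that measurement does not itself
#' consolidate memory; the base state is never mutated.
#'
#' @param state the base network state (unchanged on return)
#' @param patterns list of [stimulus_pattern()]
#' @param n_trials trials per pattern
#' @param pre_run_s free-run duration before the stimulus, seconds
#' @param window_s recorded post-stimulus window, seconds
#' @param seed base seed; trial `k` of pattern `p` uses
#'   `seed + (p - 1) * n_trials + (k - 1)`
#' @return a [trial_set()] with one spike table per trial, times relative to
#'   stimulus onset (ms)
#' @export
measure_evoked_trials <- function(state, patterns, n_trials = 40,
                                  pre_run_s = 10, window_s = 1, seed = 1L) {
  stopifnot(inherits(state, "network_state"), n_trials >= 0)
  trials <- list()
  labels <- character()
  idx <- 0L
  for (p in seq_along(patterns)) {
    for (k in seq_len(n_trials)) {
      idx <- idx + 1L
      st <- state
      st$rng <- cpp_rng_seed(as.double(seed) + (p - 1) * n_trials + (k - 1))
      res <- run_engine(st, duration_s = pre_run_s + window_s,
                        stim_times_s = state$t / 1000 + pre_run_s,
                        stim_targets = list(patterns[[p]]$targets),
                        stim_amp = patterns[[p]]$amplitude,
                        plasticity = FALSE)
      sp <- res$spikes
      onset_s <- state$t / 1000 + pre_run_s
      keep <- sp$time_s >= onset_s & sp$time_s < onset_s + window_s
      trials[[idx]] <- data.frame(
        time_ms = (sp$time_s[keep] - onset_s) * 1000,
        unit = sp$unit[keep])
      labels[idx] <- patterns[[p]]$id
    }
  }
  trial_set(trials, labels, n_units = state$n, window_ms = window_s * 1000)
}

#' Full stimulation-and-recovery experiment
#'
#' Sequences the package's standard protocol on one network: noise-driven
#' development, pre-stimulation evoked measurement, repetitive stimulation,
#' and a spontaneous follow-up with periodic monitoring (spikes for
#' avalanche analysis and a 2-s synaptic-current recording for EI balance at
#' the start of each monitoring window; monitoring windows never overlap the
#' stimulation epoch), then a post-stimulation evoked measurement. The
#' reference protocol is 72 h development, 4 patterns x 900 stimuli at 1 Hz
#' and a 12-h follow-up monitored hourly for 10 min; the defaults here are
#' deliberately desk-scale, and every duration is configurable up to the
#' full protocol.
#'
#' @param n_exc,n_inh network size
#' @param params,stdp model parameters
#' @param develop_s development (free-run) duration, seconds
#' @param n_patterns,pattern_size,amplitude stimulus-pattern geometry
#' @param stimuli_per_pattern,stim_rate_hz repetitive-stimulation protocol
#' @param spontaneous_s spontaneous follow-up duration, seconds
#' @param monitor_every_s,monitor_s monitoring cadence and window, seconds
#' @param n_trials,pre_run_s,window_s evoked-measurement protocol
#' @param seed master seed (network, stimulus order, and trial streams)
#' @return a list with the final `state`, `patterns`, stimulation `log`,
#'   per-monitor recordings (`monitors`: spikes + currents), and the
#'   pre/post [trial_set()]s (`evoked_pre`, `evoked_post`)
#' @export
run_experiment <- function(n_exc = 80, n_inh = 20,
                           params = neuron_params(), stdp = stdp_params(),
                           develop_s = 600,
                           n_patterns = 4, pattern_size = 6, amplitude = 30,
                           stimuli_per_pattern = 25, stim_rate_hz = 1,
                           spontaneous_s = 1800,
                           monitor_every_s = 600, monitor_s = 120,
                           n_trials = 10, pre_run_s = 10, window_s = 1,
                           seed = 1L) {
  state <- build_network(n_exc, n_inh, params, stdp, seed = seed)
  dev <- run_free(state, develop_s)
  state <- dev$state
  patterns <- make_patterns(state, n_patterns, pattern_size,
                            amplitude = amplitude, seed = seed + 1000L)
  evoked_pre <- measure_evoked_trials(state, patterns, n_trials = n_trials,
                                      pre_run_s = pre_run_s,
                                      window_s = window_s,
                                      seed = seed + 2000L)
  stim <- run_repetitive_stimulation(state, patterns,
                                     n_per_pattern = stimuli_per_pattern,
                                     rate_hz = stim_rate_hz)
  state <- stim$state
  monitors <- list()
  elapsed <- 0
  while (elapsed + monitor_s <= spontaneous_s) {
    cur_s <- min(2, monitor_s)
    mon_cur <- run_free(state, cur_s, record_currents = TRUE)
    mon_rest <- run_free(mon_cur$state, monitor_s - cur_s)
    state <- mon_rest$state
    monitors[[length(monitors) + 1L]] <- list(
      t_start_s = (state$t / 1000) - monitor_s,
      spikes = spike_train(
        c(mon_cur$spikes$time_s, mon_rest$spikes$time_s),
        c(mon_cur$spikes$unit, mon_rest$spikes$unit),
        is_exc = state$is_exc),
      currents = mon_cur$currents)
    gap <- min(monitor_every_s - monitor_s, spontaneous_s - elapsed - monitor_s)
    if (gap > 0) state <- run_free(state, gap)$state
    elapsed <- elapsed + monitor_s + max(gap, 0)
  }
  evoked_post <- measure_evoked_trials(state, patterns, n_trials = n_trials,
                                       pre_run_s = pre_run_s,
                                       window_s = window_s,
                                       seed = seed + 3000L)
  list(state = state, patterns = patterns, stim_log = stim$log,
       monitors = monitors, evoked_pre = evoked_pre,
       evoked_post = evoked_post)
}
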