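# Independent oracles used to freeze expected values.

# Brute-force all-to-all STDP: explicit double sum over the full spike
# history, clipping after each event, ties resolved pre-before-post --
# deliberately O(n^2) and independent of the trace implementation.
stdp_brute_force <- function(pre_times, post_times, pre_is_exc, w0 = 0,
                             params = stdp_params()) {
  Fwin <- function(t) {
    if (pre_is_exc) stdp_window_e(t, params) else stdp_window_i(t, params)
  }
  ev <- data.frame(
    t = c(pre_times, post_times),
    side = rep(c("pre", "post"), c(length(pre_times), length(post_times))))
  ev <- ev[order(ev$t, match(ev$side, c("pre", "post"))), , drop = FALSE]
  w <- w0
  for (i in seq_len(nrow(ev))) {
    if (ev$side[i] == "pre") {
      earlier <- post_times[post_times < ev$t[i]]
      dw <- if (length(earlier)) sum(Fwin(earlier - ev$t[i])) else 0
    } else {
      earlier <- pre_times[pre_times < ev$t[i]]
      dw <- if (length(earlier)) sum(Fwin(ev$t[i] - earlier)) else 0
    }
    w <- min(max(w + dw, 0), 1)
  }
  w
}

# exact subthreshold solution of the membrane equation with g_exc=g_inh=0:
# v(t) = v_rest + (v0 - v_rest) * exp(-t/tau_m)
v_closed_form <- function(v0, t_ms, params = neuron_params()) {
  params$v_rest + (v0 - params$v_rest) * exp(-t_ms / params$tau_m)
}

# strip row names so content comparisons ignore subsetting history
unrowname <- function(df) {
  rownames(df) <- NULL
  df
}

trial_spikes_equal <- function(a, b) {
  length(a$trials) == length(b$trials) &&
    all(mapply(function(x, y) {
      isTRUE(all.equal(unrowname(x), unrowname(y)))
    }, a$trials, b$trials))
}
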