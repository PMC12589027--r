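#' STDP window functions
#'
#' `stdp_window_e()` is the temporally asymmetric excitatory window,
#' `A_E * exp(-t/tau_E)` for `t >= 0` (post after pre: potentiation) and
#' `-A_E * beta_E * exp(t/tau_E)` for `t < 0` (pre after post: depression).
#' `stdp_window_i()` is the symmetric inhibitory window
#' `A_I/(1 - r*beta_I) * (exp(-|t|/tau_I1) - r*beta_I*exp(-|t|/tau_I2))`
#' with `r = tau_I1/tau_I2`: potentiating at small lags, depressing at
#' larger lags when `beta_I > r` (a "Mexican-hat" shape).
#'
#' The lag convention is `t = t_post - t_pre` in ms throughout. The
#' coincident case `t = 0` takes the `t >= 0` branch of the excitatory
#' window; the inhibitory window is continuous at 0 and evaluates to `A_I`
#' there for any valid `beta_I`.
#'
#' @param delta_t lag(s) `t_post - t_pre` in ms (finite)
#' @param params an [stdp_params()] object
#' @return weight increment(s), dimensionless
#' @export
#' @examples
#' p <- stdp_params()
#' stdp_window_e(0, p)    # +A_E
#' stdp_window_i(0, p)    # +A_I
stdp_window_e <- function(delta_t, params = stdp_params()) {
  if (any(!is.finite(delta_t))) stop("delta_t must be finite")
  ifelse(delta_t >= 0,
         params$A_E * exp(-delta_t / params$tau_E),
         -params$A_E * params$beta_E * exp(delta_t / params$tau_E))
}

#' @rdname stdp_window_e
#' @export
stdp_window_i <- function(delta_t, params = stdp_params()) {
  if (any(!is.finite(delta_t))) stop("delta_t must be finite")
  r <- params$tau_I1 / params$tau_I2
  params$A_I / (1 - r * params$beta_I) *
    (exp(-abs(delta_t) / params$tau_I1) -
       r * params$beta_I * exp(-abs(delta_t) / params$tau_I2))
}

#' Event-driven STDP weight update for a single synapse
#'
#' Processes a merged, time-ordered sequence of pre- and postsynaptic spike
#' events on one synapse and applies the all-to-all pairing rule: every
#' presynaptic spike adds the summed window value over *all* earlier
#' postsynaptic spikes, and every postsynaptic spike adds the sum over all
#' earlier presynaptic spikes; after each event the weight is clipped to
#' \[0, 1\]. The full-history sums are realized exactly (no truncation, no
#' nearest-neighbour approximation) through exponentially decaying trace
#' accumulators, one per window time constant and side.
#'
#' Events sharing the same timestamp are treated as simultaneous: the strict
#' "earlier than" rule means they do not pair with each other, and the
#' presynaptic update is applied before the postsynaptic one (relevant only
#' when clipping binds). The window is chosen by the presynaptic unit's
#' class: excitatory presynapse uses the asymmetric window, inhibitory the
#' symmetric one, regardless of the postsynaptic class.
#'
#' @param pre_times,post_times spike times of the pre- and postsynaptic unit
#'   (ms); each must be sorted nondecreasing
#' @param pre_is_exc logical: is the presynaptic unit excitatory?
#' @param w0 initial weight in \[0, 1\]
#' @param params an [stdp_params()] object
#' @return a list with the final `w` and a data frame `log` of per-event
#'   weights (columns `time`, `side`, `w`)
#' @export
#' @examples
#' # one causal pair 10 ms apart on an excitatory synapse
#' stdp_update_weight(0, 10, TRUE, w0 = 0)$w  # = 0.02 * exp(-0.5)
stdp_update_weight <- function(pre_times, post_times, pre_is_exc,
                               w0 = 0, params = stdp_params()) {
  stopifnot(is.logical(pre_is_exc), length(pre_is_exc) == 1L)
  if (is.unsorted(pre_times) || is.unsorted(post_times))
    stop("spike events must be in nondecreasing time order")
  if (w0 < 0 || w0 > 1) stop("w0 must be in [0, 1]")

  ev_t <- c(pre_times, post_times)
  ev_side <- rep(c("pre", "post"), c(length(pre_times), length(post_times)))
  # stable order; ties resolved pre-before-post by the factor level order
  o <- order(ev_t, match(ev_side, c("pre", "post")))
  ev_t <- ev_t[o]
  ev_side <- ev_side[o]

  r <- params$tau_I1 / params$tau_I2
  KI <- params$A_I / (1 - r * params$beta_I)

  # trace accumulators: sum of exp(-(now - t_s)/tau) over past spikes
  tr <- list(pre = c(e = 0, i1 = 0, i2 = 0), post = c(e = 0, i1 = 0, i2 = 0))
  t_last <- list(pre = -Inf, post = -Inf)

  decayed <- function(side, tnow) {
    if (!is.finite(t_last[[side]])) return(c(e = 0, i1 = 0, i2 = 0))
    dt <- tnow - t_last[[side]]
    tr[[side]] * exp(-dt / c(params$tau_E, params$tau_I1, params$tau_I2))
  }

  w <- w0
  log_w <- numeric(length(ev_t))
  i <- 1L
  n_ev <- length(ev_t)
  while (i <= n_ev) {
    # group events with identical timestamps: their updates all use the
    # traces as of strictly earlier spikes
    j <- i
    while (j < n_ev && ev_t[j + 1L] == ev_t[i]) j <- j + 1L
    tnow <- ev_t[i]
    pre_tr <- decayed("pre", tnow)
    post_tr <- decayed("post", tnow)
    for (k in i:j) {
      opp <- if (ev_side[k] == "pre") post_tr else pre_tr
      dw <- if (pre_is_exc) {
        if (ev_side[k] == "pre") {
          # earlier post spikes: t_post - t_pre < 0, depression branch
          -params$A_E * params$beta_E * opp[["e"]]
        } else {
          params$A_E * opp[["e"]]
        }
      } else {
        KI * (opp[["i1"]] - r * params$beta_I * opp[["i2"]])
      }
      w <- min(max(w + dw, 0), 1)
      log_w[k] <- w
    }
    # now add the spikes of this timestamp to their traces
    for (side in c("pre", "post")) {
      n_side <- sum(ev_side[i:j] == side)
      if (n_side > 0L) {
        tr[[side]] <- decayed(side, tnow) + n_side
        t_last[[side]] <- tnow
      }
    }
    i <- j + 1L
  }
  list(w = w, log = data.frame(time = ev_t, side = ev_side, w = log_w))
}
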