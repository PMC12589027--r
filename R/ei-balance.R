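#' Synaptic-current traces container
#'
#' Per-neuron excitatory and inhibitory synaptic-current traces sampled at
#' timestep resolution: `E = (E_exc - v) * g_exc` (non-negative in the
#' model's potential range) and `I = (E_inh - v) * g_inh` (non-positive),
#' in conductance-normalized units.
#'
#' @param dt_ms sampling step, ms
#' @param E,I numeric matrices (neurons x samples) of equal dimension
#' @return an object of class `current_traces`
#' @export
current_traces <- function(dt_ms, E, I) {
  E <- as.matrix(E); I <- as.matrix(I)
  if (!all(dim(E) == dim(I))) stop("E and I must have equal dimensions")
  if (any(!is.finite(E)) || any(!is.finite(I)))
    stop("current traces must be finite")
  structure(list(dt_ms = dt_ms, E = E, I = I), class = "current_traces")
}

#' Excitation-inhibition balance metrics
#'
#' Quantifies how tightly excitatory and inhibitory synaptic inputs to the
#' same neuron are coupled in time. For each neuron, the zero-lag Pearson
#' correlation between `E(t)` and the sign-flipped inhibitory trace `-I(t)`
#' is computed over the first `window_s` seconds ("balance" then reads as a
#' positive correlation near 1); `cc` is the mean over neurons whose two
#' traces both have nonzero variance in the window. `mean_E` and `mean_I`
#' are the time-and-neuron averaged input magnitudes (absolute value for the
#' inhibitory side) and `ie_ratio = mean_I / mean_E`.
#'
#' @param traces a [current_traces()] object
#' @param window_s analysis window from the start of the traces, seconds
#' @return an object of class `ei_balance_result`: a list with `cc`,
#'   `mean_E`, `mean_I`, `ie_ratio`, the number of neurons entering the
#'   correlation (`n_cc`), and a logical `flagged` that is `TRUE` when `cc`
#'   or `ie_ratio` is undefined (all-constant traces or zero excitation)
#' @export
#' @examples
#' tr <- correlated_current_pair(0.9, 5000, seed = 1)
#' ei_metrics(tr, window_s = 5000 * tr$dt_ms / 1000)$cc
ei_metrics <- function(traces, window_s = 2) {
  stopifnot(inherits(traces, "current_traces"))
  n_samp <- as.integer(round(window_s * 1000 / traces$dt_ms))
  if (n_samp < 2L || n_samp > ncol(traces$E))
    stop("window does not fit within the traces")
  E <- traces$E[, seq_len(n_samp), drop = FALSE]
  I <- traces$I[, seq_len(n_samp), drop = FALSE]
  ccs <- rep(NA_real_, nrow(E))
  for (i in seq_len(nrow(E))) {
    e <- E[i, ]
    mi <- -I[i, ]
    if (stats::sd(e) > 0 && stats::sd(mi) > 0)
      ccs[i] <- stats::cor(e, mi)
  }
  n_cc <- sum(!is.na(ccs))
  cc <- if (n_cc > 0) mean(ccs, na.rm = TRUE) else NA_real_
  mean_E <- mean(E)
  mean_I <- mean(abs(I))
  ie_ratio <- if (mean_E > 0) mean_I / mean_E else NA_real_
  structure(list(cc = cc, mean_E = mean_E, mean_I = mean_I,
                 ie_ratio = ie_ratio, n_cc = n_cc,
                 per_neuron_cc = ccs,
                 flagged = is.na(cc) || is.na(ie_ratio)),
            class = "ei_balance_result")
}

#' @exportS3Method base::print
print.ei_balance_result <- function(x, ...) {
  cat(sprintf("EI balance: cc = %.3f (over %d neurons)%s\n",
              x$cc, x$n_cc, if (x$flagged) " [flagged: undefined metric]"
              else ""))
  cat(sprintf("  mean |E| = %.4g, mean |I| = %.4g, I/E = %.3f\n",
              x$mean_E, x$mean_I, x$ie_ratio))
  invisible(x)
}
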