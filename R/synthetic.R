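# run code under a temporary R RNG seed, restoring the caller's stream
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Branching-process avalanche train with known sizes
#'
#' Generates Galton-Watson avalanche cascades: each spike produces
#' `Poisson(sigma)` offspring in the next generation, with each generation
#' capped at `n_units` simultaneous spikes and the whole avalanche truncated
#' at `max_size` spikes. The expected avalanche size without truncation is
#' `1/(1 - sigma)`; `sigma < 1` gives subcritical (geometric-tailed)
#' statistics, while `sigma` near 1 in a size-capped system piles excess
#' mass onto large avalanches. Spike times are laid out so that
#' [detect_avalanches()] recovers the generated sizes exactly: spikes within
#' an avalanche are `intra_gap_s` apart and consecutive avalanches are
#' separated by `gap_factor * intra_gap_s`, so every internal gap is below
#' the train's mean inter-spike interval and every separating gap is above
#' it (an all-singleton train decomposes into singletons either way). Times
#' live on an exact dyadic grid (`intra_gap_s` defaults to 2^-10 s, about
#' 1 ms, and `gap_factor` must be an integer) so that consecutive
#' differences and their mean carry no floating-point rounding and the
#' recovery is exact rather than approximate.
#'
#' @param sigma branching ratio (expected offspring per spike, >= 0);
#'   `sigma >= 1` requires a finite `max_size`
#' @param n_avalanches number of cascades to generate
#' @param n_units population size (spikes get random unit ids; also the
#'   per-generation cap)
#' @param gap_factor inter-avalanche gap as an integer multiple (> 1) of the
#'   intra-avalanche spacing
#' @param intra_gap_s spacing of spikes within an avalanche, seconds
#'   (a power of 2 keeps the time grid exact)
#' @param max_size truncation cap on the avalanche size
#' @param seed integer seed
#' @return a list with `spikes` (a [spike_train()]) and the ground-truth
#'   integer `sizes`
#' @export
#' @examples
#' bp <- branching_process_spikes(0.5, n_avalanches = 500, seed = 7)
#' mean(bp$sizes)  # ~ 1 / (1 - 0.5) = 2
branching_process_spikes <- function(sigma, n_avalanches = 1000,
                                     n_units = 100, gap_factor = 50L,
                                     intra_gap_s = 2^-10, max_size = Inf,
                                     seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (gap_factor <= 1 || gap_factor != round(gap_factor))
    stop("gap_factor must be an integer > 1")
  if (sigma >= 1 && !is.finite(max_size))
    stop("sigma >= 1 requires a finite max_size cap")
  sizes <- integer(n_avalanches)
  local_seed(seed, {
    for (k in seq_len(n_avalanches)) {
      size <- 1L
      active <- 1L
      while (active > 0L && size < max_size) {
        offspring <- as.integer(min(sum(stats::rpois(active, sigma)),
                                    n_units, max_size - size))
        size <- size + offspring
        active <- offspring
      }
      sizes[k] <- size
    }
    units <- sample.int(n_units, sum(sizes), replace = TRUE)
  })
  # integer gap units on the dyadic grid: cumsum, diff and the mean interval
  # are all exact, so segmentation reproduces the construction bit for bit
  gaps <- unlist(lapply(sizes, function(s) {
    c(as.integer(gap_factor), rep(1L, s - 1L))
  }))
  gaps[1L] <- 0L
  times_s <- cumsum(as.numeric(gaps)) * intra_gap_s
  list(spikes = spike_train(times_s, units), sizes = sizes)
}

#' Labeled evoked-response set with controllable class separation
#'
#' Emulates stimulus-evoked population responses for decoder testing: each
#' class has a fixed spatial rate pattern (per-unit offsets
#' `separation * N(0,1)`, drawn once per class) that is active during the
#' first `signal_bins` latency bins and absent afterwards, on top of a
#' common base rate; per-trial rate jitter of `noise_sd` Hz is added and
#' spike counts are Poisson. `separation = 0` makes the classes
#' indistinguishable (decoders must fall to chance); separation much larger
#' than the noise drives the Bayes error toward 0. The class signal
#' disappears after `signal_bins * bin_width_ms` ms, so the ground-truth
#' fading-memory decay time is exactly that latency.
#'
#' @param n_classes,n_trials classes and trials per class
#' @param n_units population size
#' @param separation scale of the class-specific rate offsets, Hz
#' @param noise_sd per-trial rate jitter, Hz
#' @param signal_bins number of leading bins carrying the class signal
#' @param bin_width_ms latency bin width, ms
#' @param base_rate_hz class-independent background rate, Hz
#' @param window_ms recorded window, ms
#' @param seed integer seed
#' @return a [trial_set()] with balanced labels
#' @export
labeled_response_set <- function(n_classes = 4, n_trials = 40, n_units = 100,
                                 separation = 5, noise_sd = 0.5,
                                 signal_bins = 5, bin_width_ms = 20,
                                 base_rate_hz = 2, window_ms = 400,
                                 seed = 1L) {
  stopifnot(n_classes > 0, n_trials > 0, n_units > 0)
  n_bins <- as.integer(floor(window_ms / bin_width_ms))
  bin_s <- bin_width_ms / 1000
  trials <- list()
  labels <- character()
  local_seed(seed, {
    pattern <- matrix(stats::rnorm(n_classes * n_units), n_classes, n_units)
    idx <- 0L
    for (cl in seq_len(n_classes)) {
      for (k in seq_len(n_trials)) {
        idx <- idx + 1L
        tms <- numeric()
        uns <- integer()
        for (bn in seq_len(n_bins)) {
          sig <- if (bn <= signal_bins) separation * pattern[cl, ] else 0
          rate <- pmax(base_rate_hz + sig +
                         stats::rnorm(n_units, sd = noise_sd), 0)
          counts <- stats::rpois(n_units, rate * bin_s)
          tot <- sum(counts)
          if (tot > 0L) {
            tms <- c(tms, (bn - 1L) * bin_width_ms +
                       stats::runif(tot) * bin_width_ms)
            uns <- c(uns, rep.int(seq_len(n_units), counts))
          }
        }
        trials[[idx]] <- data.frame(time_ms = tms, unit = uns)
        labels[idx] <- paste0("s", cl)
      }
    }
  })
  trial_set(trials, labels, n_units = n_units, window_ms = window_ms)
}

#' Correlated excitatory/inhibitory current pair
#'
#' Generates one neuron's worth of synthetic current traces whose
#' excitatory trace and sign-flipped inhibitory trace have population
#' correlation exactly `rho`: both are `sqrt(rho) * shared +
#' sqrt(1 - rho) * independent` Gaussian mixtures around a positive offset.
#' Serves as the ground-truth oracle for the [ei_metrics()] estimator.
#'
#' @param rho target correlation in \[0, 1\]
#' @param n_samples number of samples
#' @param dt_ms nominal sampling step, ms
#' @param seed integer seed
#' @return a [current_traces()] object with one row
#' @export
correlated_current_pair <- function(rho, n_samples, dt_ms = 0.1, seed = 1L) {
  if (!is.numeric(rho) || rho < 0 || rho > 1)
    stop("rho must be in [0, 1]")
  local_seed(seed, {
    shared <- stats::rnorm(n_samples)
    e1 <- stats::rnorm(n_samples)
    e2 <- stats::rnorm(n_samples)
  })
  E <- 10 + sqrt(rho) * shared + sqrt(1 - rho) * e1
  negI <- 10 + sqrt(rho) * shared + sqrt(1 - rho) * e2
  current_traces(dt_ms, matrix(E, 1), matrix(-negI, 1))
}

#' MEA-like recording with stimulation artifacts
#'
#' Takes a clean stimulus-aligned [trial_set()] and produces the
#' contaminated recording a microelectrode array would deliver: spurious
#' artifact spikes are injected within `artifact_window_ms` of each stimulus
#' onset (on random units), chosen units are flagged as saturated and given
#' additional spurious spikes, and the matching ground-truth clean set (the
#' template minus anything [preprocess_in_vitro()] would remove) is returned
#' alongside for round-trip testing.
#'
#' @param template a clean [trial_set()]
#' @param n_artifact_spikes artifact spikes injected per trial
#' @param saturated_units integer ids of units to flag as saturated
#' @param artifact_window_ms artifact window after stimulus onset, ms
#' @param seed integer seed
#' @return a list with `noisy` (flagged, contaminated `trial_set`) and
#'   `clean` (the ground truth after perfect preprocessing)
#' @export
mea_like_recording <- function(template, n_artifact_spikes = 3,
                               saturated_units = integer(),
                               artifact_window_ms = 1, seed = 1L) {
  stopifnot(inherits(template, "trial_set"))
  saturated_units <- as.integer(saturated_units)
  n_units <- template$n_units
  clean_trials <- lapply(template$trials, function(tr) {
    keep <- !(tr$time_ms >= 0 & tr$time_ms < artifact_window_ms) &
      !(tr$unit %in% saturated_units)
    tr[keep, , drop = FALSE]
  })
  noisy_trials <- clean_trials
  local_seed(seed, {
    for (i in seq_along(noisy_trials)) {
      add <- data.frame(
        time_ms = stats::runif(n_artifact_spikes, 0, artifact_window_ms),
        unit = sample.int(n_units, n_artifact_spikes, replace = TRUE))
      if (length(saturated_units) > 0L) {
        add <- rbind(add, data.frame(
          time_ms = stats::runif(length(saturated_units), 0,
                                 template$window_ms),
          unit = saturated_units))
      }
      noisy_trials[[i]] <- rbind(noisy_trials[[i]], add)
    }
  })
  sat <- rep(FALSE, n_units)
  sat[saturated_units] <- TRUE
  list(
    noisy = trial_set(noisy_trials, template$labels, n_units,
                      template$window_ms, saturated = sat),
    clean = trial_set(clean_trials, template$labels, n_units,
                      template$window_ms))
}
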