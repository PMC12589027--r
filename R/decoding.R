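#' Labeled evoked-trial container
#'
#' A trial set holds stimulus-aligned evoked responses: one spike table per
#' trial (columns `time_ms`, `unit`, times relative to stimulus onset), a
#' stimulus label per trial, the population size, and per-unit exclusion
#' flags (e.g. electrodes saturated by stimulation).
#'
#' @param trials list of data frames with columns `time_ms` and `unit`
#' @param labels stimulus label per trial (coerced to factor)
#' @param n_units population size
#' @param window_ms length of the recorded post-stimulus window, ms
#' @param saturated logical vector of length `n_units` flagging units to be
#'   dropped by [preprocess_in_vitro()]
#' @return an object of class `trial_set`
#' @export
trial_set <- function(trials, labels, n_units, window_ms,
                      saturated = rep(FALSE, n_units)) {
  if (length(trials) != length(labels))
    stop("one label per trial is required")
  if (length(saturated) != n_units)
    stop("saturated flags must have length n_units")
  for (tr in trials) {
    if (!all(c("time_ms", "unit") %in% names(tr)))
      stop("each trial needs columns time_ms and unit")
    if (nrow(tr) > 0 && (any(tr$unit < 1) || any(tr$unit > n_units)))
      stop("trial references an unknown unit id")
  }
  structure(list(trials = trials, labels = factor(labels),
                 n_units = as.integer(n_units), window_ms = window_ms,
                 saturated = saturated),
            class = "trial_set")
}

#' @exportS3Method base::print
print.trial_set <- function(x, ...) {
  cat(sprintf("trial set: %d trials, %d classes, %d units, %g-ms window\n",
              length(x$trials), nlevels(x$labels), x$n_units, x$window_ms))
  print(table(x$labels))
  invisible(x)
}

#' Stimulation-artifact and saturated-unit preprocessing
#'
#' The cleanup applied to microelectrode-array recordings before decoding:
#' spikes within `artifact_window_ms` after the stimulus (electrical-artifact
#' contamination) are removed from every trial, and units flagged as
#' saturated by stimulation are dropped from all trials (their spikes are
#' deleted and the flag recorded in the `excluded` field, which
#' [bin_rate_vectors()] honours).
#'
#' @param trials a [trial_set()]
#' @param artifact_window_ms exclusion window after stimulus onset, ms
#' @return the cleaned `trial_set`, with `excluded` marking dropped units
#' @export
preprocess_in_vitro <- function(trials, artifact_window_ms = 1) {
  stopifnot(inherits(trials, "trial_set"))
  drop_units <- which(trials$saturated)
  cleaned <- lapply(trials$trials, function(tr) {
    keep <- !(tr$time_ms >= 0 & tr$time_ms < artifact_window_ms) &
      !(tr$unit %in% drop_units)
    tr[keep, , drop = FALSE]
  })
  out <- trial_set(cleaned, trials$labels, trials$n_units, trials$window_ms,
                   saturated = rep(FALSE, trials$n_units))
  out$excluded <- trials$saturated
  out
}

#' Firing-rate feature vectors for one latency bin
#'
#' For each trial and unit, counts spikes in the half-open bin
#' `[latency_ms, latency_ms + bin_width_ms)` and divides by the bin width to
#' obtain a rate in Hz, giving a trials x units feature matrix. Units marked
#' `excluded` (see [preprocess_in_vitro()]) are dropped from the columns.
#'
#' @param trials a [trial_set()]
#' @param bin_width_ms bin width, ms
#' @param latency_ms bin start relative to stimulus onset, ms
#' @return a list with the feature matrix `X` (Hz), the factor `y` of
#'   labels, and `units` (the unit ids of the columns)
#' @export
bin_rate_vectors <- function(trials, bin_width_ms = 20, latency_ms = 0) {
  stopifnot(inherits(trials, "trial_set"))
  if (latency_ms < 0) stop("latency must be >= 0")
  if (latency_ms + bin_width_ms > trials$window_ms)
    stop("bin [", latency_ms, ", ", latency_ms + bin_width_ms,
         ") extends beyond the ", trials$window_ms, "-ms recording window")
  units <- seq_len(trials$n_units)
  if (!is.null(trials$excluded)) units <- units[!trials$excluded]
  if (length(units) == 0L) stop("no units remain after exclusion")
  X <- t(vapply(trials$trials, function(tr) {
    sel <- tr$time_ms >= latency_ms & tr$time_ms < latency_ms + bin_width_ms
    counts <- tabulate(tr$unit[sel], nbins = trials$n_units)
    counts[units] / (bin_width_ms / 1000)
  }, numeric(length(units))))
  list(X = X, y = trials$labels, units = units)
}

# z-score columns by training-fold statistics; constant columns pass through
scale_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sd, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sd, "/"))
}

# Sparse (L1-penalized) multinomial logistic fit + class prediction.
# Degenerate training folds without feature variation fall back to the
# majority class.
slr_predict <- function(Xtr, ytr, Xte, lambda) {
  ytr <- droplevels(factor(ytr))
  if (nlevels(ytr) < 2L)
    stop("decoder needs at least 2 classes in the training data")
  sc <- scale_train_test(Xtr, Xte)
  if (all(apply(sc$train, 2, stats::sd) == 0)) {
    maj <- names(which.max(table(ytr)))
    return(rep(maj, nrow(Xte)))
  }
  # glmnet emits advisory warnings for small per-class counts; leave-one-out
  # folds hit these routinely and they carry no signal here
  fit <- suppressWarnings(
    glmnet::glmnet(sc$train, ytr, family = "multinomial", alpha = 1,
                   nlambda = 30, lambda.min.ratio = 1e-3))
  as.character(stats::predict(fit, sc$test, s = lambda, type = "class"))
}

#' Cross-validated decoding accuracy
#'
#' Mean held-out accuracy of a sparse (L1-penalized) multinomial logistic
#' regression decoder under stratified shuffle cross-validation: `n_splits`
#' independent splits, each holding out a fraction `test_frac` of the trials
#' of every class (at least one per class), the decoder refit on the rest.
#' This is distinct from k-fold cross-validation - the held-out sets of
#' different splits may overlap. Features are z-scored per unit on each
#' training fold.
#'
#' @param X trials x units feature matrix (e.g. from [bin_rate_vectors()])
#' @param y class label per trial
#' @param n_splits number of stratified shuffle splits
#' @param test_frac held-out fraction per class
#' @param lambda L1 regularization strength of the decoder
#' @param seed seed for the split stream
#' @return mean held-out accuracy in \[0, 1\], with the per-split accuracies
#'   in attribute `"per_split"`
#' @export
decode_accuracy <- function(X, y, n_splits = 10, test_frac = 0.1,
                            lambda = 0.01, seed = 1L) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes")
  if (min(table(y)) < 2L) stop("need at least 2 trials per class")
  accs <- numeric(n_splits)
  local_seed(seed, {
    for (s in seq_len(n_splits)) {
      test_idx <- unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(test_frac * length(idx))))
      }))
      pred <- slr_predict(X[-test_idx, , drop = FALSE], y[-test_idx],
                          X[test_idx, , drop = FALSE], lambda)
      accs[s] <- mean(pred == as.character(y[test_idx]))
    }
  })
  structure(mean(accs), per_split = accs)
}

# leave-one-out correct count for one feature matrix
loo_correct <- function(X, y, lambda) {
  y <- factor(y)
  correct <- 0L
  for (i in seq_len(nrow(X))) {
    pred <- slr_predict(X[-i, , drop = FALSE], y[-i],
                        X[i, , drop = FALSE], lambda)
    correct <- correct + as.integer(pred == as.character(y[i]))
  }
  correct
}

#' Fading-memory decay time
#'
#' Scans post-stimulus latency bins from 0 in steps of `bin_width_ms`. For
#' each bin, the leave-one-out cross-validated correct count `k` (out of all
#' `n` trials, classes pooled) is tested against the chance rate
#' `1/n_classes` with a one-sided exact binomial test. The decay time is the
#' start latency of the first bin whose p-value is not below `alpha` - the
#' time at which decodability first falls back to chance. If every bin stays
#' significant the decay time is the end of the scanned window; if the first
#' bin is already at chance it is 0. No smoothing and no multiple-testing
#' correction are applied: the `p < alpha` rule is per bin.
#'
#' @param trials a [trial_set()] with balanced classes
#' @param bin_width_ms bin width, ms
#' @param alpha per-bin significance level
#' @param lambda decoder regularization strength
#' @param max_latency_ms last bin start to scan (defaults to the recording
#'   window)
#' @return an object of class `decoding_result`: a list with the per-bin
#'   table `bins` (columns `latency_ms`, `k_correct`, `n`, `accuracy`,
#'   `p_value`), `decay_time_ms`, and the call parameters
#' @export
decay_time <- function(trials, bin_width_ms = 20, alpha = 0.05,
                       lambda = 0.01, max_latency_ms = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  if (length(unique(table(trials$labels))) != 1L)
    stop("decay_time expects balanced per-class trial counts")
  if (is.null(max_latency_ms)) max_latency_ms <- trials$window_ms
  lats <- seq(0, max_latency_ms - bin_width_ms, by = bin_width_ms)
  n_classes <- nlevels(trials$labels)
  n <- length(trials$trials)
  rows <- lapply(lats, function(lat) {
    fv <- bin_rate_vectors(trials, bin_width_ms, lat)
    k <- loo_correct(fv$X, fv$y, lambda)
    p <- stats::binom.test(k, n, p = 1 / n_classes,
                           alternative = "greater")$p.value
    data.frame(latency_ms = lat, k_correct = k, n = n,
               accuracy = k / n, p_value = p)
  })
  bins <- do.call(rbind, rows)
  first_ns <- which(bins$p_value >= alpha)
  decay <- if (length(first_ns) == 0L) max(lats) + bin_width_ms
           else bins$latency_ms[first_ns[1L]]
  structure(list(bins = bins, decay_time_ms = decay,
                 bin_width_ms = bin_width_ms, alpha = alpha,
                 n_classes = n_classes),
            class = "decoding_result")
}

#' @exportS3Method base::print
print.decoding_result <- function(x, ...) {
  cat(sprintf("fading-memory decoding: %d bins of %g ms, chance = %.3g\n",
              nrow(x$bins), x$bin_width_ms, 1 / x$n_classes))
  cat(sprintf("  decay time = %g ms (first bin with p >= %g)\n",
              x$decay_time_ms, x$alpha))
  invisible(x)
}

#' Compare decoding results between two conditions
#'
#' Paired comparison of decoding across conditions (for instance before
#' versus after repetitive stimulation), over a set of paired replicates
#' (networks or cultures). Per latency bin, a Friedman rank test across the
#' two conditions with replicates as blocks; across replicates, a Wilcoxon
#' signed-rank test on the paired decay times.
#'
#' @param results_a,results_b lists of [decay_time()] results, paired by
#'   position; at least two pairs
#' @param alternative alternative hypothesis for the Wilcoxon test on decay
#'   times (`b - a`): `"two.sided"`, `"greater"` or `"less"`
#' @return a list with `per_bin` (data frame: `latency_ms`, `chisq`,
#'   `p_value`) and `wilcoxon` (list: `statistic`, `p_value`,
#'   `decay_a`, `decay_b`)
#' @export
compare_conditions <- function(results_a, results_b,
                               alternative = "two.sided") {
  if (inherits(results_a, "decoding_result")) results_a <- list(results_a)
  if (inherits(results_b, "decoding_result")) results_b <- list(results_b)
  if (length(results_a) != length(results_b))
    stop("conditions must be paired: lengths differ")
  if (length(results_a) < 2L)
    stop("at least 2 paired replicates are required")
  lats <- results_a[[1L]]$bins$latency_ms
  for (r in c(results_a, results_b)) {
    if (!identical(r$bins$latency_ms, lats))
      stop("mismatched latency bins across paired results")
  }
  acc <- function(rs) t(vapply(rs, function(r) r$bins$accuracy,
                               numeric(length(lats))))
  acc_a <- acc(results_a)
  acc_b <- acc(results_b)
  per_bin <- do.call(rbind, lapply(seq_along(lats), function(j) {
    m <- cbind(a = acc_a[, j], b = acc_b[, j])
    if (all(m[, 1] == m[, 2])) {
      data.frame(latency_ms = lats[j], chisq = 0, p_value = 1)
    } else {
      ft <- stats::friedman.test(m)
      data.frame(latency_ms = lats[j], chisq = unname(ft$statistic),
                 p_value = ft$p.value)
    }
  }))
  da <- vapply(results_a, function(r) r$decay_time_ms, 0)
  db <- vapply(results_b, function(r) r$decay_time_ms, 0)
  if (all(db - da == 0)) {
    wil <- list(statistic = NA_real_, p_value = 1, decay_a = da, decay_b = db)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(db, da, paired = TRUE, alternative = alternative))
    wil <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                decay_a = da, decay_b = db)
  }
  list(per_bin = per_bin, wilcoxon = wil)
}
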