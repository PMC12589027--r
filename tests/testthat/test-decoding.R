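make_toy_trials <- function() {
  trials <- list(
    data.frame(time_ms = c(0.5, 5, 15, 30), unit = c(1L, 1L, 2L, 3L)),
    data.frame(time_ms = c(0.2, 25), unit = c(2L, 1L)),
    data.frame(time_ms = numeric(), unit = integer()),
    data.frame(time_ms = c(3, 19.999, 20), unit = c(1L, 1L, 1L)))
  trial_set(trials, c("a", "b", "a", "b"), n_units = 4, window_ms = 100)
}

test_that("artifact-window and saturated-unit preprocessing", {
  ts <- make_toy_trials()
  clean <- preprocess_in_vitro(ts, artifact_window_ms = 1)
  # spikes at 0.5 and 0.2 ms post-stimulus are artifacts and removed
  expect_equal(nrow(clean$trials[[1]]), 3)
  expect_false(any(clean$trials[[1]]$time_ms < 1))
  expect_equal(nrow(clean$trials[[2]]), 1)
  # window 0 and no flags: identity
  same <- preprocess_in_vitro(ts, artifact_window_ms = 0)
  expect_true(trial_spikes_equal(same, ts))
  # saturated units are dropped from every trial
  ts$saturated[1] <- TRUE
  noflag <- preprocess_in_vitro(ts, artifact_window_ms = 0)
  expect_false(any(unlist(lapply(noflag$trials, `[[`, "unit")) == 1L))
  expect_true(noflag$excluded[1])
  # all units flagged: the population is empty and downstream errors surface
  ts$saturated[] <- TRUE
  allgone <- preprocess_in_vitro(ts)
  expect_error(bin_rate_vectors(allgone, 20, 0), "no units")
})

test_that("rate vectors use half-open bins and Hz units", {
  ts <- make_toy_trials()
  fv <- bin_rate_vectors(ts, bin_width_ms = 20, latency_ms = 0)
  # trial 1: spikes at 0.5, 5, 15 ms from units 1,1,2 -> 2 and 1 spikes
  expect_equal(fv$X[1, ], c(100, 50, 0, 0))
  # empty trial -> zero vector
  expect_equal(fv$X[3, ], rep(0, 4))
  # spike exactly at latency + bin width is excluded (half-open bin):
  # trial 4 has spikes at 3, 19.999, 20 -> only two fall in [0, 20)
  expect_equal(fv$X[4, 1], 100)
  # and it is included in the next bin
  fv2 <- bin_rate_vectors(ts, 20, 20)
  expect_equal(fv2$X[4, 1], 50)
  expect_error(bin_rate_vectors(ts, 20, 90), "beyond")
  expect_error(bin_rate_vectors(ts, 20, -1), "latency")
})

test_that("decoder reaches ceiling on separable classes and chance on noise", {
  ts <- labeled_response_set(4, 40, 100, separation = 30, noise_sd = 0.01,
                             seed = 5)
  fv <- bin_rate_vectors(ts, 20, 0)
  expect_gte(as.numeric(decode_accuracy(fv$X, fv$y, seed = 5)), 0.99)
  # indistinguishable classes: accuracy within the 99% binomial CI of 0.25
  # (n = 10 splits x 16 held-out trials)
  ts0 <- labeled_response_set(4, 40, 100, separation = 0, seed = 3)
  fv0 <- bin_rate_vectors(ts0, 20, 0)
  acc0 <- as.numeric(decode_accuracy(fv0$X, fv0$y, seed = 5))
  margin <- qnorm(0.995) * sqrt(0.25 * 0.75 / 160)
  expect_lt(abs(acc0 - 0.25), margin)
  expect_error(decode_accuracy(fv0$X, rep("a", nrow(fv0$X))), "2 classes")
})

test_that("accuracy is stable under duplication and unit permutation", {
  # duplication invariance is checked at the ceiling regime where the Bayes
  # accuracy pins it down; anywhere below ceiling, shuffle splits leak a
  # held-out sample's duplicated twin into the training fold and the
  # decoder's accuracy genuinely rises
  ts_hi <- labeled_response_set(4, 20, 40, separation = 30, noise_sd = 0.01,
                                seed = 11)
  fv_hi <- bin_rate_vectors(ts_hi, 20, 0)
  base_hi <- as.numeric(decode_accuracy(fv_hi$X, fv_hi$y, seed = 2))
  dup_hi <- as.numeric(decode_accuracy(rbind(fv_hi$X, fv_hi$X),
                                       c(fv_hi$y, fv_hi$y), seed = 2))
  expect_equal(dup_hi, base_hi, tolerance = 0.021)

  # relabeling the units must not change anything the decoder sees
  ts <- labeled_response_set(4, 20, 40, separation = 3, noise_sd = 0.5,
                             seed = 11)
  fv <- bin_rate_vectors(ts, 20, 0)
  base <- as.numeric(decode_accuracy(fv$X, fv$y, seed = 2))
  set.seed(1)
  perm <- sample(ncol(fv$X))
  permuted <- as.numeric(decode_accuracy(fv$X[, perm], fv$y, seed = 2))
  expect_equal(permuted, base, tolerance = 0.021)
})

test_that("leave-one-out binomial p-values match tail enumeration", {
  # oracle: exact binomial tail computed by direct enumeration
  n <- 160
  p0 <- 0.25
  tail_p <- function(k) sum(dbinom(k:n, n, p0))
  ks <- c(40, 45, 50, 52, 60)
  for (k in ks) {
    expect_equal(binom.test(k, n, p0, alternative = "greater")$p.value,
                 tail_p(k), tolerance = 1e-12)
  }
  # the minimal significant correct count at alpha = 0.05
  k_crit <- min(which(vapply(0:n, tail_p, 0) < 0.05)) - 1L
  expect_true(tail_p(k_crit) < 0.05 && tail_p(k_crit - 1L) >= 0.05)
})

test_that("decay time recovers the constructed signal duration", {
  # class signal confined to the first five 20-ms bins -> decay at 100 ms
  ts <- labeled_response_set(4, 10, 50, separation = 8, noise_sd = 0.5,
                             signal_bins = 5, window_ms = 200, seed = 4)
  r <- decay_time(ts, bin_width_ms = 20)
  expect_equal(r$decay_time_ms, 100, tolerance = 20 / 100)
  expect_true(all(r$bins$p_value >= 0 & r$bins$p_value <= 1))
  expect_true(all(r$bins$accuracy >= 0 & r$bins$accuracy <= 1))
  # indistinguishable classes from the start: decay time 0
  ts0 <- labeled_response_set(4, 10, 30, separation = 0, window_ms = 100,
                              seed = 6)
  r0 <- decay_time(ts0, bin_width_ms = 20)
  expect_equal(r0$decay_time_ms, 0)
})

test_that("condition comparison: Wilcoxon on decay times, Friedman per bin", {
  ts <- labeled_response_set(2, 6, 20, separation = 6, noise_sd = 0.3,
                             signal_bins = 2, window_ms = 80, seed = 7)
  r <- decay_time(ts, 20)
  rs <- list(r, r, r, r, r, r)
  same <- compare_conditions(rs, rs)
  expect_equal(same$wilcoxon$p_value, 1)
  expect_true(all(same$per_bin$p_value == 1))
  # positive shift in all pairs: significant one-sided at n = 6; with
  # distinct shifts the exact signed-rank null gives p = 1/2^6
  shift <- mapply(function(x, d) { x$decay_time_ms <- x$decay_time_ms + d; x },
                  rs, c(20, 40, 60, 80, 100, 120), SIMPLIFY = FALSE)
  up <- compare_conditions(rs, shift, alternative = "greater")
  expect_lt(up$wilcoxon$p_value, 0.05)
  expect_equal(up$wilcoxon$p_value, 1 / 2^6, tolerance = 1e-12)
  expect_error(compare_conditions(rs[1], rs[1]), "at least 2")
  expect_error(compare_conditions(rs, rs[1:3]), "paired")
  bad <- r
  bad$bins <- r$bins[-1, ]
  expect_error(compare_conditions(rs, list(r, r, r, r, r, bad)),
               "mismatched")
})
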