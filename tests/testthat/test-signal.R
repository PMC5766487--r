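# signal: band-pass filter, noise estimate, detection, sorting, unit
# rejection

fs <- 20000

test_that("band-pass preserves 1 kHz, rejects 50 Hz and mains-range hum", {
  t <- seq(0, 1, by = 1 / fs)
  s1k <- continuous_signal(sin(2 * pi * 1000 * t), fs)
  out <- bandpass_filter(s1k)
  # discard the filter transient, compare steady-state RMS
  n <- length(t)
  rms <- function(x) sqrt(mean(x^2))
  gain_db <- 20 * log10(rms(out$samples[(n / 2):n]) / rms(s1k$samples[(n / 2):n]))
  expect_lt(abs(gain_db), 1)

  s50 <- continuous_signal(sin(2 * pi * 50 * t), fs)
  out50 <- bandpass_filter(s50)
  att_db <- 20 * log10(rms(out50$samples[(n / 2):n]) / rms(s50$samples[(n / 2):n]))
  expect_lt(att_db, -20)

  z <- bandpass_filter(continuous_signal(numeric(1000) + 0, fs))
  expect_equal(z$samples, numeric(1000))
  expect_error(bandpass_filter(continuous_signal(rnorm(100), 5000)),
               "sampling rate")
})

test_that("band-pass magnitude response meets its design contract", {
  sos <- rbind(dhdecoder:::.design_ellip(4, 300, fs, 0.5, 50, "high"),
               dhdecoder:::.design_ellip(4, 3000, fs, 0.5, 50, "low"))
  h <- function(f) 20 * log10(Mod(sos_freq_response(sos, f, fs)))
  interior <- h(seq(350, 2800, by = 50))
  expect_lt(max(interior) - min(interior), 1)     # <= 1 dB deviation
  expect_lt(max(abs(interior)), 1.05)             # near unit gain
  expect_lt(max(h(seq(10, 100, by = 10))), -50)   # stopband attenuation
  expect_lt(max(h(seq(7000, 9500, by = 500))), -50)
})

test_that("noise SD estimator is calibrated and robust", {
  set.seed(1)
  g <- continuous_signal(rnorm(1e6), fs)
  expect_true(abs(estimate_noise_sd(g) - 1) < 0.01)
  expect_identical(estimate_noise_sd(continuous_signal(numeric(100) + 0, fs)), 0)
  # 1% of samples replaced by +-50 "spikes": estimate barely moves
  x <- g$samples
  idx <- seq(1, 1e6, by = 100)
  x[idx] <- 50 * sign(x[idx])
  est <- estimate_noise_sd(continuous_signal(x, fs))
  expect_gt(est, 0.98); expect_lt(est, 1.05)
})

test_that("detection finds inserted spikes exactly, merges close events", {
  # deterministic sub-threshold floor with known MAD:
  # |sin| has median 1/sqrt(2), so MAD-estimate = 0.707/0.6745 = 1.048
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  floor_sig <- sin(2 * pi * 3100 * t)
  w <- spike_template(fs, amp = 8)
  peak_off <- which.max(abs(w)) - 1L
  true_t <- seq(0.05, 0.95, by = 0.1)
  x <- floor_sig
  for (t0 in true_t) {
    i <- round(t0 * fs) - peak_off + 1L
    x[i:(i + length(w) - 1)] <- x[i:(i + length(w) - 1)] + w
  }
  det <- detect_spikes(continuous_signal(x, fs), mult = 4)
  expect_equal(nrow(det$snippets), length(true_t))
  expect_lt(max(abs(det$peak_times - true_t)), 5e-4)

  # everywhere below threshold -> empty
  det0 <- detect_spikes(continuous_signal(floor_sig, fs), mult = 10)
  expect_equal(nrow(det0$snippets), 0)

  # two templates closer than the dead time -> one detection
  x2 <- floor_sig
  for (t0 in c(0.5, 0.5006)) {
    i <- round(t0 * fs) - peak_off + 1L
    x2[i:(i + length(w) - 1)] <- x2[i:(i + length(w) - 1)] + w
  }
  det2 <- detect_spikes(continuous_signal(x2, fs), mult = 4)
  expect_equal(nrow(det2$snippets), 1)

  expect_error(detect_spikes(continuous_signal(numeric(100) + 0, fs)),
               "threshold")
})

test_that("false-positive rate on pure noise sits under the Gaussian bound", {
  set.seed(42)
  dur <- 10
  g <- continuous_signal(rnorm(dur * fs), fs)
  det <- detect_spikes(g, mult = 4)
  observed_rate <- nrow(det$snippets) / dur
  bound <- fs * 2 * pnorm(-4)          # expected threshold exceedances/s
  expect_lt(observed_rate, 3 * bound)
})

test_that("sorting separates distinct templates and is order-invariant", {
  set.seed(7)
  fs_s <- 20000
  w1 <- spike_template(fs_s, amp = 10)
  w2 <- -0.8 * rev(spike_template(fs_s, amp = 10))
  n_per <- 80
  snips <- rbind(
    t(replicate(n_per, w1 + rnorm(length(w1), 0, 0.5))),
    t(replicate(n_per, w2 + rnorm(length(w2), 0, 0.5))))
  truth <- rep(1:2, each = n_per)
  ss <- snippet_set(snips, seq_len(2 * n_per) / 1000, fs_s)
  sorted <- sort_spikes(ss, max_units = 5)
  expect_equal(length(unique(sorted$labels)), 2)
  agree <- max(mean(sorted$labels == truth), mean(sorted$labels == 3 - truth))
  expect_gte(agree, 0.95)

  # permutation invariance of the induced partition
  perm <- sample(2 * n_per)
  sorted_p <- sort_spikes(snippet_set(snips[perm, ], (seq_len(2 * n_per) / 1000)[perm], fs_s),
                          max_units = 5)
  same_pair <- function(l) outer(l, l, "==")
  expect_identical(same_pair(sorted_p$labels),
                   same_pair(sorted$labels[perm]))

  # identical snippets -> one unit
  same <- snippet_set(matrix(rep(w1, 10), 10, byrow = TRUE),
                      1:10 / 100, fs_s)
  expect_equal(unique(sort_spikes(same)$labels), 1L)
})

test_that("three moderate-noise templates are recovered in most seeds", {
  fs_s <- 20000
  w1 <- spike_template(fs_s, amp = 10)
  w2 <- -0.8 * rev(w1)
  w3 <- c(w1[-(1:6)], numeric(6)) * 0.9 - 0.4 * w2
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    snips <- rbind(t(replicate(50, w1 + rnorm(length(w1), 0, 0.7))),
                   t(replicate(50, w2 + rnorm(length(w2), 0, 0.7))),
                   t(replicate(50, w3 + rnorm(length(w3), 0, 0.7))))
    sorted <- sort_spikes(snippet_set(snips, seq_len(150) / 1000, fs_s),
                          max_units = 5)
    if (length(unique(sorted$labels)) == 3) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_seeds)
})

test_that("low-rate units are rejected, multiunit pool never", {
  trains <- list(
    spike_train(sort(runif(3000, 0, 300)), 0L, 300),     # pool
    spike_train(1.0, 1L, 300),                           # 1 spike / 5 min
    spike_train(sort(runif(3000, 0, 300)), 2L, 300))     # 10 Hz
  kept <- filter_low_rate_units(trains, min_rate = 1 / 30)
  expect_identical(vapply(kept, `[[`, integer(1), "unit_id"), c(0L, 2L))
  expect_identical(filter_low_rate_units(list()), list())
})
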