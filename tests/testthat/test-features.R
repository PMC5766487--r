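# features: FR counting, FIR smoothing, ISI spline, dataset assembly

test_that("compute_fr matches brute-force window counts on random trains", {
  set.seed(10)
  for (i in 1:100) {
    dur <- runif(1, 2, 6)
    n <- rpois(1, 10 * dur)
    st <- spike_train(sort(runif(n, 0, dur)), 1L, dur)
    fr <- compute_fr(st, 0.3, 0.05)
    tt <- dhdecoder:::.feature_times(fr)
    oracle <- vapply(tt, function(t)
      sum(st$times > t - 0.3 & st$times <= t) / 0.3, numeric(1))
    expect_equal(fr$values, oracle)
  }
})

test_that("compute_fr reproduces the worked examples", {
  # spikes every 10 ms: each full 300 ms window holds 30 -> 100 spikes/s
  st <- spike_train(seq(0.01, 5, by = 0.01), 1L, 5)
  fr <- compute_fr(st)
  expect_true(all(abs(fr$values - 100) < 1e-9))

  # one spike at t = 1: windows with t in [1.0, 1.3) are 1/0.3, others 0
  st1 <- spike_train(1.0, 1L, 3)
  fr1 <- compute_fr(st1)
  tt <- dhdecoder:::.feature_times(fr1)
  in_win <- tt >= 1.0 & tt < 1.3
  expect_equal(fr1$values[in_win], rep(1 / 0.3, sum(in_win)))
  expect_equal(fr1$values[!in_win], numeric(sum(!in_win)))

  # empty train -> zeros
  expect_true(all(compute_fr(spike_train(numeric(0), 1L, 2))$values == 0))
  expect_error(compute_fr(spike_train(0.1, 1L, 0.2)), "window")
})

test_that("mean FR over a long Poisson train recovers the true rate", {
  set.seed(3)
  rate <- 15; dur <- 200
  st <- spike_train(sort(runif(rpois(1, rate * dur), 0, dur)), 1L, dur)
  fr <- compute_fr(st)
  # MC sd of the mean of the windowed estimate ~ sqrt(rate/(window*n_eff))
  n_eff <- dur / 0.3
  expect_lt(abs(mean(fr$values) - rate), 3 * sqrt(rate / 0.3 / n_eff))
})

test_that("smooth_fr has unit DC gain, strong Nyquist attenuation, taps impulse", {
  const <- feature_series(rep(40, 200), 20, 0, "fr", 0L)
  sm <- smooth_fr(const)
  expect_lt(max(abs(sm$values - 40)), 0.05)

  h <- dhdecoder:::.design_fir_kaiser(20, 8, 10, 60)
  expect_equal(sum(h), 1)
  hf <- function(f) abs(sum(h * exp(-2i * pi * f / 20 * seq_along(h))))
  expect_lt(20 * log10(hf(10)), -50)     # at the 10 Hz edge (Nyquist)
  expect_gt(20 * log10(hf(1)), -0.1)     # passband

  # impulse in -> delay-compensated taps out
  n <- 101; imp <- numeric(n); imp[51] <- 1
  fs_imp <- feature_series(imp, 20, 0, "fr", 0L)
  out <- smooth_fr(fs_imp, clip_negative = FALSE)
  m <- (length(h) - 1) / 2
  expect_equal(out$values[(51 - m):(51 + m)], h)
  expect_error(smooth_fr(feature_series(rep(1, 10), 20, 0, "fr")), "shorter")
})

test_that("compute_isi interpolates knots exactly and holds outside", {
  # regular 50 ms spiking -> constant 0.050 s
  st <- spike_train(seq(0.05, 3, by = 0.05), 1L, 3)
  isi <- compute_isi(st, 20, span = c(0, 3))
  expect_lt(max(abs(isi$values - 0.05)), 1e-9)

  # irregular intervals: spline passes through every knot
  tt <- cumsum(c(0.1, 0.01, 0.02, 0.03, 0.04))
  st2 <- spike_train(tt, 2L, 1)
  knots_t <- tt[-1]; knots_v <- diff(tt)
  sp <- spline(knots_t, knots_v, xout = knots_t, method = "natural")$y
  expect_lt(max(abs(sp - knots_v)), 1e-9)
  # and the sampled series agrees at grid points coinciding with knots
  isi2 <- compute_isi(st2, 100, span = c(0, 1))
  g <- dhdecoder:::.feature_times(isi2)
  for (k in seq_along(knots_t)) {
    j <- which(abs(g - knots_t[k]) < 1e-9)
    if (length(j)) expect_lt(abs(isi2$values[j] - knots_v[k]), 1e-9)
  }
  # held at nearest knot outside the knot range
  expect_equal(isi2$values[1], knots_v[1])
  expect_equal(isi2$values[length(isi2$values)], knots_v[length(knots_v)])

  expect_error(compute_isi(spike_train(c(0.1, 0.2, 0.3), 3L, 1)), "unit 3")
})

test_that("build_dataset lags, z-scores, and round-trips normalization", {
  set.seed(4)
  kin <- gen_kinematics(30, 2, seed = 2)
  f1 <- feature_series(runif(595, 10, 50), 20, 0.3, "fr", 0L)
  f2 <- feature_series(runif(595, 0.01, 0.2), 20, 0.3, "isi", 0L)
  ds <- build_dataset(list(f1, f2), kin, lag_count = 2)
  expect_equal(nrow(ds$inputs), 593)
  expect_equal(ncol(ds$inputs), 6)
  # lag arithmetic against direct indexing
  raw <- dhdecoder:::.zscore_invert(ds$inputs, ds$norm_in)
  expect_equal(raw[, "fr_u0_lag0"], f1$values[3:595], ignore_attr = TRUE)
  expect_equal(raw[, "fr_u0_lag2"], f1$values[1:593], ignore_attr = TRUE)
  expect_equal(raw[, "isi_u0_lag1"], f2$values[2:594], ignore_attr = TRUE)
  # inverse normalization round-trip
  expect_lt(max(abs(raw[, 1] - f1$values[3:595])), 1e-9)
  # z-scored columns
  expect_lt(max(abs(colMeans(ds$inputs))), 1e-12)
  expect_lt(max(abs(apply(ds$inputs, 2, sd) - 1)), 1e-12)

  # lag 0, single feature -> one z-scored column
  ds0 <- build_dataset(f1, kin, lag_count = 0)
  expect_equal(ncol(ds0$inputs), 1)
  expect_equal(as.numeric(ds0$inputs),
               as.numeric(scale(f1$values)), tolerance = 1e-12)

  # constant feature column dropped with a warning
  fc <- feature_series(rep(5, 595), 20, 0.3, "fr", 1L)
  expect_warning(dsc <- build_dataset(list(f1, fc), kin, lag_count = 0),
                 "zero-variance")
  expect_equal(ncol(dsc$inputs), 1)

  # non-overlapping span rejected
  short_kin <- gen_kinematics(5, 2, seed = 2)
  expect_error(build_dataset(f1, short_kin, 2), "cover")
})

test_that("held-out data reuses training normalization", {
  kin <- gen_kinematics(30, 2, seed = 3)
  set.seed(5)
  f_tr <- feature_series(runif(595, 10, 50), 20, 0.3, "fr", 0L)
  f_te <- feature_series(runif(595, 10, 50), 20, 0.3, "fr", 0L)
  ds_tr <- build_dataset(f_tr, kin, 2)
  ds_te <- build_dataset(f_te, kin, 2, normalization = dataset_normalization(ds_tr))
  expect_identical(ds_te$norm_in, ds_tr$norm_in)
  raw_te <- dhdecoder:::.zscore_invert(ds_te$inputs, ds_tr$norm_in)
  expect_lt(max(abs(raw_te[, 1] - f_te$values[3:595])), 1e-9)
})
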