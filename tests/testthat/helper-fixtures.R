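# Shared fixtures, all generated in code.

# small tuned + untuned two-unit world for selection / tuning tests
two_unit_model <- function() {
  encoding_model(list(
    list(baseline_rate = -95, gain = c(1.2, 0, 0)),            # hip-tuned
    list(baseline_rate = 15, gain = c(0, 0, 0))                # spontaneous
  ))
}

# a decoder_dataset built directly from given input/target matrices,
# bypassing feature extraction (for stack/rnn unit tests)
direct_dataset <- function(inputs, targets_deg, fs = 20) {
  inputs <- as.matrix(inputs)
  targets_deg <- as.matrix(targets_deg)
  colnames(targets_deg) <- c("hip", "knee", "ankle")
  nz_in <- dhdecoder:::.zscore_fit(inputs)
  nz_in$scale[nz_in$scale <= 1e-12] <- 1
  nz_out <- dhdecoder:::.zscore_fit(targets_deg)
  dhdecoder::decoder_dataset(
    dhdecoder:::.zscore_apply(inputs, nz_in),
    dhdecoder:::.zscore_apply(targets_deg, nz_out),
    times = seq_len(nrow(inputs)) / fs, fs = fs, lag_count = 0,
    norm_in = nz_in, norm_out = nz_out,
    meta = list(kinds = "fr", unit_ids = 0L, keep = rep(TRUE, ncol(inputs))))
}

# three smooth quasi-periodic target angle trajectories (degrees)
smooth_targets <- function(n, fs = 20) {
  t <- seq_len(n) / fs
  cbind(hip = 115 + 20 * sin(2 * pi * t / 2),
        knee = 105 + 22 * sin(2 * pi * t / 2 + 0.6),
        ankle = 105 + 30 * sin(2 * pi * t / 2 + 1.1))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
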