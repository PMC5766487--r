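# Feature extraction: sliding-window firing rate (FR), spline-resampled
# interspike-interval series (ISI), and assembly of time-aligned decoder
# datasets with lagged, z-scored inputs.
#
# Both feature streams live on one 20 Hz clock: the FR window hops by 50 ms
# (a 300 ms window with 250 ms overlap) and the ISI spline is sampled at
# 20 Hz, so the stacked decoder can consume them sample-for-sample.

#' Construct a feature series
#'
#' @param values numeric feature values.
#' @param fs sampling rate in Hz (nominal 20).
#' @param t0 time of the first value in seconds.
#' @param kind `"fr"` or `"isi"`.
#' @param unit_id originating unit (0 = multiunit pool).
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, fs, t0, kind = c("fr", "isi"), unit_id = 0L) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("feature values must be finite")
  if (kind == "fr" && any(values < 0)) stop("firing rates must be >= 0")
  if (kind == "isi" && any(values <= 0)) stop("ISI values must be > 0")
  structure(list(values = values, fs = fs, t0 = t0, kind = kind,
                 unit_id = as.integer(unit_id)),
            class = "feature_series")
}

.feature_times <- function(f) f$t0 + (seq_along(f$values) - 1) / f$fs

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s, unit %d: %d samples @ %g Hz from t=%.2f s\n",
              toupper(x$kind), x$unit_id, length(x$values), x$fs, x$t0))
  invisible(x)
}

#' Continuous firing rate by sliding-window counting
#'
#' Counts spikes in a causal window of `window_s` seconds ending at each
#' output time and divides by the window length (spikes/s). The window
#' slides by `hop_s` (300 ms window, 50 ms hop = 250 ms overlap -> a 20 Hz
#' series). Output times run from `window_s` to the train duration.
#'
#' @param train a [spike_train()].
#' @param window_s counting window in seconds.
#' @param hop_s hop between output samples in seconds.
#' @return A `"fr"` [feature_series()] at `1/hop_s` Hz.
#' @export
compute_fr <- function(train, window_s = 0.300, hop_s = 0.050) {
  stopifnot(inherits(train, "spike_train"))
  if (!(window_s > hop_s && hop_s > 0))
    stop("window_s > hop_s > 0 is required")
  if (window_s > train$duration) stop("window longer than the recording")
  n_out <- floor((train$duration - window_s) / hop_s + 1e-9) + 1
  t_out <- window_s + (seq_len(n_out) - 1) * hop_s
  st <- train$times
  # spikes in (t - window, t]: cumulative counts at t minus at t - window;
  # 1 ns tolerance keeps boundary spikes on the intended side of the
  # half-open window when grid times are not exactly representable
  cnt <- findInterval(t_out + 1e-9, st) - findInterval(t_out - window_s + 1e-9, st)
  feature_series(cnt / window_s, fs = 1 / hop_s, t0 = window_s,
                 kind = "fr", unit_id = train$unit_id)
}

#' Low-pass smooth a firing-rate series
#'
#' Linear-phase FIR low-pass (Kaiser design: 60 dB stopband, passband
#' ripple well under 1 dB) with the group delay compensated, so the output
#' stays time-aligned with the input. The 10 Hz cutoff at a 20 Hz series
#' rate is realized as a transition band from `f_pass` to `f_stop` (the
#' stopband edge sits at Nyquist). Small negative filter ringing is clipped
#' to zero by default.
#'
#' @param fr a `"fr"` [feature_series()].
#' @param f_pass,f_stop transition band edges in Hz.
#' @param atten stopband attenuation in dB.
#' @param clip_negative clip negative ringing to 0.
#' @return A smoothed `"fr"` [feature_series()] of the same length.
#' @export
smooth_fr <- function(fr, f_pass = 8, f_stop = 10, atten = 60,
                      clip_negative = TRUE) {
  stopifnot(inherits(fr, "feature_series"))
  if (fr$kind != "fr") stop("smooth_fr expects a firing-rate series")
  h <- .design_fir_kaiser(fr$fs, f_pass, f_stop, atten)
  y <- .fir_filter_centered(h, fr$values)
  if (clip_negative) y <- pmax(y, 0)
  out <- fr
  out$values <- as.numeric(y)
  out
}

#' Interspike-interval series resampled to a uniform rate
#'
#' Consecutive spike times define interval knots `(t_k, t_k - t_{k-1})` for
#' `k >= 2`; a natural cubic spline through the knots is evaluated on a
#' uniform `fs_out` grid over `span`. Outside the knot range the series is
#' held at the nearest knot value (spline extrapolation diverges, and the
#' ISI is conventionally defined across silent gaps).
#'
#' @param train a [spike_train()] with at least 4 spikes.
#' @param fs_out output rate in Hz.
#' @param span `(t_start, t_end)` in seconds; defaults to the full duration.
#' @return An `"isi"` [feature_series()].
#' @export
compute_isi <- function(train, fs_out = 20, span = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) < 4)
    stop(sprintf("unit %d has %d spikes; at least 4 are required for the ISI spline",
                 train$unit_id, length(train$times)))
  if (is.null(span)) span <- c(0, train$duration)
  knots_t <- train$times[-1]
  knots_v <- diff(train$times)
  n_out <- floor((span[2] - span[1]) * fs_out + 1e-9) + 1
  t_out <- span[1] + (seq_len(n_out) - 1) / fs_out
  t_eval <- pmin(pmax(t_out, knots_t[1]), knots_t[length(knots_t)])
  v <- spline(knots_t, knots_v, xout = t_eval, method = "natural")$y
  v <- pmax(v, .Machine$double.eps)      # spline undershoot cannot make ISI <= 0
  feature_series(v, fs = fs_out, t0 = span[1], kind = "isi",
                 unit_id = train$unit_id)
}

#' Construct a decoder dataset
#'
#' @param inputs numeric input matrix (rows = time).
#' @param targets numeric target matrix (rows = time, columns
#'   hip/knee/ankle), stored z-scored.
#' @param times row timestamps in seconds.
#' @param fs feature rate in Hz.
#' @param lag_count number of past samples per feature in the inputs.
#' @param norm_in,norm_out per-column `center`/`scale` normalization applied
#'   to inputs and targets.
#' @param meta feature configuration echo (kinds, window, hop).
#' @return An object of class `decoder_dataset`.
#' @export
decoder_dataset <- function(inputs, targets, times, fs, lag_count,
                            norm_in, norm_out, meta = list()) {
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  if (nrow(inputs) != nrow(targets))
    stop("inputs and targets must have equal row counts")
  if (any(!is.finite(inputs)) || any(!is.finite(targets)))
    stop("dataset contains non-finite entries")
  structure(list(inputs = inputs, targets = targets, times = times, fs = fs,
                 lag_count = lag_count, norm_in = norm_in,
                 norm_out = norm_out, meta = meta),
            class = "decoder_dataset")
}

#' @export
print.decoder_dataset <- function(x, ...) {
  cat(sprintf("<decoder_dataset> %d rows x %d inputs (+%d lags) @ %g Hz\n",
              nrow(x$inputs), ncol(x$inputs), x$lag_count, x$fs))
  invisible(x)
}

.zscore_fit <- function(m) {
  list(center = colMeans(m), scale = apply(m, 2, sd))
}
.zscore_apply <- function(m, nz) {
  sweep(sweep(m, 2, nz$center, "-"), 2, nz$scale, "/")
}
.zscore_invert <- function(m, nz) {
  sweep(sweep(m, 2, nz$scale, "*"), 2, nz$center, "+")
}

# anti-alias and resample kinematics onto arbitrary output times:
# zero-phase 8th-order Butterworth at 0.4 * target rate, then linear
# interpolation of the filtered 100 Hz series
.resample_kin <- function(kin, t_out, fs_out) {
  # the last motion frame covers its full sample interval
  if (min(t_out) < min(kin$times) - 1e-9 ||
      max(t_out) > max(kin$times) + 1 / kin$rate + 1e-9)
    stop("kinematics do not cover the feature time span")
  ang <- .angle_matrix(kin)
  if (fs_out < kin$rate) {
    sos <- .design_butter_low(8, 0.4 * fs_out, kin$rate)
    ang <- apply(ang, 2, function(col) .sosfiltfilt(sos, col))
  }
  apply(ang, 2, function(col) approx(kin$times, col, xout = t_out, rule = 2)$y)
}

#' Assemble a time-aligned decoder dataset
#'
#' Kinematic targets are anti-alias filtered and resampled from the
#' motion-capture rate onto the common feature clock. Inputs are the current
#' plus `lag_count` past samples of every feature series, z-scored per
#' column; rows lacking a complete lag history are dropped. Targets are
#' z-scored as well (normalization recorded and inverted at prediction
#' time). Zero-variance input columns are dropped with a warning. Pass the
#' `normalization` of a training dataset to normalize held-out data with
#' training statistics.
#'
#' @param features list of [feature_series()] sharing `fs` and `t0`.
#' @param kin a [kinematics_series()] covering the feature time span.
#' @param lag_count number of past samples per feature (default 2, matching
#'   the two delay taps of the recurrent decoder).
#' @param normalization optional list with `norm_in`, `norm_out` and `keep`
#'   from a previously built training dataset.
#' @return A [decoder_dataset()].
#' @export
build_dataset <- function(features, kin, lag_count = 2, normalization = NULL) {
  raw <- .assemble_lagged(features, kin, lag_count)
  .finalize_dataset(raw, normalization)
}

# lagged input matrix + degree-scale targets for one trial, no normalization
.assemble_lagged <- function(features, kin, lag_count, time_offset = 0) {
  if (inherits(features, "feature_series")) features <- list(features)
  fs <- unique(vapply(features, `[[`, numeric(1), "fs"))
  t0 <- unique(vapply(features, `[[`, numeric(1), "t0"))
  if (length(fs) != 1 || length(t0) != 1)
    stop("all feature series must share fs and t0")
  nvals <- unique(vapply(features, function(f) length(f$values), integer(1)))
  if (length(nvals) != 1) stop("all feature series must have equal length")
  times <- .feature_times(features[[1]])
  fmat <- do.call(cbind, lapply(features, `[[`, "values"))
  colnames(fmat) <- vapply(features, function(f)
    sprintf("%s_u%d", f$kind, f$unit_id), character(1))

  keep_rows <- (lag_count + 1):nrow(fmat)
  if (length(keep_rows) < 1) stop("dataset too short for the lag history")
  blocks <- lapply(0:lag_count, function(l)
    fmat[keep_rows - l, , drop = FALSE])
  inputs <- do.call(cbind, blocks)
  colnames(inputs) <- unlist(lapply(0:lag_count, function(l)
    paste0(colnames(fmat), "_lag", l)))
  times <- times[keep_rows]

  targets_deg <- .resample_kin(kin, times, fs)
  colnames(targets_deg) <- c("hip", "knee", "ankle")
  list(inputs = inputs, targets_deg = targets_deg, times = times + time_offset,
       fs = fs, lag_count = lag_count,
       kinds = vapply(features, `[[`, character(1), "kind"),
       unit_ids = vapply(features, `[[`, integer(1), "unit_id"))
}

.finalize_dataset <- function(raw, normalization = NULL) {
  inputs <- raw$inputs
  targets_deg <- raw$targets_deg
  if (is.null(normalization)) {
    nz_in <- .zscore_fit(inputs)
    keep <- nz_in$scale > 1e-12
    if (!all(keep)) {
      warning(sprintf("dropping %d zero-variance input column(s): %s",
                      sum(!keep), paste(colnames(inputs)[!keep], collapse = ", ")))
      inputs <- inputs[, keep, drop = FALSE]
      nz_in <- lapply(nz_in, `[`, keep)
    }
    nz_out <- .zscore_fit(targets_deg)
  } else {
    keep <- normalization$keep
    inputs <- inputs[, keep, drop = FALSE]
    nz_in <- normalization$norm_in
    nz_out <- normalization$norm_out
  }
  decoder_dataset(.zscore_apply(inputs, nz_in), .zscore_apply(targets_deg, nz_out),
                  raw$times, raw$fs, raw$lag_count, nz_in, nz_out,
                  meta = list(kinds = raw$kinds, unit_ids = raw$unit_ids,
                              keep = if (is.null(normalization)) keep else normalization$keep))
}

#' Assemble one dataset from several recording trials
#'
#' Per-trial lagged matrices are stacked row-wise (each trial's
#' lag-incomplete head dropped, timestamps offset by the trial start), and
#' the z-scoring statistics are fitted on the combined rows — or taken from
#' `normalization` for held-out trials.
#'
#' @param feature_sets list over trials; each element a [feature_series()]
#'   or list of them.
#' @param kins list of per-trial [kinematics_series()].
#' @param lag_count past samples per feature.
#' @param trial_offsets per-trial time offsets in seconds (defaults to
#'   cumulative trial spans, making row timestamps unique).
#' @param normalization see [build_dataset()].
#' @return A [decoder_dataset()].
#' @export
build_multitrial_dataset <- function(feature_sets, kins, lag_count = 2,
                                     trial_offsets = NULL,
                                     normalization = NULL) {
  n_tr <- length(feature_sets)
  stopifnot(length(kins) == n_tr)
  if (is.null(trial_offsets)) {
    spans <- vapply(kins, function(k) max(k$times) + 1 / k$rate, numeric(1))
    trial_offsets <- cumsum(c(0, spans))[seq_len(n_tr)]
  }
  raws <- lapply(seq_len(n_tr), function(i)
    .assemble_lagged(feature_sets[[i]], kins[[i]], lag_count,
                     time_offset = trial_offsets[i]))
  raw <- list(inputs = do.call(rbind, lapply(raws, `[[`, "inputs")),
              targets_deg = do.call(rbind, lapply(raws, `[[`, "targets_deg")),
              times = unlist(lapply(raws, `[[`, "times")),
              fs = raws[[1]]$fs, lag_count = lag_count,
              kinds = raws[[1]]$kinds, unit_ids = raws[[1]]$unit_ids)
  .finalize_dataset(raw, normalization)
}

#' Normalization bundle of a training dataset
#'
#' @param data a [decoder_dataset()].
#' @return List with `norm_in`, `norm_out`, `keep`, suitable for the
#'   `normalization` argument of [build_dataset()].
#' @export
dataset_normalization <- function(data) {
  stopifnot(inherits(data, "decoder_dataset"))
  list(norm_in = data$norm_in, norm_out = data$norm_out, keep = data$meta$keep)
}

#' Denormalize target-scale predictions back to degrees
#'
#' @param data a [decoder_dataset()] carrying the target normalization.
#' @param pred matrix of normalized predictions.
#' @return Matrix in degrees.
#' @export
denormalize_targets <- function(data, pred) {
  .zscore_invert(pred, data$norm_out)
}
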