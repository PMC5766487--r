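# Raw-trace preprocessing: band-pass filtering, amplitude-threshold spike
# detection, snippet extraction, simplified PCA/k-means sorting, and
# low-rate unit rejection.

#' Construct a continuous signal
#'
#' @param samples numeric sample vector.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, fs, t0 = 0) {
  if (fs <= 0) stop("fs must be positive")
  if (!length(samples)) stop("samples must be non-empty")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "continuous_signal")
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Band-pass filter an extracellular trace (300-3000 Hz)
#'
#' Cascade of a fourth-order elliptic high-pass at `f_lo` and a fourth-order
#' elliptic low-pass at `f_hi` (0.5 dB passband ripple, 50 dB stopband
#' attenuation per stage). Applied causally by default; `zero_phase = TRUE`
#' switches to forward-backward filtering.
#'
#' @param raw a [continuous_signal()].
#' @param f_lo,f_hi band edges in Hz.
#' @param zero_phase apply forward-backward (non-causal) filtering.
#' @return A [continuous_signal()] of the same length and rate.
#' @export
bandpass_filter <- function(raw, f_lo = 300, f_hi = 3000, zero_phase = FALSE) {
  stopifnot(inherits(raw, "continuous_signal"))
  if (raw$fs <= 2 * f_hi) stop("sampling rate too low for the upper band edge")
  sos <- rbind(.design_ellip(4, f_lo, raw$fs, 0.5, 50, "high"),
               .design_ellip(4, f_hi, raw$fs, 0.5, 50, "low"))
  y <- if (zero_phase) .sosfiltfilt(sos, raw$samples) else .sosfilt(sos, raw$samples)
  if (any(!is.finite(y))) stop("non-finite values after filtering")
  continuous_signal(y, raw$fs, raw$t0)
}

#' Robust noise standard deviation of a filtered trace
#'
#' Median-absolute-amplitude estimator `median(|x|) / 0.6745`, robust to the
#' spikes riding on the noise floor (a plain SD is inflated when firing is
#' dense).
#'
#' @param filtered a [continuous_signal()].
#' @return Estimated noise SD (same units as the samples); 0 for an all-zero
#'   signal, which callers must reject as a threshold.
#' @export
estimate_noise_sd <- function(filtered) {
  stopifnot(inherits(filtered, "continuous_signal"))
  median(abs(filtered$samples)) / 0.6745
}

#' Construct a snippet set
#'
#' Aligned spike waveforms extracted around detection peaks.
#'
#' @param snippets numeric matrix, one row per detected event.
#' @param peak_times event peak times in seconds.
#' @param fs sampling rate in Hz.
#' @param labels optional integer unit labels (assigned by [sort_spikes()]).
#' @return An object of class `snippet_set`.
#' @export
snippet_set <- function(snippets, peak_times, fs, labels = NULL) {
  snippets <- as.matrix(snippets)
  if (nrow(snippets) != length(peak_times))
    stop("one peak time is required per snippet")
  if (!is.null(labels) && length(labels) != length(peak_times))
    stop("one label is required per snippet")
  structure(list(snippets = snippets, peak_times = as.numeric(peak_times),
                 fs = fs, labels = labels),
            class = "snippet_set")
}

#' @export
print.snippet_set <- function(x, ...) {
  cat(sprintf("<snippet_set> %d snippets x %d samples%s\n",
              nrow(x$snippets), ncol(x$snippets),
              if (is.null(x$labels)) " (unsorted)"
              else sprintf(", %d units", length(setdiff(unique(x$labels), 0L)))))
  invisible(x)
}

#' Detect spikes by amplitude threshold
#'
#' The detection threshold is `mult` times the robust noise SD
#' ([estimate_noise_sd()]). A spike event is each upward crossing of the
#' absolute signal above the threshold, aligned to the local
#' absolute-amplitude peak within `align_window_ms`; events closer than
#' `dead_time_ms` are merged into one. Snippets are extracted centered on
#' each peak (`pre_ms` before, `post_ms` after); events whose window falls
#' off the trace are dropped.
#'
#' @param filtered a band-pass filtered [continuous_signal()].
#' @param mult threshold multiplier (field convention 4).
#' @param align_window_ms peak-search window after the crossing, ms.
#' @param dead_time_ms minimum separation between events, ms.
#' @param pre_ms,post_ms snippet extent around the peak, ms.
#' @return A [snippet_set()] without labels.
#' @export
detect_spikes <- function(filtered, mult = 4, align_window_ms = 1,
                          dead_time_ms = 1, pre_ms = 0.8, post_ms = 1.6) {
  stopifnot(inherits(filtered, "continuous_signal"), mult > 0)
  x <- filtered$samples
  fs <- filtered$fs
  thr <- mult * estimate_noise_sd(filtered)
  if (thr == 0) stop("zero detection threshold (all-zero signal)")
  ax <- abs(x)
  above <- ax > thr
  cross <- which(above & !c(FALSE, above[-length(above)]))   # upward crossings
  n_align <- max(1L, round(align_window_ms / 1000 * fs))
  n_dead <- round(dead_time_ms / 1000 * fs)
  peaks <- integer(0)
  last <- -Inf
  for (i in cross) {
    if (i - last < n_dead) next
    j1 <- min(i + n_align, length(x))
    pk <- i + which.max(ax[i:j1]) - 1L
    peaks <- c(peaks, pk)
    last <- i
  }
  # merge peaks closer than the dead time (possible when a later crossing
  # aligns to an earlier maximum)
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) >= n_dead)]
  n_pre <- round(pre_ms / 1000 * fs)
  n_post <- round(post_ms / 1000 * fs)
  ok <- peaks - n_pre >= 1 & peaks + n_post <= length(x)
  peaks <- peaks[ok]
  snips <- matrix(0, length(peaks), n_pre + n_post + 1)
  for (k in seq_along(peaks))
    snips[k, ] <- x[(peaks[k] - n_pre):(peaks[k] + n_post)]
  snippet_set(snips, filtered$t0 + (peaks - 1) / fs, fs)
}

# mean silhouette width of a partition, subsampled for large sets
.mean_silhouette <- function(scores, labels, max_n = 2000) {
  if (length(unique(labels)) < 2) return(NA_real_)
  n <- nrow(scores)
  idx <- seq_len(n)
  if (n > max_n) idx <- round(seq(1, n, length.out = max_n))
  sil <- cluster::silhouette(labels[idx], stats::dist(scores[idx, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Sort detected spikes into putative units
#'
#' Simplified sorter standing in for superparamagnetic waveform clustering:
#' snippets are projected on their first principal components and clustered
#' by k-means, with the cluster count chosen over `1..max_units` by the mean
#' silhouette criterion (count 1 is chosen when no multi-cluster partition
#' reaches `min_silhouette`). Labels `1..K` are assigned by decreasing
#' cluster size; label 0 (the multiunit pool) remains the union of all
#' events. Externally sorted labels can be injected via [snippet_set()]
#' directly, bypassing this function.
#'
#' @param snips a [snippet_set()] with at least 2 snippets.
#' @param max_units maximum number of clusters to consider.
#' @param n_pc number of principal components used as features.
#' @param min_silhouette silhouette below which one unit is declared.
#' @return The input with `labels` filled in.
#' @export
sort_spikes <- function(snips, max_units = 5, n_pc = 3, min_silhouette = 0.5) {
  stopifnot(inherits(snips, "snippet_set"))
  n <- nrow(snips$snippets)
  if (n < 2) stop("at least 2 snippets are required for sorting")
  max_units <- min(max_units, n)
  sv <- apply(snips$snippets, 2, var)
  if (all(sv < 1e-24)) {                       # identical snippets
    snips$labels <- rep(1L, n)
    return(snips)
  }
  pc <- prcomp(snips$snippets, center = TRUE, scale. = FALSE)
  k_use <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(k_use), drop = FALSE]
  best_k <- 1L
  best_sil <- -Inf
  best_cl <- rep(1L, n)
  for (k in seq_len(max_units)[-1]) {
    if (k > n - 1) break
    centers <- .deterministic_centers(scores, k)
    if (is.null(centers)) next
    cl <- tryCatch(kmeans(scores, centers = centers, iter.max = 100),
                   error = function(e) NULL)
    if (is.null(cl)) next
    s <- .mean_silhouette(scores, cl$cluster)
    if (is.finite(s) && s > best_sil) {
      best_sil <- s; best_k <- k; best_cl <- cl$cluster
    }
  }
  if (best_k == 1L || best_sil < min_silhouette) {
    snips$labels <- rep(1L, n)
    return(snips)
  }
  # relabel 1..K by decreasing cluster size (ties by cluster mean norm)
  sizes <- table(best_cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- integer(length(sizes))
  remap[as.integer(names(sizes))[ord]] <- seq_along(ord)
  snips$labels <- remap[best_cl]
  snips
}

# order-independent initial centers: Ward hierarchical clustering on a
# deterministic subsample, so sorting is invariant to snippet permutation
.deterministic_centers <- function(scores, k) {
  n <- nrow(scores)
  idx <- seq_len(n)
  if (n > 2000) {
    ord <- order(scores[, 1], scores[, ncol(scores)])
    idx <- ord[round(seq(1, n, length.out = 2000))]
  }
  sub <- scores[idx, , drop = FALSE]
  hc <- stats::hclust(stats::dist(sub), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  if (length(unique(grp)) < k) return(NULL)
  cen <- t(vapply(seq_len(k), function(g)
    colMeans(sub[grp == g, , drop = FALSE]), numeric(ncol(sub))))
  if (anyDuplicated(cen)) return(NULL)
  cen
}

#' Convert sorted snippets to per-unit spike trains
#'
#' @param snips a labeled [snippet_set()].
#' @param duration recording duration in seconds.
#' @return List of [spike_train()]s: the multiunit pool (id 0) followed by
#'   units in label order.
#' @export
snippets_to_trains <- function(snips, duration) {
  stopifnot(inherits(snips, "snippet_set"))
  if (is.null(snips$labels)) stop("snippet set is unsorted; run sort_spikes()")
  ids <- sort(setdiff(unique(snips$labels), 0L))
  out <- list(spike_train(sort(unique(snips$peak_times)), 0L, duration))
  for (id in ids) {
    tt <- sort(snips$peak_times[snips$labels == id])
    out <- c(out, list(spike_train(tt[!duplicated(tt)], id, duration)))
  }
  out
}

#' Drop units firing below a minimum rate
#'
#' A near-silent unit (of the order of one spike per minute) carries no
#' kinematic information and is removed before decoding. The multiunit pool
#' (id 0) is never removed.
#'
#' @param trains list of [spike_train()]s.
#' @param min_rate minimum mean rate in Hz; default keeps units above
#'   2 spikes/min (twice the one-spike-per-minute floor).
#' @return Filtered list of spike trains.
#' @export
filter_low_rate_units <- function(trains, min_rate = 2 / 60) {
  Filter(function(tr) {
    tr$unit_id == 0L || length(tr$times) / tr$duration >= min_rate
  }, trains)
}
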