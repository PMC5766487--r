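# Evaluation: range-normalized RMS error and coefficient of determination
# (both in percent), histogram mutual information, most-informative-unit
# selection, and law-of-cosines joint angles from motion-capture markers.

#' Range-normalized RMS error (percent)
#'
#' `NRMS = 100 / (max(x) - min(x)) * sqrt(mean((x - xhat)^2))` with `x` the
#' measured series and `xhat` the prediction.
#'
#' @param measured,predicted equal-length numeric vectors (length >= 2);
#'   `measured` must not be constant.
#' @return NRMS in percent.
#' @export
compute_nrms <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal lengths")
  if (length(measured) < 2) stop("at least 2 points are required")
  rng <- max(measured) - min(measured)
  if (rng <= 0) stop("measured series is constant (zero range)")
  100 / rng * sqrt(mean((measured - predicted)^2))
}

#' Coefficient of determination (percent)
#'
#' `R^2 = 100 * (1 - sum((x - xhat)^2) / sum((x - mean(x))^2))`. May be
#' negative for predictions worse than the mean.
#'
#' @inheritParams compute_nrms
#' @return R-squared in percent.
#' @export
compute_r2 <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal lengths")
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot <= 0) stop("measured series is constant")
  100 * (1 - sum((measured - predicted)^2) / ss_tot)
}

#' Histogram mutual information (bits)
#'
#' Plug-in estimate from the joint 2-D histogram with equal-frequency
#' (quantile) bin edges per variable; negative rounding artifacts are
#' clipped at zero. Quantile binning is robust to the heavy-tailed ISI
#' distribution.
#'
#' @param a,b equal-length numeric vectors.
#' @param bins number of bins per variable (>= 2).
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(a, b, bins = 16) {
  if (length(a) != length(b)) stop("a and b must have equal lengths")
  if (bins < 2) stop("bins must be >= 2")
  bin_of <- function(x) {
    edges <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(edges) < 3) return(NULL)
    findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  }
  ia <- bin_of(a); ib <- bin_of(b)
  if (is.null(ia) || is.null(ib)) {
    warning("degenerate (near-constant) input; returning MI = 0")
    return(0)
  }
  pj <- table(ia, ib) / length(a)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log2(pj[nz] / outer(pa, pb)[nz]))
  max(mi, 0)
}

#' Resample a feature series onto kinematics, or vice versa
#'
#' Internal helper: evaluates the three joint angles on a feature series'
#' time grid (anti-aliased when downsampling).
#' @noRd
.angles_on_feature_grid <- function(kin, feat) {
  .resample_kin(kin, .feature_times(feat), feat$fs)
}

#' Select the most informative unit
#'
#' Computes the chosen feature (FR or ISI) for every sorted single unit,
#' estimates the mutual information between that feature and each of the
#' three joint angles, ranks units by the mean MI across joints, and
#' returns the best unit id (ties broken by the lower id). The multiunit
#' pool (id 0) does not compete.
#'
#' @param trains list of [spike_train()]s (after low-rate filtering).
#' @param kin a [kinematics_series()] covering the recording.
#' @param feature `"fr"` or `"isi"`.
#' @param bins MI histogram bins.
#' @param window_s,hop_s FR window parameters (see [compute_fr()]).
#' @return The selected unit id (integer).
#' @export
select_most_informative_unit <- function(trains, kin, feature = c("fr", "isi"),
                                         bins = 16, window_s = 0.3, hop_s = 0.05) {
  feature <- match.arg(feature)
  singles <- Filter(function(tr) tr$unit_id != 0L, trains)
  if (!length(singles)) stop("no sorted single units available")
  score <- vapply(singles, function(tr) {
    f <- tryCatch({
      if (feature == "fr") smooth_fr(compute_fr(tr, window_s, hop_s))
      else compute_isi(tr, fs_out = 1 / hop_s,
                       span = c(window_s, tr$duration))
    }, error = function(e) NULL)
    if (is.null(f)) return(-Inf)
    ang <- .angles_on_feature_grid(kin, f)
    mean(vapply(1:3, function(j)
      mutual_information(f$values, ang[, j], bins), numeric(1)))
  }, numeric(1))
  ids <- vapply(singles, `[[`, integer(1), "unit_id")
  best <- which(score == max(score))
  ids[best[which.min(ids[best])]]
}

#' Joint angles from five motion-capture markers
#'
#' Markers overlie the iliac crest, hip (greater trochanter), knee (lateral
#' femoral condyle), ankle (lateral malleolus) and MTP joint. Each joint
#' angle is the included angle at its marker between the two adjacent
#' markers, by the law of cosines
#' `cos(theta) = (a^2 + b^2 - c^2) / (2ab)` with `a`, `b` the adjacent
#' segment lengths and `c` the opposite distance.
#'
#' @param frames data.frame with column `time_s` and 15 coordinate columns
#'   `<marker>_<axis>` for markers `ic, hip, knee, ankle, mtp` and axes
#'   `x, y, z`; or a list with `times` and an `n x 5 x 3` `positions` array.
#' @param rate sampling rate in Hz; inferred from the times if omitted.
#' @return A [kinematics_series()] of hip, knee and ankle angles in degrees.
#' @export
joint_angles_from_markers <- function(frames, rate = NULL) {
  if (is.data.frame(frames)) {
    times <- frames$time_s
    markers <- c("ic", "hip", "knee", "ankle", "mtp")
    pos <- array(0, c(nrow(frames), 5, 3))
    for (i in seq_along(markers)) for (k in 1:3)
      pos[, i, k] <- frames[[paste0(markers[i], "_", c("x", "y", "z")[k])]]
  } else {
    times <- frames$times
    pos <- frames$positions
  }
  if (is.null(rate)) rate <- 1 / median(diff(times))
  seglen <- function(i, j) sqrt(rowSums((pos[, i, , drop = FALSE] -
                                           pos[, j, , drop = FALSE])^2))
  angle_at <- function(v, prev, nxt) {
    a <- seglen(v, prev); b <- seglen(v, nxt); cc <- seglen(prev, nxt)
    if (any(a <= 0) || any(b <= 0))
      stop("coincident adjacent markers (zero segment length)")
    cth <- pmin(pmax((a^2 + b^2 - cc^2) / (2 * a * b), -1), 1)
    acos(cth) * 180 / pi
  }
  kinematics_series(times,
                    hip = angle_at(2, 1, 3),
                    knee = angle_at(3, 2, 4),
                    ankle = angle_at(4, 3, 5),
                    rate = rate)
}

#' Per-joint decoding score report
#'
#' NRMS and R-squared per joint plus their means across joints, mirroring
#' the usual per-animal summary tables.
#'
#' @param measured a [kinematics_series()] or 3-column matrix of measured
#'   angles.
#' @param predicted 3-column matrix (or kinematics series) of predictions,
#'   aligned row-for-row.
#' @return An object of class `score_report`: data.frame rows hip, knee,
#'   ankle, mean with columns `nrms`, `r2`, plus attribute `n_points`.
#' @export
score_report <- function(measured, predicted) {
  m <- if (inherits(measured, "kinematics_series")) .angle_matrix(measured)
       else as.matrix(measured)
  p <- if (inherits(predicted, "kinematics_series")) .angle_matrix(predicted)
       else as.matrix(predicted)
  if (!all(dim(m) == dim(p))) stop("measured and predicted are not aligned")
  nrms <- vapply(1:3, function(j) compute_nrms(m[, j], p[, j]), numeric(1))
  r2 <- vapply(1:3, function(j) compute_r2(m[, j], p[, j]), numeric(1))
  rep_df <- data.frame(joint = c("hip", "knee", "ankle", "mean"),
                       nrms = c(nrms, mean(nrms)),
                       r2 = c(r2, mean(r2)))
  structure(rep_df, class = c("score_report", "data.frame"),
            n_points = nrow(m))
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("Decoding scores (%d points):\n", attr(x, "n_points")))
  df <- as.data.frame(x)
  df$nrms <- sprintf("%.1f%%", df$nrms)
  df$r2 <- sprintf("%.1f%%", df$r2)
  print(df, row.names = FALSE)
  invisible(x)
}
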