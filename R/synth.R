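# Synthetic world: stepping-like limb kinematics, position-tuned spiking
# units, and optional raw extracellular rendering. Every generator is a pure
# function of its arguments including the seed.

#' Construct a kinematics series
#'
#' Time-aligned hip/knee/ankle joint-angle trajectories sampled on a uniform
#' grid.
#'
#' @param times strictly increasing, uniformly spaced times in seconds.
#' @param hip,knee,ankle joint angles in degrees, in `(0, 180]`.
#' @param rate sampling rate in Hz.
#' @return An object of class `kinematics_series`.
#' @export
kinematics_series <- function(times, hip, knee, ankle, rate) {
  n <- length(times)
  if (length(hip) != n || length(knee) != n || length(ankle) != n)
    stop("all three angle arrays must have the same length as `times`")
  if (n > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("`times` must be strictly increasing")
    if (any(abs(dt - 1 / rate) > 1e-9))
      stop("`times` spacing must equal 1/rate within 1e-9 s")
  }
  ang <- c(hip, knee, ankle)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang > 180))
    stop("angles must lie in (0, 180] degrees")
  structure(list(times = times, hip = hip, knee = knee, ankle = ankle,
                 rate = rate),
            class = "kinematics_series")
}

#' @export
print.kinematics_series <- function(x, ...) {
  cat(sprintf("<kinematics_series> %d samples @ %g Hz, %.1f s\n",
              length(x$times), x$rate, diff(range(x$times))))
  invisible(x)
}

.angle_matrix <- function(kin) cbind(hip = kin$hip, knee = kin$knee, ankle = kin$ankle)

#' Construct a spike train
#'
#' @param times spike times in seconds, strictly increasing, within
#'   `[0, duration]`.
#' @param unit_id integer unit label; 0 denotes the pooled multiunit train.
#' @param duration recording duration in seconds.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id, duration) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (length(times) && (min(times) < 0 || max(times) > duration))
    stop("spike times must lie in [0, duration]")
  structure(list(times = times, unit_id = as.integer(unit_id),
                 duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %d: %d spikes over %.1f s (%.2f Hz)\n",
              x$unit_id, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Construct a position-tuned encoding model
#'
#' Describes how each synthetic unit maps joint angles to an instantaneous
#' firing rate: `lambda(t) = g(baseline + sum_j gain_j * angle_j(t))` with
#' `g` a rectified-linear or exponential nonlinearity. For the exponential
#' map, `baseline` and `gain` are in log-rate units.
#'
#' @param units list of unit descriptions; each a list with fields
#'   `baseline_rate` (Hz, may be negative pre-nonlinearity for the relu map),
#'   `gain` (length-3 Hz/degree weights for hip/knee/ankle), optional
#'   `nonlinearity` (`"relu"` or `"exp"`, default relu), optional
#'   `refractory_s` (default 0.0015 s) and optional `waveform_template`
#'   (sample vector used by [gen_raw()]).
#' @return An object of class `encoding_model`.
#' @export
encoding_model <- function(units) {
  units <- lapply(units, function(u) {
    u <- modifyList(list(nonlinearity = "relu", refractory_s = 0.0015,
                         waveform_template = NULL), u)
    if (!u$nonlinearity %in% c("relu", "exp"))
      stop("nonlinearity must be 'relu' or 'exp'")
    if (u$refractory_s < 0) stop("refractory_s must be >= 0")
    if (length(u$gain) != 3) stop("gain must have one weight per joint")
    u
  })
  structure(list(units = units), class = "encoding_model")
}

.unit_rate <- function(u, angles) {
  drive <- u$baseline_rate + as.numeric(angles %*% u$gain)
  lam <- switch(u$nonlinearity,
                relu = pmax(drive, 0),
                exp = exp(drive))
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("internal invariant violation: non-finite or negative rate")
  lam
}

#' Generate stepping-like joint-angle trajectories
#'
#' Each joint follows a smooth quasi-periodic waveform — a fundamental plus
#' one second harmonic of the cycle period, with fixed inter-joint phase
#' offsets — confined to its configured range. `jitter` introduces
#' cycle-to-cycle variability of both the period and the amplitude.
#'
#' @param duration recording duration in seconds.
#' @param cycle_period nominal stepping period in seconds.
#' @param angle_ranges 3x2 matrix of (lo, hi) degrees, rows hip/knee/ankle.
#' @param jitter fractional cycle-to-cycle period/amplitude variability in
#'   `[0, 1)`; 0 gives an exactly periodic trajectory.
#' @param rate sampling rate in Hz (motion-capture clock, default 100).
#' @param phase_offsets per-joint phase offsets in radians.
#' @param harmonic relative amplitude of the second harmonic.
#' @param seed integer RNG seed; output is a pure function of the arguments.
#' @return A [kinematics_series()].
#' @export
gen_kinematics <- function(duration, cycle_period,
                           angle_ranges = rbind(hip = c(95, 140),
                                                knee = c(80, 130),
                                                ankle = c(70, 140)),
                           jitter = 0.05, rate = 100,
                           phase_offsets = c(0, 0.6, 1.1),
                           harmonic = 0.3, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (cycle_period <= 0) stop("cycle_period must be positive")
  angle_ranges <- as.matrix(angle_ranges)
  if (any(angle_ranges[, 1] >= angle_ranges[, 2]))
    stop("each angle range must satisfy lo < hi")
  if (jitter < 0 || jitter >= 1) stop("jitter must lie in [0, 1)")
  n <- round(duration * rate)
  times <- (seq_len(n) - 1) / rate

  # per-cycle period and amplitude factors; jitter = 0 -> exact periodicity
  n_cycles <- ceiling(duration / cycle_period) + 2L
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  per_fac <- 1 + jitter * pmax(pmin(rnorm(n_cycles), 2), -2) / 2
  amp_fac <- 1 - jitter * runif(n_cycles)
  bounds <- cumsum(c(0, cycle_period * per_fac))
  cyc <- findInterval(times, bounds)
  local_phase <- 2 * pi * (times - bounds[cyc]) / (cycle_period * per_fac[cyc])
  phase <- 2 * pi * (cyc - 1) + local_phase

  joints <- vector("list", 3)
  for (j in 1:3) {
    s <- sin(phase + phase_offsets[j]) +
      harmonic * sin(2 * (phase + phase_offsets[j]))
    s <- s / (1 + harmonic)                       # |s| <= 1 -> confinement
    mid <- mean(angle_ranges[j, ])
    half <- diff(angle_ranges[j, ]) / 2
    joints[[j]] <- mid + half * amp_fac[cyc] * s
  }
  kinematics_series(times, joints[[1]], joints[[2]], joints[[3]], rate)
}

# seed bookkeeping so generators do not disturb the caller's RNG stream
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate spike trains from tuned units
#'
#' Spikes are drawn per unit by thinning an inhomogeneous Poisson process
#' whose rate follows the encoding model evaluated on the kinematics
#' (piecewise-linear in time between kinematic samples), then censored by
#' the unit's absolute refractory period. The pooled multiunit train
#' (unit id 0) is the merged superposition of all units.
#'
#' @param kin a [kinematics_series()].
#' @param model an [encoding_model()].
#' @param seed integer RNG seed.
#' @return List of [spike_train()]s: first the multiunit pool (id 0), then
#'   units 1..U in model order.
#' @export
gen_spikes <- function(kin, model, seed = 1L) {
  stopifnot(inherits(kin, "kinematics_series"), inherits(model, "encoding_model"))
  if (!length(kin$times)) stop("kinematics series is empty")
  if (!length(model$units)) stop("encoding model must contain at least one unit")
  duration <- max(kin$times) + 1 / kin$rate
  angles <- .angle_matrix(kin)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  trains <- vector("list", length(model$units))
  for (i in seq_along(model$units)) {
    u <- model$units[[i]]
    lam <- .unit_rate(u, angles)
    lam_max <- max(lam)
    if (lam_max <= 0) {
      trains[[i]] <- spike_train(numeric(0), i, duration)
      next
    }
    # homogeneous candidates at lam_max, thinned by lam(t)/lam_max
    n_cand <- stats::rpois(1, lam_max * duration)
    cand <- sort(runif(n_cand, 0, duration))
    lam_t <- approx(kin$times, lam, xout = cand, rule = 2)$y
    keep <- runif(n_cand) < lam_t / lam_max
    st <- cand[keep]
    if (u$refractory_s > 0 && length(st) > 1) {
      kept <- .refractory_censor(st, u$refractory_s)
      st <- st[kept]
    }
    trains[[i]] <- spike_train(st, i, duration)
  }
  pooled <- sort(unlist(lapply(trains, `[[`, "times")))
  pooled <- pooled[!duplicated(pooled)]           # ties have measure zero
  c(list(spike_train(pooled, 0L, duration)), trains)
}

.refractory_censor <- function(st, refr) {
  keep <- logical(length(st))
  last <- -Inf
  for (k in seq_along(st)) {
    if (st[k] - last >= refr) {
      keep[k] <- TRUE
      last <- st[k]
    }
  }
  keep
}

#' Default extracellular spike waveform template
#'
#' A biphasic (negative-then-positive) damped-sine waveform of about 1.6 ms,
#' peak absolute amplitude `amp`.
#'
#' @param fs sampling rate in Hz.
#' @param amp peak absolute amplitude (volts, or any consistent unit).
#' @param duration_s template support in seconds.
#' @return numeric sample vector.
#' @export
spike_template <- function(fs, amp = 1, duration_s = 0.0016) {
  t <- seq(0, duration_s, by = 1 / fs)
  w <- -sin(2 * pi * t / 0.001) * exp(-t / 0.0005)
  w / max(abs(w)) * amp
}

#' Render a raw extracellular trace from spike trains
#'
#' The trace is the superposition of each unit's waveform template placed
#' with its peak at every spike time, plus white Gaussian noise.
#'
#' @param trains list of [spike_train()]s (the multiunit pool, id 0, is
#'   skipped so spikes are not rendered twice).
#' @param model an [encoding_model()] supplying per-unit
#'   `waveform_template`s; units without one use [spike_template()].
#' @param fs sampling rate in Hz (>= 10 kHz; acquisition nominal 20 kHz).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer RNG seed.
#' @return A [continuous_signal()].
#' @export
gen_raw <- function(trains, model, fs = 20000, noise_sd = 0, seed = 1L) {
  if (fs < 10000) stop("fs must be at least 10 kHz for raw rendering")
  duration <- max(vapply(trains, `[[`, numeric(1), "duration"))
  n <- round(duration * fs)
  x <- numeric(n)
  singles <- Filter(function(tr) tr$unit_id != 0L, trains)
  for (tr in singles) {
    u <- if (tr$unit_id <= length(model$units)) model$units[[tr$unit_id]] else NULL
    w <- if (!is.null(u) && !is.null(u$waveform_template)) u$waveform_template
         else spike_template(fs)
    if (length(w) > n) stop("waveform template longer than the trace")
    peak_off <- which.max(abs(w)) - 1L
    for (t0 in tr$times) {
      i0 <- round(t0 * fs) - peak_off + 1L
      i1 <- i0 + length(w) - 1L
      wi <- w
      if (i0 < 1) { wi <- wi[(2 - i0):length(wi)]; i0 <- 1L }
      if (i1 > n) { wi <- wi[1:(length(wi) - (i1 - n))]; i1 <- n }
      x[i0:i1] <- x[i0:i1] + wi
    }
  }
  if (noise_sd > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
    x <- x + rnorm(n, 0, noise_sd)
  }
  continuous_signal(x, fs, t0 = 0)
}
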