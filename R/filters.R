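# IIR / FIR design primitives.
#
# Nothing here is exposed to the casual user beyond the frequency-response
# helper; the extracellular band-pass (elliptic) and the kinematics
# anti-alias (Butterworth) are built on these. Elliptic design follows the
# classical Landen/Jacobi-function route; filters are realized as cascaded
# biquads (second-order sections) and applied sample-by-sample in C++.

# ---- Jacobi elliptic machinery -------------------------------------------

.landen <- function(k) {
  v <- numeric(0)
  while (k > .Machine$double.eps) {
    k <- (k / (1 + sqrt(1 - k^2)))^2
    v <- c(v, k)
    if (length(v) > 64) break
  }
  v
}

# complete elliptic integral K(k) via the Landen sequence
.ellipK <- function(k) {
  if (k >= 1) return(Inf)
  prod(1 + .landen(k)) * pi / 2
}

# cd(u*K, k) for u normalized to [0, 1] (possibly complex)
.cde <- function(u, k) {
  v <- .landen(k)
  w <- cos(u * pi / 2)
  for (i in rev(seq_along(v))) {
    w <- (1 + v[i]) * w / (1 + v[i] * w^2)
  }
  w
}

# sn(u*K, k), u normalized
.sne <- function(u, k) {
  v <- .landen(k)
  w <- sin(u * pi / 2)
  for (i in rev(seq_along(v))) {
    w <- (1 + v[i]) * w / (1 + v[i] * w^2)
  }
  w
}

.acos_c <- function(z) -1i * log(z + 1i * sqrt(1 - z^2))

# inverse cd, normalized by K; supports complex w
.acde <- function(w, k) {
  v <- .landen(k)
  v_prev <- k
  for (i in seq_along(v)) {
    w <- w / (1 + sqrt(1 - w^2 * v_prev^2)) * 2 / (1 + v[i])
    v_prev <- v[i]
  }
  (2 / pi) * .acos_c(w)
}

.asne <- function(w, k) 1 - .acde(w, k)

# degree equation: selectivity k for order N and discrimination k1
.ellipdeg <- function(N, k1) {
  L <- floor(N / 2)
  ui <- (2 * seq_len(L) - 1) / N
  kc <- sqrt(1 - k1^2)
  kp <- kc^N * (prod(Re(.sne(ui, kc))))^4
  sqrt(1 - kp^2)
}

# ---- analog prototypes (zero/pole/gain, cutoff 1 rad/s) -------------------

# Elliptic low-pass prototype. Even orders only (all we use is N = 4).
.ellip_prototype <- function(N, rp, rs) {
  stopifnot(N %% 2 == 0, rp > 0, rs > rp)
  ep <- sqrt(10^(rp / 10) - 1)
  es <- sqrt(10^(rs / 10) - 1)
  k1 <- ep / es
  k <- .ellipdeg(N, k1)
  L <- N / 2
  ui <- (2 * seq_len(L) - 1) / N
  za <- 1i / (k * Re(.cde(ui, k)))
  v0 <- -1i * .asne(1i / ep, k1) / N
  pa <- 1i * .cde(ui - 1i * v0, k)
  z <- c(za, Conj(za))
  p <- c(pa, Conj(pa))
  # even order: DC sits at the passband-ripple trough
  h0 <- 10^(-rp / 20)
  g <- h0 * Re(prod(-p) / prod(-z))
  list(z = z, p = p, g = g)
}

.butter_prototype <- function(N) {
  kk <- seq_len(N)
  p <- exp(1i * pi * (2 * kk + N - 1) / (2 * N))
  list(z = complex(0), p = p, g = 1)
}

# ---- s-plane transforms + bilinear -> second-order sections ---------------

.zpk_lp2lp <- function(proto, wc) {
  nz <- length(proto$z); np <- length(proto$p)
  list(z = proto$z * wc, p = proto$p * wc, g = proto$g * wc^(np - nz))
}

.zpk_lp2hp <- function(proto, wc) {
  nz <- length(proto$z); np <- length(proto$p)
  g <- proto$g * Re(prod(-proto$z) / prod(-proto$p))
  z <- c(wc / proto$z, rep(0 + 0i, np - nz))
  list(z = z, p = wc / proto$p, g = g)
}

# bilinear transform of an analog zpk (equal-order guaranteed by the
# transforms above after zero padding) into digital zpk at rate fs
.zpk_bilinear <- function(zpk, fs) {
  c2 <- 2 * fs
  zd <- (c2 + zpk$z) / (c2 - zpk$z)
  pd <- (c2 + zpk$p) / (c2 - zpk$p)
  gd <- zpk$g * Re(prod(c2 - zpk$z) / prod(c2 - zpk$p))
  list(z = zd, p = pd, g = gd)
}

# pair conjugate roots into biquads; roots come ordered as (x_1..x_L,
# conj(x_1)..conj(x_L)) or are real
.zpk2sos <- function(zpk) {
  # quadratic factors: each complex-conjugate pair, or two real roots
  quads <- function(r) {
    tol <- 1e-12
    cplx <- r[Im(r) > tol]
    real <- sort(Re(r[abs(Im(r)) <= tol]))
    if (length(real) %% 2 != 0) stop("odd number of real roots")
    out <- lapply(cplx, function(z) c(1, -2 * Re(z), Mod(z)^2))
    if (length(real))
      out <- c(out, lapply(seq(1, length(real), by = 2), function(i)
        c(1, -(real[i] + real[i + 1]), real[i] * real[i + 1])))
    out
  }
  bs <- quads(zpk$z)
  as <- quads(zpk$p)
  stopifnot(length(bs) == length(as))
  n <- length(as)
  sos <- matrix(0, n, 6)
  for (i in seq_len(n)) sos[i, ] <- c(bs[[i]], as[[i]])
  sos[1, 1:3] <- sos[1, 1:3] * zpk$g
  sos
}

# digital elliptic low- or high-pass as SOS; f_edge in Hz, fs in Hz
.design_ellip <- function(N, f_edge, fs, rp, rs, type = c("low", "high")) {
  type <- match.arg(type)
  if (f_edge <= 0 || f_edge >= fs / 2)
    stop("filter edge must lie strictly inside (0, fs/2)")
  wc <- 2 * fs * tan(pi * f_edge / fs)
  proto <- .ellip_prototype(N, rp, rs)
  zpk <- if (type == "low") .zpk_lp2lp(proto, wc) else .zpk_lp2hp(proto, wc)
  .zpk2sos(.zpk_bilinear(zpk, fs))
}

.design_butter_low <- function(N, f_edge, fs) {
  if (f_edge <= 0 || f_edge >= fs / 2)
    stop("filter edge must lie strictly inside (0, fs/2)")
  wc <- 2 * fs * tan(pi * f_edge / fs)
  zpk <- .zpk_bilinear(.zpk_lp2lp(.butter_prototype(N), wc), fs)
  # bilinear leaves N zeros at z = -1 implicit (analog zeros at infinity)
  zpk$z <- rep(-1 + 0i, length(zpk$p))
  # renormalize DC gain to exactly 1
  h1 <- abs(prod(1 - zpk$z) / prod(1 - zpk$p)) * abs(zpk$g)
  zpk$g <- zpk$g / h1
  .zpk2sos(zpk)
}

# complex frequency response of an SOS cascade at frequencies f (Hz)
#' Frequency response of a second-order-section filter cascade
#'
#' @param sos matrix with rows `(b0, b1, b2, a0, a1, a2)`.
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return complex vector of the response at `f`.
#' @keywords internal
sos_freq_response <- function(sos, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    h <- h * (b[1] + b[2] * z1 + b[3] * z1^2) / (a[1] + a[2] * z1 + a[3] * z1^2)
  }
  h
}

.sosfilt <- function(sos, x) sosfilt_cpp(sos, as.numeric(x))

# zero-phase forward-backward SOS filtering with odd-reflection padding
.sosfiltfilt <- function(sos, x) {
  n <- length(x)
  pad <- min(n - 1, 12 * nrow(sos))
  if (pad < 1) stop("signal too short for zero-phase filtering")
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- .sosfilt(sos, xp)
  y <- rev(.sosfilt(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

# ---- FIR (Kaiser) ---------------------------------------------------------

# linear-phase low-pass by Kaiser-windowed sinc; atten in dB governs both
# stopband attenuation and (indirectly) passband ripple
.design_fir_kaiser <- function(fs, f_pass, f_stop, atten = 60) {
  stopifnot(f_stop > f_pass, f_stop <= fs / 2)
  df <- (f_stop - f_pass) / fs
  beta <- if (atten > 50) {
    0.1102 * (atten - 8.7)
  } else if (atten >= 21) {
    0.5842 * (atten - 21)^0.4 + 0.07886 * (atten - 21)
  } else 0
  ntaps <- ceiling((atten - 8) / (2.285 * 2 * pi * df)) + 1
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1          # odd -> integer group delay
  m <- ntaps - 1
  nn <- 0:m
  fc <- (f_pass + f_stop) / 2 / fs                  # normalized cutoff
  arg <- 2 * fc * (nn - m / 2)
  h_ideal <- 2 * fc * ifelse(arg == 0, 1, sin(pi * arg) / (pi * arg))
  w <- besselI(beta * sqrt(pmax(0, 1 - (2 * nn / m - 1)^2)), 0) / besselI(beta, 0)
  h <- h_ideal * w
  h / sum(h)                                        # exact unit DC gain
}

# centered (delay-compensated) FIR application with edge-value padding
.fir_filter_centered <- function(h, x) {
  n <- length(x)
  m <- (length(h) - 1) / 2
  if (n < length(h)) stop("series shorter than the FIR filter length")
  xp <- c(rep(x[1], m), x, rep(x[n], m))
  stats::convolve(xp, rev(h), type = "filter")
}
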