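# eval: NRMS, R2, mutual information, unit selection, marker angles

test_that("NRMS and R2 match a direct-summation oracle and worked cases", {
  nrms_oracle <- function(x, xh) {
    s <- 0
    for (i in seq_along(x)) s <- s + (x[i] - xh[i])^2
    100 / (max(x) - min(x)) * sqrt(s / length(x))
  }
  r2_oracle <- function(x, xh) {
    s1 <- 0; s2 <- 0; m <- mean(x)
    for (i in seq_along(x)) {
      s1 <- s1 + (x[i] - xh[i])^2
      s2 <- s2 + (x[i] - m)^2
    }
    100 * (1 - s1 / s2)
  }
  set.seed(1)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n, 100, 20); xh <- x + rnorm(n, 0, 5)
    expect_equal(compute_nrms(x, xh), nrms_oracle(x, xh), tolerance = 1e-12)
    expect_equal(compute_r2(x, xh), r2_oracle(x, xh), tolerance = 1e-12)
  }
  # worked examples
  expect_identical(compute_nrms(c(0, 10), c(0, 10)), 0)
  expect_equal(compute_nrms(c(0, 10), c(5, 5)), 50)
  expect_equal(compute_r2(c(0, 10), c(5, 5)), 0)
  expect_identical(compute_r2(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(compute_r2(c(1, 2, 3), rep(2, 3)), 0)
  expect_error(compute_nrms(1:3, 1:4), "length")
  expect_error(compute_nrms(c(5, 5), c(1, 2)), "constant")
  # R2 may be negative for worse-than-mean predictions
  expect_lt(compute_r2(c(0, 10), c(20, -20)), 0)
})

test_that("mutual information: identity, independence, Gaussian closed form", {
  set.seed(2)
  a <- runif(1e5)
  expect_equal(mutual_information(a, a, 16), 4, tolerance = 1e-2)
  b <- runif(1e5)
  expect_lt(mutual_information(a, b, 16), 0.02)
  # bivariate Gaussian rho = 0.9: MI = -0.5 * log2(1 - rho^2) bits
  rho <- 0.9
  z1 <- rnorm(1e5); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1e5)
  mi_true <- -0.5 * log2(1 - rho^2)
  expect_lt(abs(mutual_information(z1, z2, 16) - mi_true) / mi_true, 0.1)
  # symmetry is exact (transposed binning)
  expect_identical(mutual_information(z1, z2, 16), mutual_information(z2, z1, 16))
  # shuffled series carries ~no information
  expect_lt(mutual_information(z1, sample(z2), 16), 0.03)
  expect_warning(mi0 <- mutual_information(rep(1, 100), rnorm(100)), "degenerate")
  expect_identical(mi0, 0)
})

test_that("most informative unit: tuned beats spontaneous, ties break low", {
  kin <- gen_kinematics(90, 2, seed = 3)
  sp <- gen_spikes(kin, two_unit_model(), seed = 4)
  expect_identical(select_most_informative_unit(sp, kin, "fr"), 1L)

  # single unit -> that unit
  expect_identical(select_most_informative_unit(sp[c(1, 3)], kin, "fr"), 2L)

  # two identical trains -> lower id
  t1 <- sp[[2]]
  t2 <- t1; t2$unit_id <- 9L
  expect_identical(select_most_informative_unit(list(t1, t2), kin, "fr"), 1L)
  expect_error(select_most_informative_unit(list(sp[[1]]), kin, "fr"), "no sorted")
})

test_that("law-of-cosines marker angles: exact cases and rigid invariance", {
  mk <- function(ic, hip, knee, ankle, mtp) {
    pos <- array(0, c(1, 5, 3))
    pos[1, 1, ] <- ic; pos[1, 2, ] <- hip; pos[1, 3, ] <- knee
    pos[1, 4, ] <- ankle; pos[1, 5, ] <- mtp
    list(times = 0, positions = pos)
  }
  # collinear -> 180 at every joint
  f <- mk(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0))
  k <- joint_angles_from_markers(f, rate = 100)
  expect_equal(c(k$hip, k$knee, k$ankle), rep(180, 3))

  # 3-4-5 right angle at the knee: hip-knee = 3, knee-ankle = 4, hip-ankle = 5
  f2 <- mk(c(-1, 0, 0), c(0, 0, 0), c(3, 0, 0), c(3, 4, 0), c(3, 4, 1))
  expect_equal(joint_angles_from_markers(f2, rate = 100)$knee, 90)

  # segments 2 and 3 with opposite sqrt(7): 60 degrees
  th <- acos((4 + 9 - 7) / 12)
  f3 <- mk(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0),
           c(2 - 3 * cos(th), 3 * sin(th), 0), c(2, 3, 1))
  expect_equal(joint_angles_from_markers(f3, rate = 100)$knee, 60)

  # invariance to rigid rotation + translation
  set.seed(5)
  for (i in 1:10) {
    pos <- array(rnorm(15), c(1, 5, 3))
    fr0 <- list(times = 0, positions = pos)
    k0 <- joint_angles_from_markers(fr0, rate = 100)
    qr_rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    shift <- rnorm(3)
    pos2 <- pos
    for (m in 1:5) pos2[1, m, ] <- as.numeric(qr_rot %*% pos[1, m, ]) + shift
    k1 <- joint_angles_from_markers(list(times = 0, positions = pos2), rate = 100)
    expect_equal(c(k1$hip, k1$knee, k1$ankle), c(k0$hip, k0$knee, k0$ankle),
                 tolerance = 1e-9)
  }
  # coincident adjacent markers rejected
  f4 <- mk(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(joint_angles_from_markers(f4, rate = 100), "coincident")
})

test_that("score_report aggregates per-joint metrics with a mean row", {
  tg <- smooth_targets(200)
  perfect <- score_report(tg, tg)
  expect_equal(perfect$nrms, rep(0, 4))
  expect_equal(perfect$r2, rep(100, 4))

  set.seed(6)
  noisy <- tg + matrix(rnorm(600, 0, 3), 200, 3)
  rep1 <- score_report(tg, noisy)
  expect_equal(rep1$nrms[4], mean(rep1$nrms[1:3]))
  expect_equal(rep1$r2[4], mean(rep1$r2[1:3]))

  # random predictions vs independent targets: mean R2 near or below 0
  rnd <- matrix(rnorm(600, 110, 25), 200, 3)
  expect_lt(score_report(tg, rnd)$r2[4], 10)
})
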