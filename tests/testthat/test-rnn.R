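# rnn: forward recursion, exact Jacobian, Levenberg-Marquardt descent

fd_jacobian <- function(params, X, Y, burn_in = 2, h = 1e-6) {
  v <- params_to_vec(params)
  res_at <- function(vv) {
    out <- rnn_forward(vec_to_params(vv, params), X)$outputs
    rows <- (burn_in + 1):nrow(X)
    as.numeric(t(out[rows, , drop = FALSE] - Y[rows, , drop = FALSE]))
  }
  vapply(seq_along(v), function(i) {
    e <- v; e[i] <- e[i] + h; r1 <- res_at(e)
    e[i] <- e[i] - 2 * h; (r1 - res_at(e)) / (2 * h)
  }, numeric(length(res_at(v))))
}

test_that("forward pass matches hand-unrolled recursion and edge cases", {
  # all weights zero, c = 0 -> outputs zero (hidden saturate at 0.5)
  p0 <- rnn_init(2, 3, 3, seed = 1, weight_init_scale = 0)
  X <- matrix(rnorm(10 * 2), 10, 2)
  fw <- rnn_forward(p0, X)
  expect_equal(fw$outputs, matrix(0, 10, 3), ignore_attr = TRUE)
  expect_equal(unique(as.numeric(fw$y1)), 0.5)

  # q = r = 1, zero weights, c = 1 -> constant 0.5
  p1 <- rnn_init(1, 1, 1, n_out = 1, seed = 1, weight_init_scale = 0)
  p1$c[] <- 1
  expect_equal(as.numeric(rnn_forward(p1, matrix(rnorm(5)))$outputs),
               rep(0.5, 5))

  # hand-set scalar weights, 3-step sequence, independent unroll oracle
  ph <- p1
  ph$w1[] <- 0.5; ph$v1[] <- 0.3; ph$u1[] <- -0.2; ph$b1[] <- 0.1
  ph$w2[] <- 0.7; ph$v2[] <- 0.2; ph$u2[] <- 0.1; ph$b2[] <- -0.3; ph$c[] <- 2
  x <- c(1, -1, 0.5)
  sig <- function(a) 1 / (1 + exp(-a))
  y1p <- c(0, 0); y2p <- c(0, 0); oracle <- numeric(3)
  for (t in 1:3) {
    y1 <- sig(0.5 * x[t] + 0.3 * y1p[1] - 0.2 * y1p[2] + 0.1)
    y2 <- sig(0.7 * y1 + 0.2 * y2p[1] + 0.1 * y2p[2] - 0.3)
    oracle[t] <- 2 * y2
    y1p <- c(y1, y1p[1]); y2p <- c(y2, y2p[1])
  }
  expect_equal(as.numeric(rnn_forward(ph, matrix(x))$outputs), oracle,
               tolerance = 1e-12)

  # determinism, bit for bit
  expect_identical(rnn_forward(ph, matrix(x)), rnn_forward(ph, matrix(x)))
  expect_error(rnn_forward(ph, matrix(rnorm(6), 3, 2)), "expects p=1")
})

test_that("Jacobian matches central finite differences on random draws", {
  set.seed(20)
  for (i in 1:5) {
    p <- rnn_init(sample(1:3, 1), sample(2:3, 1), sample(2:3, 1),
                  seed = 100 + i, weight_init_scale = 1.5)
    Tn <- sample(8:15, 1)
    X <- matrix(rnorm(Tn * p$p), Tn, p$p)
    Y <- matrix(rnorm(Tn * 3), Tn, 3)
    jr <- compute_jacobian(p, X, Y)
    Jfd <- fd_jacobian(p, X, Y)
    expect_lt(max(abs(jr$J - Jfd)) / max(abs(Jfd)), 1e-4)
  }
})

test_that("Jacobian analytic structure: c = 0 gives residuals = -targets", {
  p <- rnn_init(2, 3, 4, seed = 3)
  p$c[] <- 0
  X <- matrix(rnorm(12 * 2), 12, 2)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  jr <- compute_jacobian(p, X, Y, burn_in = 0)
  expect_equal(jr$residuals, as.numeric(t(-Y)))
  # d residual(t, k) / d c_{j,k} = y2_j(t)
  y2 <- rnn_forward(p, X)$y2
  nw <- ncol(jr$J)
  c_cols <- (nw - 4 * 3 + 1):nw           # r*m trailing block
  Jc <- jr$J[, c_cols]
  for (t in 1:12) for (k in 1:3) {
    row <- (t - 1) * 3 + k
    expect_equal(Jc[row, (k - 1) * 4 + 1:4], y2[t, ], ignore_attr = TRUE)
  }
  # zero-length input -> empty residuals and J
  jr0 <- compute_jacobian(p, matrix(0, 0, 2), matrix(0, 0, 3))
  expect_length(jr0$residuals, 0)
  expect_equal(dim(jr0$J), c(0L, nw))
})

test_that("LM training descends monotonically and fits a constant", {
  set.seed(30)
  Tn <- 120
  X <- matrix(rnorm(Tn * 2), Tn, 2)
  Yc <- matrix(rep(c(0.3, -0.2, 0.8), each = Tn), Tn, 3)
  fit <- lm_train(NULL, list(inputs = X, targets = Yc),
                  train_config(max_epochs = 30, val_fraction = 0, seed = 2),
                  q = 3, r = 3)
  expect_true(all(diff(fit$history$sse_train) < 0))   # accepted-step descent
  expect_lt(tail(fit$history$sse_train, 1), 1e-6 * fit$sse0 + 1e-8)

  # determinism end to end
  fit2 <- lm_train(NULL, list(inputs = X, targets = Yc),
                   train_config(max_epochs = 30, val_fraction = 0, seed = 2),
                   q = 3, r = 3)
  expect_identical(params_to_vec(fit$params), params_to_vec(fit2$params))
})

test_that("teacher-student: the network recovers a teacher's map", {
  # noise-free data from a random q = r = 2 teacher; held-out NMSE < 1%.
  # Best-of-3 random starts per seed: standard practice for small LM
  # networks, which otherwise occasionally park in a local minimum.
  ok <- 0
  for (s in 1:5) {
    teacher <- rnn_init(2, 2, 2, seed = 200 + s, weight_init_scale = 2)
    teacher$c <- teacher$c * 4
    set.seed(1000 + s)
    Tn <- 300
    X <- matrix(rnorm(Tn * 2), Tn, 2)
    Y <- rnn_forward(teacher, X)$outputs
    n_tr <- 200
    best <- NULL; best_sse <- Inf
    for (k in 0:2) {
      fit <- lm_train(NULL, list(inputs = X[1:n_tr, ], targets = Y[1:n_tr, ]),
                      train_config(max_epochs = 150, val_fraction = 0,
                                   seed = s + 100L * k),
                      q = 2, r = 2)
      sse <- tail(fit$history$sse_train, 1)
      if (sse < best_sse) { best_sse <- sse; best <- fit }
    }
    # accepted-step SSE descends by orders of magnitude on noise-free data
    expect_lt(best_sse, 1e-3 * best$sse0)
    pred <- rnn_forward(best$params, X)$outputs
    ho <- (n_tr + 1):Tn
    nmse <- mean((pred[ho, ] - Y[ho, ])^2) /
      mean(sweep(Y[ho, ], 2, colMeans(Y[ho, ]))^2)
    if (nmse < 0.01) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("params vector round-trip and init scaling", {
  p <- rnn_init(3, 4, 5, seed = 9, weight_init_scale = 0.7)
  v <- params_to_vec(p)
  expect_identical(params_to_vec(vec_to_params(v, p)), v)
  expect_lte(max(abs(p$w1)), 0.7 / sqrt(3))
  expect_lte(max(abs(p$v1)), 0.7 / sqrt(4))
  expect_true(all(p$b1 == 0))
})
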