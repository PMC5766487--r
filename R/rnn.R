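# Recurrent multilayer perceptron with two sigmoid hidden layers, each with
# one- and two-step delayed self-feedback, and a linear 3-output readout:
#
#   y1(t) = f( W1' x(t) + V1' y1(t-1) + U1' y1(t-2) + b1 )
#   y2(t) = f( W2' y1(t) + V2' y2(t-1) + U2' y2(t-2) + b2 )
#   (hip, knee, ankle)(t) = C' y2(t)
#
# f is the logistic sigmoid; hidden states before the sequence start are
# zero, and the first `burn_in` samples are excluded from the loss to wash
# out the transient. Trained by Levenberg-Marquardt with the exact Jacobian
# propagated through the recurrence.

#' Construct or initialize RNN parameters
#'
#' Weights are drawn uniformly in `[-s, s]` with `s =
#' weight_init_scale / sqrt(fan_in)` per matrix; biases start at zero.
#'
#' @param p input dimension.
#' @param q,r first and second hidden-layer sizes.
#' @param n_out number of linear outputs (3 joint angles).
#' @param seed integer RNG seed for the draw.
#' @param weight_init_scale scale multiplier for the init range.
#' @return An object of class `rnn_params`.
#' @export
rnn_init <- function(p, q = 8, r = 8, n_out = 3, seed = 1L,
                     weight_init_scale = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  dr <- function(nr, nc, fan) {
    matrix(runif(nr * nc, -1, 1) * weight_init_scale / sqrt(fan), nr, nc)
  }
  structure(list(p = as.integer(p), q = as.integer(q), r = as.integer(r),
                 n_out = as.integer(n_out),
                 w1 = dr(p, q, p), v1 = dr(q, q, q), u1 = dr(q, q, q),
                 b1 = numeric(q),
                 w2 = dr(q, r, q), v2 = dr(r, r, r), u2 = dr(r, r, r),
                 b2 = numeric(r),
                 c = dr(r, n_out, r)),
            class = "rnn_params")
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("<rnn_params> p=%d, hidden %d/%d, %d outputs (%d weights)\n",
              x$p, x$q, x$r, x$n_out, length(params_to_vec(x))))
  invisible(x)
}

#' Flatten RNN parameters to a weight vector (and back)
#'
#' Canonical column-major layout: `w1, v1, u1, b1, w2, v2, u2, b2, c`.
#'
#' @param params an `rnn_params` object.
#' @return Numeric weight vector.
#' @export
params_to_vec <- function(params) {
  c(as.numeric(params$w1), as.numeric(params$v1), as.numeric(params$u1),
    params$b1, as.numeric(params$w2), as.numeric(params$v2),
    as.numeric(params$u2), params$b2, as.numeric(params$c))
}

#' @rdname params_to_vec
#' @param vec weight vector in the canonical layout.
#' @export
vec_to_params <- function(vec, params) {
  p <- params$p; q <- params$q; r <- params$r; m <- params$n_out
  sizes <- c(p * q, q * q, q * q, q, q * r, r * r, r * r, r, r * m)
  stopifnot(length(vec) == sum(sizes))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  take <- function(i) vec[starts[i]:ends[i]]
  params$w1 <- matrix(take(1), p, q)
  params$v1 <- matrix(take(2), q, q)
  params$u1 <- matrix(take(3), q, q)
  params$b1 <- take(4)
  params$w2 <- matrix(take(5), q, r)
  params$v2 <- matrix(take(6), r, r)
  params$u2 <- matrix(take(7), r, r)
  params$b2 <- take(8)
  params$c <- matrix(take(9), r, m)
  params
}

.check_inputs <- function(params, inputs) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != params$p)
    stop(sprintf("input has %d columns but the network expects p=%d",
                 ncol(inputs), params$p))
  inputs
}

#' Forward simulation of the recurrent network
#'
#' Exact unrolled recursion from zero initial hidden states.
#'
#' @param params an `rnn_params` object.
#' @param inputs time-by-p input matrix.
#' @return List with `outputs` (time x n_out) and hidden trajectories `y1`,
#'   `y2`.
#' @export
rnn_forward <- function(params, inputs) {
  inputs <- .check_inputs(params, inputs)
  if (!nrow(inputs))
    return(list(outputs = matrix(0, 0, params$n_out),
                y1 = matrix(0, 0, params$q), y2 = matrix(0, 0, params$r)))
  rnn_forward_cpp(params$w1, params$v1, params$u1, params$b1,
                  params$w2, params$v2, params$u2, params$b2, params$c,
                  inputs)
}

#' Residuals and exact Jacobian of the network
#'
#' Residuals are the vectorized `(output - target)` values for all time
#' steps past the burn-in; the Jacobian holds the exact derivative of every
#' residual with respect to every weight, propagated through the recurrence
#' (real-time recurrent learning through the full sequence, no truncation).
#'
#' @param params an `rnn_params` object.
#' @param inputs time-by-p input matrix.
#' @param targets time-by-n_out target matrix.
#' @param burn_in leading samples excluded from the residuals.
#' @return List with `residuals` and `J` (residuals x weights).
#' @export
compute_jacobian <- function(params, inputs, targets, burn_in = 2) {
  inputs <- .check_inputs(params, inputs)
  targets <- as.matrix(targets)
  if (nrow(targets) != nrow(inputs) || ncol(targets) != params$n_out)
    stop("targets must be time x n_out, aligned with inputs")
  if (!nrow(inputs)) {
    nw <- length(params_to_vec(params))
    return(list(residuals = numeric(0), J = matrix(0, 0, nw)))
  }
  jr <- rnn_jacobian_cpp(params$w1, params$v1, params$u1, params$b1,
                         params$w2, params$v2, params$u2, params$b2, params$c,
                         inputs, targets, as.integer(burn_in))
  jr$residuals <- as.numeric(jr$residuals)
  jr
}

#' Levenberg-Marquardt training configuration
#'
#' @param mu_init initial damping; the step solves
#'   `(J'J + mu I) delta = J' residuals`.
#' @param mu_up,mu_down damping multipliers on rejected/accepted steps
#'   (`mu_up > 1 > mu_down > 0`).
#' @param max_epochs maximum accepted epochs.
#' @param val_fraction trailing contiguous fraction of the rows held out for
#'   validation-based early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed (weight init and any tie-breaking).
#' @param weight_init_scale initial-weight scale (see [rnn_init()]).
#' @param mu_max damping overflow bound; training stops beyond it.
#' @param burn_in leading samples excluded from the loss.
#' @param n_starts number of random restarts; the fit with the best
#'   validation SSE (training SSE when no validation rows are held out) is
#'   kept. Like any small nonlinear least-squares problem, LM occasionally
#'   parks in a local minimum; best-of-k restarts is the standard remedy.
#' @return An object of class `train_config`.
#' @export
train_config <- function(mu_init = 1e-3, mu_up = 10, mu_down = 0.1,
                         max_epochs = 100, val_fraction = 0.2, patience = 10,
                         seed = 1L, weight_init_scale = 1, mu_max = 1e10,
                         burn_in = 2, n_starts = 1L) {
  stopifnot(mu_init > 0, mu_up > 1, mu_down > 0, mu_down < 1,
            val_fraction >= 0, val_fraction < 1, n_starts >= 1)
  structure(list(mu_init = mu_init, mu_up = mu_up, mu_down = mu_down,
                 max_epochs = max_epochs, val_fraction = val_fraction,
                 patience = patience, seed = as.integer(seed),
                 weight_init_scale = weight_init_scale, mu_max = mu_max,
                 burn_in = burn_in, n_starts = as.integer(n_starts)),
            class = "train_config")
}

.as_xy <- function(data) {
  if (inherits(data, "decoder_dataset"))
    list(x = data$inputs, y = data$targets)
  else list(x = as.matrix(data$inputs), y = as.matrix(data$targets))
}

.sse_rows <- function(out, y, rows) {
  d <- out[rows, , drop = FALSE] - y[rows, , drop = FALSE]
  sum(d * d)
}

#' Train the recurrent network by Levenberg-Marquardt
#'
#' Iterates `delta = -(J'J + mu I)^{-1} J' residuals` on the training rows
#' (all but the trailing validation fraction). A step is accepted only if
#' the training SSE decreases, otherwise `mu` is inflated and the step
#' retried; on acceptance `mu` is deflated. Training stops at `max_epochs`
#' accepted steps, damping overflow, or `patience` accepted epochs without
#' validation improvement; the validation-best weights are returned (the
#' final weights when no validation rows are held out).
#'
#' @param params initial `rnn_params` (e.g. from [rnn_init()]); if `NULL`,
#'   initialized from the data dimensions with `cfg$seed`.
#' @param data a [decoder_dataset()] or list with `inputs` and `targets`.
#' @param cfg a [train_config()].
#' @param q,r hidden sizes used when `params` is `NULL`.
#' @return List with `params` (best weights), `history` (data.frame: epoch,
#'   sse_train, sse_val, mu) and `sse0` (initial training SSE).
#' @export
lm_train <- function(params = NULL, data, cfg = train_config(), q = 8, r = 8) {
  n_starts <- if (is.null(cfg$n_starts)) 1L else cfg$n_starts
  best <- NULL
  best_score <- Inf
  for (k in seq_len(n_starts) - 1L) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + 1000L * k
    fit <- .lm_train_once(params, data, cfg_k, q, r)
    score <- if (!is.null(fit$history) && any(is.finite(fit$history$sse_val)))
      min(fit$history$sse_val)
    else if (!is.null(fit$history)) min(fit$history$sse_train)
    else Inf
    if (is.null(best) || score < best_score) {
      best_score <- score
      best <- fit
    }
  }
  best
}

.lm_train_once <- function(params, data, cfg, q, r) {
  xy <- .as_xy(data)
  Tn <- nrow(xy$x)
  if (is.null(params))
    params <- rnn_init(ncol(xy$x), q, r, ncol(xy$y), seed = cfg$seed,
                       weight_init_scale = cfg$weight_init_scale)
  n_val <- floor(cfg$val_fraction * Tn)
  n_tr <- Tn - n_val
  if (n_tr <= cfg$burn_in) stop("too few training rows")
  nw <- length(params_to_vec(params))
  if (n_tr * params$n_out < nw)
    warning(sprintf("only %d residuals for %d weights; fit is underdetermined",
                    n_tr * params$n_out, nw))
  x_tr <- xy$x[seq_len(n_tr), , drop = FALSE]
  y_tr <- xy$y[seq_len(n_tr), , drop = FALSE]
  val_rows <- if (n_val > 0) (n_tr + 1):Tn else integer(0)

  eval_val <- function(p) {
    if (!n_val) return(NA_real_)
    out <- rnn_forward(p, xy$x)$outputs
    .sse_rows(out, xy$y, val_rows)
  }

  mu <- cfg$mu_init
  jr <- compute_jacobian(params, x_tr, y_tr, cfg$burn_in)
  sse <- sum(jr$residuals^2)
  sse0 <- sse
  best_val <- eval_val(params)
  best_params <- params
  stall <- 0L
  hist <- vector("list", cfg$max_epochs)
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    JtJ <- crossprod(jr$J)
    g <- crossprod(jr$J, jr$residuals)
    accepted <- FALSE
    while (mu <= cfg$mu_max) {
      delta <- tryCatch(solve(JtJ + diag(mu, nw), g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- vec_to_params(params_to_vec(params) - as.numeric(delta), params)
        out <- rnn_forward(cand, x_tr)$outputs
        sse_new <- .sse_rows(out, y_tr, (cfg$burn_in + 1):n_tr)
        if (!is.finite(sse_new)) stop("non-finite loss during training")
        if (sse_new < sse) {
          params <- cand
          sse <- sse_new
          mu <- mu * cfg$mu_down
          accepted <- TRUE
          break
        }
      }
      mu <- mu * cfg$mu_up
    }
    if (!accepted) break                      # damping overflow: converged
    epoch <- epoch + 1L
    sv <- eval_val(params)
    hist[[epoch]] <- data.frame(epoch = epoch, sse_train = sse,
                                sse_val = sv, mu = mu)
    if (n_val) {
      if (sv < best_val - 1e-12) {
        best_val <- sv
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    if (epoch < cfg$max_epochs)
      jr <- compute_jacobian(params, x_tr, y_tr, cfg$burn_in)
  }
  if (!n_val) best_params <- params
  list(params = best_params, history = do.call(rbind, hist[seq_len(epoch)]),
       sse0 = sse0)
}

#' Predict joint angles with a trained network
#'
#' @param params trained `rnn_params`.
#' @param data a [decoder_dataset()]; predictions are denormalized to
#'   degrees using its stored target normalization.
#' @return Time-by-3 matrix of angles in degrees.
#' @export
rnn_predict <- function(params, data) {
  stopifnot(inherits(data, "decoder_dataset"))
  out <- rnn_forward(params, data$inputs)$outputs
  colnames(out) <- c("hip", "knee", "ankle")[seq_len(ncol(out))]
  denormalize_targets(data, out)
}
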