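# Stacked generalization: level-0 FR and ISI recurrent decoders trained on
# the first part of the training data, a level-1 recurrent combiner trained
# on the second part from the level-0 predictions, plus single-stream
# baselines. Level-1 never sees the targets of the part its level-0 models
# were fitted on.

.check_aligned <- function(data_fr, data_isi) {
  stopifnot(inherits(data_fr, "decoder_dataset"),
            inherits(data_isi, "decoder_dataset"))
  if (nrow(data_fr$inputs) != nrow(data_isi$inputs) ||
      max(abs(data_fr$times - data_isi$times)) > 1e-9)
    stop("FR and ISI datasets are not row-aligned (timestamps differ)")
}

.subset_dataset <- function(data, rows) {
  decoder_dataset(data$inputs[rows, , drop = FALSE],
                  data$targets[rows, , drop = FALSE],
                  data$times[rows], data$fs, data$lag_count,
                  data$norm_in, data$norm_out, data$meta)
}

#' Split aligned training datasets into the two stacking parts
#'
#' Contiguous-in-time split: part 0 (earlier rows, used to fit the level-0
#' models) and part 1 (later rows, used to fit the level-1 combiner), cut at
#' the identical boundary in both streams.
#'
#' @param data_fr,data_isi row-aligned [decoder_dataset()]s.
#' @param ratio fraction of rows in part 0 (0 < ratio < 1; floor rule).
#' @return List `part0_fr`, `part0_isi`, `part1_fr`, `part1_isi`.
#' @export
split_training <- function(data_fr, data_isi, ratio = 0.5) {
  .check_aligned(data_fr, data_isi)
  n <- nrow(data_fr$inputs)
  n0 <- floor(ratio * n)
  if (n0 < 1 || n0 >= n)
    stop("split ratio leaves an empty part")
  list(part0_fr = .subset_dataset(data_fr, 1:n0),
       part0_isi = .subset_dataset(data_isi, 1:n0),
       part1_fr = .subset_dataset(data_fr, (n0 + 1):n),
       part1_isi = .subset_dataset(data_isi, (n0 + 1):n))
}

#' Train the two-level stacked decoder
#'
#' Level-0 FR and ISI networks are trained on part 0 of their own stream;
#' both then predict on part 1, and the resulting 6-column prediction matrix
#' (z-scored with part-1 statistics) becomes the input of the level-1
#' combiner network whose targets are the part-1 measured angles.
#'
#' @param data_fr,data_isi row-aligned training [decoder_dataset()]s.
#' @param cfg0,cfg1 [train_config()]s for level 0 and level 1.
#' @param ratio part-0 fraction of the contiguous split.
#' @param q0,r0 level-0 hidden sizes; `q1,r1` level-1 hidden sizes (the
#'   combiner is a small network of the same recurrent form).
#' @param level1_linear use a linear (identity-readout) combiner ablation:
#'   level-1 is then an ordinary least-squares map from predictions to
#'   targets.
#' @return An object of class `stack_model`.
#' @export
train_stack <- function(data_fr, data_isi, cfg0 = train_config(),
                        cfg1 = cfg0, ratio = 0.5, q0 = 8, r0 = 8,
                        q1 = 4, r1 = 4, level1_linear = FALSE) {
  .check_aligned(data_fr, data_isi)
  parts <- split_training(data_fr, data_isi, ratio)
  fit_fr <- lm_train(NULL, parts$part0_fr, cfg0, q = q0, r = r0)
  cfg0b <- cfg0; cfg0b$seed <- cfg0$seed + 1L
  fit_isi <- lm_train(NULL, parts$part0_isi, cfg0b, q = q0, r = r0)

  pred_fr <- rnn_predict(fit_fr$params, parts$part1_fr)
  pred_isi <- rnn_predict(fit_isi$params, parts$part1_isi)
  l1_raw <- cbind(pred_fr, pred_isi)
  colnames(l1_raw) <- c(paste0("fr_", colnames(pred_fr)),
                        paste0("isi_", colnames(pred_isi)))
  nz_l1 <- .zscore_fit(l1_raw)
  nz_l1$scale[nz_l1$scale <= 1e-12] <- 1
  l1_in <- .zscore_apply(l1_raw, nz_l1)
  l1_data <- list(inputs = l1_in, targets = parts$part1_fr$targets)

  if (level1_linear) {
    xm <- cbind(1, l1_in)
    beta <- qr.coef(qr(xm, LAPACK = TRUE), l1_data$targets)
    beta[is.na(beta)] <- 0                 # rank-deficient columns drop out
    level1 <- list(beta = beta)
    class(level1) <- "linear_combiner"
  } else {
    level1 <- lm_train(NULL, l1_data, cfg1, q = q1, r = r1)$params
  }

  structure(list(level0_fr = fit_fr$params, level0_isi = fit_isi$params,
                 level1 = level1, norm_l1 = nz_l1,
                 norm_out = data_fr$norm_out,
                 split_ratio = ratio,
                 level1_times = parts$part1_fr$times,
                 metadata = list(fs = data_fr$fs,
                                 lag_count_fr = data_fr$lag_count,
                                 lag_count_isi = data_isi$lag_count,
                                 kinds_fr = data_fr$meta$kinds,
                                 kinds_isi = data_isi$meta$kinds)),
            class = "stack_model")
}

#' @export
print.stack_model <- function(x, ...) {
  cat(sprintf("<stack_model> level-0 FR (%d/%d) + ISI (%d/%d), level-1 %s\n",
              x$level0_fr$q, x$level0_fr$r, x$level0_isi$q, x$level0_isi$r,
              if (inherits(x$level1, "linear_combiner")) "linear"
              else sprintf("RNN (%d/%d)", x$level1$q, x$level1$r)))
  invisible(x)
}

.stack_check_meta <- function(model, data_fr, data_isi) {
  got <- list(fs = data_fr$fs, lag_count_fr = data_fr$lag_count,
              lag_count_isi = data_isi$lag_count,
              kinds_fr = data_fr$meta$kinds, kinds_isi = data_isi$meta$kinds)
  same <- function(a, b) isTRUE(all.equal(a, b, check.attributes = FALSE))
  bad <- names(Filter(isFALSE, Map(same, model$metadata[names(got)], got)))
  if (length(bad))
    stop("feature configuration mismatch with the trained stack: ",
         paste(bad, collapse = ", "))
}

#' Predict joint angles with a stacked decoder
#'
#' Runs the full chain: level-0 forward passes on both streams, z-scoring
#' of their predictions with the training-time statistics, level-1 forward
#' pass, denormalization back to degrees.
#'
#' @param model a [train_stack()] result.
#' @param data_fr,data_isi row-aligned [decoder_dataset()]s built with the
#'   same feature configuration as at training time.
#' @return Time-by-3 matrix of predicted angles in degrees.
#' @export
stack_predict <- function(model, data_fr, data_isi) {
  stopifnot(inherits(model, "stack_model"))
  .check_aligned(data_fr, data_isi)
  .stack_check_meta(model, data_fr, data_isi)
  pred_fr <- rnn_predict(model$level0_fr, data_fr)
  pred_isi <- rnn_predict(model$level0_isi, data_isi)
  l1_in <- .zscore_apply(cbind(pred_fr, pred_isi), model$norm_l1)
  if (inherits(model$level1, "linear_combiner")) {
    outn <- cbind(1, l1_in) %*% model$level1$beta
  } else {
    outn <- rnn_forward(model$level1, l1_in)$outputs
  }
  out <- .zscore_invert(outn, model$norm_out)
  colnames(out) <- c("hip", "knee", "ankle")
  out
}

#' Train a single-stream baseline decoder
#'
#' The conventional comparison model: one recurrent network on one feature
#' stream (FR or ISI), trained on the full training set without the
#' stacking split.
#'
#' @param data a [decoder_dataset()].
#' @param cfg a [train_config()].
#' @param q,r hidden sizes.
#' @return Trained `rnn_params`.
#' @export
train_baseline <- function(data, cfg = train_config(), q = 8, r = 8) {
  lm_train(NULL, data, cfg, q = q, r = r)$params
}
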