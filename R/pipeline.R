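# Pipeline orchestration: one validated config drives synth -> features ->
# training -> evaluation, reproducibly from a single seed. The config is a
# plain named list (JSON on disk); every consumed key is declared in the
# default template and unknown keys are rejected.

#' Benchmark encoding model: four position-tuned units
#'
#' Four rectified-linear units whose drives rise with extension of one (or
#' a mix) of the joints, spanning roughly 10-80 Hz over the default
#' stepping ranges; refractory period 1.5 ms.
#'
#' @return An [encoding_model()].
#' @export
benchmark_encoding_model <- function() {
  encoding_model(list(
    list(baseline_rate = -95, gain = c(1.2, 0, 0)),
    list(baseline_rate = -62, gain = c(0, 0.9, 0)),
    list(baseline_rate = -32, gain = c(0, 0, 0.6)),
    list(baseline_rate = -90, gain = c(0.5, 0.4, 0.3))
  ))
}

#' Default pipeline configuration
#'
#' @param seed global integer seed.
#' @return Named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(n_trials = 4L, duration_s = 300, cycle_period_s = 2,
                 jitter = 0.05, rate_hz = 100, units = "benchmark"),
    trials = list(train = 1:3, model_selection = integer(0), test = 4L),
    features = list(window_s = 0.3, hop_s = 0.05, lag_count = 2L),
    decoders = list(variants = c("fr", "isi", "stack"),
                    inputs = "multiunit"),
    rnn = list(q = 5L, r = 5L, q1 = 4L, r1 = 4L, max_epochs = 40L,
               patience = 8L, val_fraction = 0.15, split_ratio = 0.5,
               mu_init = 1e-3, mu_up = 10, mu_down = 0.1, n_starts = 1L),
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and enforces the trial-role
#' invariants (model-selection and test trials disjoint; train and test
#' trials disjoint; roles within `1..n_trials`).
#'
#' @param config named list or path to a JSON config file.
#' @return The completed, validated config list.
#' @export
validate_pipeline_config <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  def <- default_pipeline_config(if (!is.null(config$seed)) config$seed else 1L)
  check_keys <- function(given, template, path = "") {
    unknown <- setdiff(names(given), names(template))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (nm in names(given))
      if (is.list(template[[nm]]) && !is.null(names(template[[nm]])))
        check_keys(as.list(given[[nm]]), template[[nm]], paste0(path, nm, "."))
  }
  check_keys(config, def)
  cfg <- modifyList(def, config)
  tr <- cfg$trials
  if (length(intersect(tr$model_selection, tr$test)))
    stop("model-selection trials must be disjoint from test trials")
  if (length(intersect(tr$train, tr$test)))
    stop("training trials must be disjoint from test trials")
  all_tr <- c(tr$train, tr$model_selection, tr$test)
  if (any(all_tr < 1 | all_tr > cfg$synth$n_trials))
    stop("trial indices must lie in 1..n_trials")
  if (!all(cfg$decoders$variants %in% c("fr", "isi", "stack")))
    stop("decoder variants must be among fr, isi, stack")
  if (!all(cfg$decoders$inputs %in% c("multiunit", "single")))
    stop("decoder inputs must be among multiunit, single")
  cfg
}

.trial_seed <- function(seed, trial, salt) {
  as.integer((seed * 1009L + trial * 131L + salt) %% .Machine$integer.max)
}

#' Run the full decoding pipeline from a configuration
#'
#' Generates the synthetic trials, extracts multiunit (and, if configured,
#' most-informative-single-unit) FR and ISI features, trains the configured
#' decoder variants on the training trials, evaluates on the held-out test
#' trials, and returns one [score_report()] per decoder variant plus a
#' manifest sufficient to re-run the experiment bit-identically. When
#' `out_dir` is set, reports and the manifest are written there as JSON.
#'
#' @param config list or JSON path; see [default_pipeline_config()].
#' @return List with `reports` (named by `<variant>_<input>`), `manifest`,
#'   and `selected_unit` (when single-unit decoding is configured).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- validate_pipeline_config(config)
  sy <- cfg$synth
  model <- if (identical(sy$units, "benchmark")) benchmark_encoding_model()
           else encoding_model(sy$units)

  kins <- list(); spikes <- list()
  for (i in seq_len(sy$n_trials)) {
    kins[[i]] <- gen_kinematics(sy$duration_s, sy$cycle_period_s,
                                jitter = sy$jitter, rate = sy$rate_hz,
                                seed = .trial_seed(cfg$seed, i, 1L))
    spikes[[i]] <- filter_low_rate_units(
      gen_spikes(kins[[i]], model, seed = .trial_seed(cfg$seed, i, 2L)))
  }

  fe <- cfg$features
  unit_for <- list(multiunit = 0L)
  if ("single" %in% cfg$decoders$inputs) {
    first_train <- cfg$trials$train[1]
    unit_for$single <- select_most_informative_unit(
      spikes[[first_train]], kins[[first_train]], "fr",
      window_s = fe$window_s, hop_s = fe$hop_s)
  }

  get_train <- function(trial, uid) {
    tr <- Filter(function(s) s$unit_id == uid, spikes[[trial]])[[1]]
    tr
  }
  feat <- function(trial, uid, kind) {
    tr <- get_train(trial, uid)
    if (kind == "fr") smooth_fr(compute_fr(tr, fe$window_s, fe$hop_s))
    else compute_isi(tr, fs_out = 1 / fe$hop_s,
                     span = c(fe$window_s, tr$duration))
  }

  rn <- cfg$rnn
  mk_cfg <- function(seed_off) {
    train_config(mu_init = rn$mu_init, mu_up = rn$mu_up, mu_down = rn$mu_down,
                 max_epochs = rn$max_epochs, val_fraction = rn$val_fraction,
                 patience = rn$patience, seed = cfg$seed + seed_off,
                 n_starts = rn$n_starts)
  }

  reports <- list()
  for (input in cfg$decoders$inputs) {
    uid <- unit_for[[input]]
    datasets <- list()
    for (kind in c("fr", "isi")) {
      tr_feats <- lapply(cfg$trials$train, function(i) feat(i, uid, kind))
      tr_kins <- kins[cfg$trials$train]
      train_ds <- build_multitrial_dataset(tr_feats, tr_kins, fe$lag_count)
      te_feats <- lapply(cfg$trials$test, function(i) feat(i, uid, kind))
      te_kins <- kins[cfg$trials$test]
      test_ds <- build_multitrial_dataset(
        te_feats, te_kins, fe$lag_count,
        trial_offsets = 1e6 + seq_along(te_feats) * 1e3,
        normalization = dataset_normalization(train_ds))
      datasets[[kind]] <- list(train = train_ds, test = test_ds)
    }
    measured <- denormalize_targets(datasets$fr$test, datasets$fr$test$targets)
    for (variant in cfg$decoders$variants) {
      pred <- switch(variant,
        fr = rnn_predict(train_baseline(datasets$fr$train, mk_cfg(10L),
                                        q = rn$q, r = rn$r),
                         datasets$fr$test),
        isi = rnn_predict(train_baseline(datasets$isi$train, mk_cfg(20L),
                                         q = rn$q, r = rn$r),
                          datasets$isi$test),
        stack = stack_predict(
          train_stack(datasets$fr$train, datasets$isi$train,
                      cfg0 = mk_cfg(30L), cfg1 = mk_cfg(40L),
                      ratio = rn$split_ratio, q0 = rn$q, r0 = rn$r,
                      q1 = rn$q1, r1 = rn$r1),
          datasets$fr$test, datasets$isi$test))
      reports[[paste0(variant, "_", input)]] <- score_report(measured, pred)
    }
  }

  manifest <- list(package = "dhdecoder",
                   version = as.character(utils::packageVersion("dhdecoder")),
                   r_version = R.version.string,
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   selected_unit = unit_for$single)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports))
      jsonlite::write_json(as.data.frame(reports[[nm]]),
                           file.path(cfg$out_dir, paste0("report_", nm, ".json")),
                           digits = NA)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(reports = reports, manifest = manifest, selected_unit = unit_for$single)
}
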