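# External interfaces: columnar text for spike trains, kinematics and
# features; flat little-endian float32 binary + JSON sidecar for raw
# traces; JSON for trained models and score reports.

#' Write / read spike trains as columnar text
#'
#' Two columns (`time_s`, `unit_id`), tab separated, with the recording
#' duration carried in a `# duration_s=` header comment.
#'
#' @param trains list of [spike_train()]s.
#' @param path output file.
#' @export
write_spike_trains <- function(trains, path) {
  dur <- max(vapply(trains, `[[`, numeric(1), "duration"))
  df <- do.call(rbind, lapply(trains, function(tr)
    if (length(tr$times)) data.frame(time_s = tr$times, unit_id = tr$unit_id)
    else NULL))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%.9g", dur), con)
  writeLines(sprintf("# unit_ids=%s",
                     paste(vapply(trains, `[[`, integer(1), "unit_id"),
                           collapse = ",")), con)
  writeLines("time_s\tunit_id", con)
  if (!is.null(df))
    write.table(df[order(df$unit_id, df$time_s), ], con, sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' @rdname write_spike_trains
#' @return `read_spike_trains`: list of [spike_train()]s.
#' @export
read_spike_trains <- function(path) {
  hdr <- readLines(path, n = 2)
  dur <- as.numeric(sub("# duration_s=", "", hdr[1], fixed = TRUE))
  ids <- as.integer(strsplit(sub("# unit_ids=", "", hdr[2], fixed = TRUE),
                             ",")[[1]])
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  lapply(ids, function(id)
    spike_train(sort(df$time_s[df$unit_id == id]), id, dur))
}

#' Write / read a kinematics series as columnar text
#'
#' Columns `time_s, hip_deg, knee_deg, ankle_deg`.
#' @param kin a [kinematics_series()].
#' @param path file path.
#' @export
write_kinematics <- function(kin, path) {
  df <- data.frame(time_s = kin$times, hip_deg = kin$hip,
                   knee_deg = kin$knee, ankle_deg = kin$ankle)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_kinematics
#' @return `read_kinematics`: a [kinematics_series()].
#' @export
read_kinematics <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  rate <- 1 / median(diff(df$time_s))
  kinematics_series(df$time_s, df$hip_deg, df$knee_deg, df$ankle_deg,
                    rate = round(rate, 6))
}

#' Write / read a raw trace as flat binary plus JSON sidecar
#'
#' Little-endian float32 samples; the sidecar records `fs_hz`, `n_samples`,
#' `t0_s` and `units`.
#'
#' @param sig a [continuous_signal()].
#' @param path binary path; sidecar written to `<path>.json`.
#' @param units physical unit label stored in the sidecar.
#' @export
write_raw <- function(sig, path, units = "V") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(sig$samples), con, size = 4, endian = "little")
  jsonlite::write_json(list(fs_hz = sig$fs, n_samples = length(sig$samples),
                            t0_s = sig$t0, units = units),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

#' @rdname write_raw
#' @return `read_raw`: a [continuous_signal()].
#' @export
read_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n_samples, size = 4, endian = "little")
  continuous_signal(x, meta$fs_hz, meta$t0_s)
}

#' Serialize / restore a trained recurrent network as JSON
#'
#' @param params an `rnn_params` object.
#' @param path JSON file path.
#' @export
write_rnn_model <- function(params, path) {
  obj <- list(p = params$p, q = params$q, r = params$r, n_out = params$n_out,
              weights = params_to_vec(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_rnn_model
#' @return `read_rnn_model`: an `rnn_params` object.
#' @export
read_rnn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  skel <- rnn_init(obj$p, obj$q, obj$r, obj$n_out, seed = 0L)
  vec_to_params(as.numeric(obj$weights), skel)
}

#' Write / read feature series as columnar text
#'
#' Columns `time_s, value, kind, unit_id`; several series may share a file.
#'
#' @param features a [feature_series()] or list of them.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  if (inherits(features, "feature_series")) features <- list(features)
  df <- do.call(rbind, lapply(features, function(f)
    data.frame(time_s = .feature_times(f), value = f$values,
               kind = f$kind, unit_id = f$unit_id)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_features
#' @return `read_features`: list of [feature_series()].
#' @export
read_features <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("numeric", "numeric", "character", "integer"))
  groups <- split(df, list(df$kind, df$unit_id), drop = TRUE)
  lapply(unname(groups), function(g) {
    g <- g[order(g$time_s), ]
    fs <- 1 / median(diff(g$time_s))
    feature_series(g$value, round(fs, 9), g$time_s[1], g$kind[1], g$unit_id[1])
  })
}

#' Write / read a decoder dataset as flat binary + JSON sidecar
#'
#' Inputs and targets as little-endian float64 (column-major), with column
#' names, timestamps, rates, lag count and normalization in the sidecar.
#'
#' @param data a [decoder_dataset()].
#' @param path binary path; sidecar written to `<path>.json`.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "decoder_dataset"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(data$inputs), con, size = 8, endian = "little")
  writeBin(as.numeric(data$targets), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(n_rows = nrow(data$inputs), n_inputs = ncol(data$inputs),
         n_targets = ncol(data$targets),
         input_names = colnames(data$inputs),
         times = data$times, fs = data$fs, lag_count = data$lag_count,
         norm_in = data$norm_in, norm_out = data$norm_out, meta = data$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

#' @rdname write_dataset
#' @return `read_dataset`: a [decoder_dataset()].
#' @export
read_dataset <- function(path) {
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = m$n_rows * m$n_inputs, size = 8,
               endian = "little")
  y <- readBin(con, numeric(), n = m$n_rows * m$n_targets, size = 8,
               endian = "little")
  inputs <- matrix(x, m$n_rows, m$n_inputs,
                   dimnames = list(NULL, m$input_names))
  targets <- matrix(y, m$n_rows, m$n_targets,
                    dimnames = list(NULL, c("hip", "knee", "ankle")))
  meta <- as.list(m$meta)
  decoder_dataset(inputs, targets, m$times, m$fs, m$lag_count,
                  lapply(m$norm_in, as.numeric), lapply(m$norm_out, as.numeric),
                  meta)
}

#' Write / read a snippet set as flat binary + JSON sidecar
#'
#' @param snips a [snippet_set()].
#' @param path binary path; sidecar written to `<path>.json`.
#' @export
write_snippets <- function(snips, path) {
  stopifnot(inherits(snips, "snippet_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(snips$snippets), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(n_snippets = nrow(snips$snippets), n_samples = ncol(snips$snippets),
         peak_times = snips$peak_times, fs = snips$fs, labels = snips$labels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname write_snippets
#' @return `read_snippets`: a [snippet_set()].
#' @export
read_snippets <- function(path) {
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = m$n_snippets * m$n_samples, size = 4,
               endian = "little")
  labels <- if (is.null(m$labels) || !length(m$labels)) NULL
            else as.integer(m$labels)
  snippet_set(matrix(x, m$n_snippets, m$n_samples), m$peak_times, m$fs, labels)
}

#' Write / read a stacked decoder as one JSON bundle
#'
#' Bundles the three trained networks, the level-1 input normalization, the
#' target normalization and the feature-configuration metadata.
#'
#' @param model a [train_stack()] result (RNN level-1 only).
#' @param path JSON file path.
#' @export
write_stack_model <- function(model, path) {
  stopifnot(inherits(model, "stack_model"))
  if (inherits(model$level1, "linear_combiner"))
    stop("linear-combiner stacks are not serialized; retrain with the RNN level-1")
  pk <- function(p) list(p = p$p, q = p$q, r = p$r, n_out = p$n_out,
                         weights = params_to_vec(p))
  jsonlite::write_json(
    list(level0_fr = pk(model$level0_fr), level0_isi = pk(model$level0_isi),
         level1 = pk(model$level1), norm_l1 = model$norm_l1,
         norm_out = model$norm_out, split_ratio = model$split_ratio,
         metadata = model$metadata),
    path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_stack_model
#' @return `read_stack_model`: a `stack_model`.
#' @export
read_stack_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpk <- function(o) vec_to_params(as.numeric(o$weights),
                                    rnn_init(o$p, o$q, o$r, o$n_out, seed = 0L))
  md <- as.list(m$metadata)
  md$lag_count_fr <- as.numeric(md$lag_count_fr)
  md$lag_count_isi <- as.numeric(md$lag_count_isi)
  structure(list(level0_fr = unpk(m$level0_fr), level0_isi = unpk(m$level0_isi),
                 level1 = unpk(m$level1),
                 norm_l1 = lapply(m$norm_l1, as.numeric),
                 norm_out = lapply(m$norm_out, as.numeric),
                 split_ratio = m$split_ratio,
                 level1_times = NULL, metadata = md),
            class = "stack_model")
}
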