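# Plain-text I/O: recordings, feature sequences and model banks. All numeric
# values are written with 17 significant digits so round-trips are bit-exact.

#' Write / read a raw recording as delimited text
#'
#' One sample per row, one tab-separated column per channel. The optional
#' sidecar holds per-sample ground truth (`sample`, `state`, `gesture`).
#'
#' @param recording An `semg_recording`.
#' @param path Output file for the samples.
#' @param truth_path Optional sidecar path for ground truth.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, truth_path = NULL) {
  m <- recording$samples
  header <- sprintf("# rate_hz=%g", recording$rate_hz)
  lines <- c(header, apply(m, 1, function(r) paste(fmt_num(r), collapse = "\t")))
  writeLines(lines, path)
  if (!is.null(truth_path))
    utils::write.table(recording$truth, truth_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param path Input samples file.
#' @export
read_recording <- function(path, truth_path = NULL) {
  lines <- readLines(path)
  rate <- 1000
  if (startsWith(lines[1], "#")) {
    rate <- as.numeric(sub(".*rate_hz=([0-9.eE+-]+).*", "\\1", lines[1]))
    lines <- lines[-1]
  }
  m <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  truth <- if (!is.null(truth_path))
    tibble::as_tibble(utils::read.table(truth_path, header = TRUE, sep = "\t"))
  else tibble::tibble(sample = seq_len(nrow(m)), state = NA_integer_,
                      gesture = NA_character_)
  structure(list(samples = m, rate_hz = rate, truth = truth, meta = list()),
            class = "semg_recording")
}

#' Write / read an RMS feature sequence as delimited text
#'
#' A one-line header records `window_ms`, `hop_ms`, `origin_sample` and
#' `rate_hz`; the body is one frame per row, one column per channel.
#'
#' @param features An `semg_features` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  header <- sprintf("# window_ms=%g hop_ms=%g origin_sample=%d rate_hz=%g",
                    features$window_ms, features$hop_ms,
                    features$origin_sample, features$rate_hz)
  lines <- c(header, apply(features$frames, 1,
                           function(r) paste(fmt_num(r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  h <- lines[1]
  get <- function(key) as.numeric(sub(sprintf(".*%s=([0-9.eE+-]+).*", key),
                                      "\\1", h))
  m <- do.call(rbind, lapply(strsplit(lines[-1], "\t", fixed = TRUE), as.numeric))
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  structure(list(frames = m, window_ms = get("window_ms"),
                 hop_ms = get("hop_ms"),
                 rate_hz = get("rate_hz"),
                 origin_sample = as.integer(get("origin_sample"))),
            class = "semg_features")
}

serialize_model <- function(model) {
  mat_lines <- function(m) apply(m, 1, function(r) paste(fmt_num(r), collapse = " "))
  c(sprintf("model %s %s", model$front, model$rear),
    sprintf("n_states %d", model$n_states),
    sprintf("n_channels %d", model$n_channels),
    paste("pi", paste(fmt_num(model$pi), collapse = " ")),
    "trans", mat_lines(model$trans),
    "means", mat_lines(model$means),
    "variances", mat_lines(model$variances),
    "mask", apply(model$mask, 1, function(r) paste(as.integer(r), collapse = " ")),
    sprintf("loglik %s", fmt_num(model$loglik)),
    "end")
}

parse_model <- function(lines) {
  lab <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  n_states <- as.integer(strsplit(lines[2], " ")[[1]][2])
  n_channels <- as.integer(strsplit(lines[3], " ")[[1]][2])
  pi <- as.numeric(strsplit(lines[4], " ")[[1]][-1])
  grab <- function(at, nrow, ncol) {
    m <- do.call(rbind, lapply(lines[(at + 1):(at + nrow)], function(l)
      as.numeric(strsplit(l, " ", fixed = TRUE)[[1]])))
    stopifnot(ncol(m) == ncol)
    m
  }
  at <- 5
  trans <- grab(at, n_states, n_states); at <- at + n_states + 1
  means <- grab(at, n_states, n_channels); at <- at + n_states + 1
  variances <- grab(at, n_states, n_channels); at <- at + n_states + 1
  mask <- grab(at, n_states, n_states) > 0; at <- at + n_states
  loglik <- as.numeric(strsplit(lines[at + 1], " ")[[1]][2])
  new_action_model(lab[2], lab[3], pi, trans, means, variances, mask,
                   loglik = loglik)
}

#' Write / read a model bank as structured text
#'
#' Keyed blocks per model (label, pi, transition matrix, means, variances,
#' mask); numeric fields round-trip bit-exactly.
#'
#' @param bank A `model_bank`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_bank <- function(bank, path) {
  lines <- c(sprintf("handhmm_bank %d", length(bank$models)),
             unlist(lapply(bank$models, serialize_model), use.names = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_bank
#' @export
read_model_bank <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "handhmm_bank"))
    stop_invalid("not a handhmm model bank file")
  starts <- which(startsWith(lines, "model "))
  ends <- which(lines == "end")
  models <- Map(function(s, e) parse_model(lines[s:e]), starts, ends)
  names(models) <- vapply(models, function(m)
    paste(m$front, m$rear, sep = ">"), "")
  fronts <- vapply(models, function(m) m$front, "")
  groups <- split(names(models), fronts)
  structure(list(models = models, groups = groups,
                 validation = NULL, held_out = NULL,
                 mean_val_accuracy = NA_real_, no_validation = NA,
                 config = list()),
            class = "model_bank")
}

#' Write / read a labeled dataset of recordings with a manifest
#'
#' Each recording is written as delimited samples plus a ground-truth
#' sidecar; `manifest.tsv` lists one row per recording (`file`,
#' `truth_file`, `gestures` as a `>`-separated string, `subject`, `rep`).
#'
#' @param dataset A [synth_dataset()] tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    stem <- sprintf("rec_%03d", i)
    write_recording(dataset$recording[[i]],
                    file.path(dir, paste0(stem, ".tsv")),
                    file.path(dir, paste0(stem, "_truth.tsv")))
    tibble::tibble(file = paste0(stem, ".tsv"),
                   truth_file = paste0(stem, "_truth.tsv"),
                   gestures = paste(dataset$gestures[[i]], collapse = ">"),
                   subject = dataset$subject[i], rep = dataset$rep[i])
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(dplyr::bind_rows(rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param manifest Path of a manifest written by [write_dataset()].
#' @export
read_dataset <- function(manifest) {
  dir <- dirname(manifest)
  m <- utils::read.table(manifest, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  tibble::tibble(
    action_id = m$gestures,
    gestures = strsplit(m$gestures, ">", fixed = TRUE),
    subject = m$subject,
    rep = m$rep,
    recording = lapply(seq_len(nrow(m)), function(i)
      read_recording(file.path(dir, m$file[i]),
                     file.path(dir, m$truth_file[i])))
  )
}

#' Write prediction events to a delimited file
#'
#' @param events An event tibble from [predict_action()] or
#'   [predict_multi()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
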