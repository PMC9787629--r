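# Evaluation: accuracy, confusion tables (with a nongesture outcome) and
# trigger latency in signal time.

#' Evaluate a model bank on labeled trials
#'
#' Two-gesture trials are decoded with [predict_action()] over the full bank
#' and are correct iff the single event predicts the true rear gesture.
#' Multi-gesture trials are decoded with [predict_multi()]; the k-th
#' prediction event is scored against the k-th true transition. A trial is
#' correct iff every true transition received the right prediction in order
#' (per-trial scoring); each transition is also scored independently
#' (per-transition scoring). A transition with no matching event counts as
#' nongesture (N/G). Trigger latency is
#' `(trigger_frame - true onset frame) * hop_ms` of signal time, averaged
#' over correct events; it is not wall-clock processing time.
#'
#' @param bank A `model_bank`.
#' @param trials A [prepare_trials()] tibble (`action_id`, `gestures`,
#'   `features`, `onset_frames`).
#' @param config A [window_config()].
#' @param prune Use model pruning for multi-gesture trials (default TRUE).
#' @return A `handhmm_eval` object: `trials` (per-trial results), `summary`
#'   (per-action), `confusion` (true action x predicted rear gesture or N/G,
#'   one row-count per transition), and `overall` (accuracy %, per-transition
#'   accuracy %, mean latency ms).
#' @export
evaluate_bank <- function(bank, trials, config = window_config(),
                          prune = TRUE) {
  if (!nrow(trials)) stop_invalid("no trials to evaluate")
  if (is.null(trials$onset_frames))
    stop_invalid("trials lack ground-truth onset frames; use prepare_trials()")
  hop_ms <- trials$features[[1]]$hop_ms

  res <- vector("list", nrow(trials))
  conf <- list()
  for (i in seq_len(nrow(trials))) {
    gestures <- trials$gestures[[i]]
    true_rears <- gestures[-1]
    onsets <- trials$onset_frames[[i]]
    if (length(gestures) == 2) {
      ev <- predict_action(trials$features[[i]], bank$models, config)
    } else {
      ev <- predict_multi(trials$features[[i]], bank, config, prune = prune)
    }
    k <- length(true_rears)
    pred <- ev$predicted_gesture
    aligned <- vapply(seq_len(k), function(j)
      if (j <= length(pred)) pred[j] else "N/G", "")
    match_j <- aligned == true_rears
    per_trial_correct <- all(match_j)
    lat <- vapply(seq_len(k), function(j) {
      if (j <= nrow(ev) && match_j[j])
        (ev$trigger_frame[j] - onsets[j]) * hop_ms
      else NA_real_
    }, numeric(1))
    res[[i]] <- tibble::tibble(
      action_id = trials$action_id[i],
      n_events = nrow(ev),
      n_transitions = k,
      n_matched = sum(match_j),
      correct = per_trial_correct,
      mean_latency_ms = if (any(match_j)) mean(lat, na.rm = TRUE) else NA_real_
    )
    conf[[i]] <- tibble::tibble(action_id = trials$action_id[i],
                                true_rear = true_rears, predicted = aligned)
  }
  per_trial <- dplyr::bind_rows(res)
  confusion <- dplyr::bind_rows(conf) |>
    dplyr::count(.data$action_id, .data$true_rear, .data$predicted,
                 name = "count")

  summary <- per_trial |>
    dplyr::group_by(.data$action_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = mean(.data$correct) * 100,
      transition_accuracy = sum(.data$n_matched) / sum(.data$n_transitions) * 100,
      mean_latency_ms = if (all(is.na(.data$mean_latency_ms))) NA_real_
                        else mean(.data$mean_latency_ms, na.rm = TRUE),
      .groups = "drop")

  overall <- list(
    accuracy = mean(per_trial$correct) * 100,
    transition_accuracy = sum(per_trial$n_matched) /
      sum(per_trial$n_transitions) * 100,
    mean_latency_ms = if (all(is.na(per_trial$mean_latency_ms))) NA_real_
                      else mean(per_trial$mean_latency_ms, na.rm = TRUE),
    n_trials = nrow(per_trial))

  structure(list(trials = per_trial, summary = summary, confusion = confusion,
                 overall = overall, config = config, prune = prune),
            class = "handhmm_eval")
}

#' @export
print.handhmm_eval <- function(x, ...) {
  cat(sprintf(paste0("<handhmm_eval> %d trials: accuracy %.1f%%, ",
                     "per-transition %.1f%%, mean latency %s\n"),
              x$overall$n_trials, x$overall$accuracy,
              x$overall$transition_accuracy,
              if (is.na(x$overall$mean_latency_ms)) "n/a"
              else sprintf("%.0f ms", x$overall$mean_latency_ms)))
  invisible(x)
}

#' @rdname tidy.handhmm_eval
#' @export
glance.handhmm_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$overall$accuracy,
                 transition_accuracy = x$overall$transition_accuracy,
                 mean_latency_ms = x$overall$mean_latency_ms,
                 n_trials = x$overall$n_trials)
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-action summary; `glance()` the overall one-row
#' summary.
#'
#' @param x A `handhmm_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.handhmm_eval <- function(x, ...) x$summary

#' Confusion-matrix heatmap of an evaluation report
#'
#' Rows are true rear gestures (per transition), columns predicted gestures
#' plus the nongesture outcome; fill is the row-normalized proportion.
#'
#' @param object A `handhmm_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.handhmm_eval <- function(object, ...) {
  d <- object$confusion |>
    dplyr::group_by(.data$true_rear, .data$predicted) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(prop = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$true_rear,
                                  fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop)),
                       color = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "proportion") +
    ggplot2::labs(x = "predicted rear gesture", y = "true rear gesture")
}

#' Envelope plot of a synthetic recording's RMS features
#'
#' @param object An `semg_features` object.
#' @param ... Unused.
#' @return A ggplot object with one line per channel.
#' @export
autoplot.semg_features <- function(object, ...) {
  d <- tibble::as_tibble(object$frames) |>
    dplyr::mutate(frame = dplyr::row_number()) |>
    tidyr::pivot_longer(-"frame", names_to = "channel", values_to = "rms")
  ggplot2::ggplot(d, ggplot2::aes(.data$frame, .data$rms,
                                  color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("frame (%g ms hop)", object$hop_ms), y = "RMS")
}
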