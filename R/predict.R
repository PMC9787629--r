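# Multi-gesture prediction with model pruning: group binding and window
# restart at each detected key state.

#' Predict a continuous multi-gesture action with model pruning
#'
#' Decodes windows over the active models (initially the whole bank),
#' tracking each model's cumulative max-path log-probability, and searches
#' the best-fitting model's window path for the key state. On a trigger, an
#' event predicting the model's rear gesture `h_r` is emitted; with pruning,
#' the active set is bound to the group of models whose front gesture is
#' `h_r`, every surviving decode state is reset to the initial distribution,
#' and the window restarts at the key-state frame (the partial window
#' remainder is re-decoded under the new group). Without pruning (the
#' ablation arm) the full bank stays active and accumulation is never reset;
#' events still fire at strictly increasing trigger frames.
#'
#' @param features An `semg_features` object or frames matrix.
#' @param bank A `model_bank`.
#' @param config A [window_config()].
#' @param prune Apply group binding and accumulation restart (default TRUE).
#' @return An event tibble (possibly zero rows), one row per prediction, in
#'   trigger order: `predicted_gesture`, `front`, `rear`, `trigger_frame`,
#'   `window_index`, `windows_elapsed`, `cum_logprob`.
#' @export
predict_multi <- function(features, bank, config = window_config(),
                          prune = TRUE) {
  if (!inherits(bank, "model_bank")) stop_invalid("`bank` must be a model_bank")
  obs <- as_feature_matrix(features)
  n <- nrow(obs)
  active <- names(bank$models)
  states <- lapply(bank$models[active], decode_init)
  events <- list()
  pos <- 1L
  win_idx <- 0L          # global window counter
  windows_in_run <- 0L   # windows since the current accumulation start
  last_trigger <- 0L
  while (pos <= n) {
    stop_at <- min(pos + config$length_frames - 1L, n)
    win_idx <- win_idx + 1L
    windows_in_run <- windows_in_run + 1L
    st <- step_models(states, bank$models[active], obs[pos:stop_at, , drop = FALSE])
    states <- st$states
    path <- st$paths[[st$best]]
    hit <- detect_key_state(path, config$key_state)
    trigger <- if (is.na(hit)) NA_integer_ else pos + hit - 1L
    if (!is.na(trigger) && trigger > last_trigger) {
      mdl <- bank$models[active][[st$best]]
      events[[length(events) + 1L]] <- tibble::tibble(
        predicted_gesture = mdl$rear, front = mdl$front, rear = mdl$rear,
        trigger_frame = trigger, window_index = win_idx,
        windows_elapsed = windows_in_run, cum_logprob = st$logprobs[st$best])
      last_trigger <- trigger
      if (prune) {
        active <- bank$groups[[mdl$rear]]
        states <- lapply(bank$models[active], decode_init)
        windows_in_run <- 0L
        pos <- trigger # restart accumulation at the key-state frame
        next
      }
    }
    pos <- pos + config$hop_frames
  }
  if (!length(events)) empty_events() else dplyr::bind_rows(events)
}
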