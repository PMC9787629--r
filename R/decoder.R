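# Online sliding-window Viterbi decoding with marginalized cross-window
# initialization (long-term memory) and key-state-transition prediction.

#' Sliding-window decoder configuration
#'
#' @param length_frames Window length in feature frames (default 20, i.e.
#'   1 s of signal at a 50 ms hop).
#' @param hop_frames Window increment in frames (default 20:
#'   non-overlapping windows).
#' @param key_state State index whose first appearance in the decoded path
#'   triggers the prediction (default 4, the rising transition of the rear
#'   gesture).
#' @return A `window_config` list.
#' @export
window_config <- function(length_frames = 20, hop_frames = 20, key_state = 4) {
  assert_count(length_frames, "length_frames", min = 1)
  assert_count(hop_frames, "hop_frames", min = 1)
  assert_count(key_state, "key_state", min = 1)
  if (key_state > 6) stop_invalid("`key_state` must be in 1..6")
  structure(list(length_frames = as.integer(length_frames),
                 hop_frames = as.integer(hop_frames),
                 key_state = as.integer(key_state)),
            class = "window_config")
}

#' Initialize a decode state for one model
#'
#' The cumulative per-state max-path log-probability vector starts as the
#' log initial distribution: all mass on state one.
#'
#' @param model An `action_model`.
#' @return A `decode_state` list with `delta` (length n_states, log domain)
#'   and `frames_consumed = 0`.
#' @export
decode_init <- function(model) {
  structure(list(delta = log(model$pi), frames_consumed = 0L),
            class = "decode_state")
}

#' Decode one window with marginalized initialization
#'
#' The first frame of the window is initialized from the previous window's
#' final per-state maxima (`max_j[delta_prev(j) + log a_ji] + log b_i(o_1)`),
#' or from the initial distribution when no frames have been consumed yet.
#' Remaining frames follow the standard max-product recursion. Backtracking
#' is confined to the window (the first frame carries no backpointer);
#' cumulative log-probability totals are preserved across windows.
#'
#' @param state A `decode_state` from [decode_init()] or a previous call.
#' @param model The corresponding `action_model`.
#' @param window An `semg_features` slice or frames matrix (>= 1 frame).
#' @return A list with `state` (updated `decode_state`), `path` (decoded
#'   states within the window), and `logprob` (cumulative max-path
#'   log-probability after the window).
#' @export
decode_window <- function(state, model, window) {
  obs <- as_feature_matrix(window)
  if (nrow(obs) < 1) stop_invalid("empty window")
  logB <- emission_logB(model, obs)
  logA <- log(model$trans)
  if (state$frames_consumed == 0L) {
    init <- log(model$pi) + logB[1, ]
  } else {
    hand_off <- apply(state$delta + logA, 2, max)
    init <- hand_off + logB[1, ]
  }
  v <- hmm_viterbi(logB, logA, init)
  state$delta <- v$logdelta_T
  state$frames_consumed <- state$frames_consumed + nrow(obs)
  list(state = state, path = v$path, logprob = v$logprob)
}

#' First crossing of the key state in a decoded path
#'
#' Returns the within-window index at which the path first reaches the key
#' state. In a left-to-right topology states are non-decreasing along the
#' true progression, so a path entering a window at a state beyond the key
#' state (the crossing fell on a window boundary, or the decoder took a
#' forward jump over it) has also passed the key state transition; the first
#' frame at or beyond the key state therefore marks the crossing.
#'
#' @param path Integer state path (non-empty).
#' @param key_state The trigger state index.
#' @return The within-window index of the first frame at or beyond
#'   `key_state`, or `NA_integer_` if the path never reaches it.
#' @export
detect_key_state <- function(path, key_state = 4) {
  if (!length(path)) stop_invalid("empty path")
  idx <- which(path >= key_state)
  if (length(idx)) idx[1] else NA_integer_
}

# Advance all active models over one window; returns updated states, the
# best model index (highest cumulative max delta, ties to the lowest index)
# and its within-window path.
step_models <- function(states, models, window) {
  paths <- vector("list", length(models))
  logprobs <- numeric(length(models))
  for (m in seq_along(models)) {
    r <- decode_window(states[[m]], models[[m]], window)
    states[[m]] <- r$state
    paths[[m]] <- r$path
    logprobs[m] <- r$logprob
  }
  best <- which.max(logprobs) # ties break toward the lowest index
  list(states = states, paths = paths, logprobs = logprobs, best = best)
}

empty_events <- function() {
  tibble::tibble(predicted_gesture = character(), front = character(),
                 rear = character(), trigger_frame = integer(),
                 window_index = integer(), windows_elapsed = integer(),
                 cum_logprob = numeric())
}

#' Predict the rear gesture of a continuous two-gesture action
#'
#' Advances window by window over the feature sequence, maintaining one
#' decode state per model. After each window the best-fitting model is the
#' one with the highest cumulative max-path log-probability; if that model's
#' window path contains the key state, a prediction event fires with the
#' model's rear gesture and decoding stops. The final partial window is
#' decoded at its natural length.
#'
#' @param features An `semg_features` object or frames matrix.
#' @param models List of `action_model`s (or a `model_bank`).
#' @param config A [window_config()].
#' @param memory Keep the marginalized cross-window hand-off (default TRUE).
#'   With `memory = FALSE` every window is re-initialized with the initial
#'   state distribution and per-window best-path log-probabilities are summed
#'   instead — an ablation of the decoder's long-term memory, kept for
#'   comparison experiments.
#' @return A one-row event tibble (`predicted_gesture`, `front`, `rear`,
#'   `trigger_frame`, `window_index`, `windows_elapsed`, `cum_logprob`), or a
#'   zero-row tibble if the features are exhausted without a trigger.
#' @export
predict_action <- function(features, models, config = window_config(),
                           memory = TRUE) {
  if (inherits(models, "model_bank")) models <- models$models
  if (!length(models)) stop_invalid("need at least one model")
  obs <- as_feature_matrix(features)
  states <- lapply(models, decode_init)
  carried <- numeric(length(models)) # no-memory cumulative totals
  n <- nrow(obs)
  start <- 1L
  win_idx <- 0L
  while (start <= n) {
    stop_at <- min(start + config$length_frames - 1L, n)
    win_idx <- win_idx + 1L
    if (!memory) states <- lapply(models, decode_init)
    st <- step_models(states, models, obs[start:stop_at, , drop = FALSE])
    states <- st$states
    if (!memory) {
      carried <- carried + st$logprobs
      st$logprobs <- carried
      st$best <- which.max(carried)
    }
    hit <- detect_key_state(st$paths[[st$best]], config$key_state)
    if (!is.na(hit)) {
      mdl <- models[[st$best]]
      return(tibble::tibble(
        predicted_gesture = mdl$rear, front = mdl$front, rear = mdl$rear,
        trigger_frame = start + hit - 1L, window_index = win_idx,
        windows_elapsed = win_idx, cum_logprob = st$logprobs[st$best]))
    }
    start <- start + config$hop_frames
  }
  empty_events()
}
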