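#' Default gesture activation profiles
#'
#' Builds per-channel steady-state RMS amplitude profiles for the four base
#' hand gestures (fist, fingers spread, wrist extension, wrist flexion).
#' Channels model electrodes ringing the forearm: each gesture dominates a
#' distinct sector of the ring (a smooth circular bump of high activation
#' centered on its own electrodes, evenly spaced across gestures) over a
#' common baseline, with per-channel random variation. Amplitudes are in
#' arbitrary units on roughly \[0.2, 1\]; profiles are redrawn until every
#' pair of gestures is separated by at least `3 * noise_sd` in Euclidean
#' distance, so the synthetic classes are learnable by construction.
#'
#' @param n_channels Number of sEMG channels (>= 2; the armband of the study
#'   design has 8).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param noise_sd Reference additive-noise standard deviation used for the
#'   separation requirement (same arbitrary units as the activations).
#' @param rise_ms,fall_ms Durations of the rising and declining transition
#'   phases of each gesture, in ms. Both must stay well below the steady
#'   phase of a 2500 ms gesture segment: hand transitions are much shorter
#'   than hand stabilization.
#'
#' @return A tibble with one row per gesture: `gesture`, `activation`
#'   (list-column of length-`n_channels` numeric vectors), `rise_ms`,
#'   `fall_ms`.
#' @examples
#' gesture_profiles(8, seed = 1)
#' @export
gesture_profiles <- function(n_channels = 8, seed = 1, noise_sd = 0.05,
                             rise_ms = 300, fall_ms = 300) {
  assert_count(n_channels, "n_channels", min = 2)
  assert_number(noise_sd, "noise_sd", min = 0)
  with_local_seed(seed, {
    centers <- round((seq_len(4) - 1) * n_channels / 4) + 1
    ring_d <- function(c0) {
      d <- abs(seq_len(n_channels) - c0)
      pmin(d, n_channels - d)
    }
    repeat {
      act <- t(vapply(centers, function(c0) {
        bump <- exp(-ring_d(c0)^2 / (2 * 1.2^2))
        (0.2 + 0.8 * bump) * runif(n_channels, 0.85, 1.15)
      }, numeric(n_channels)))
      act <- pmin(pmax(act, 0.05), 1.15)
      d <- as.matrix(stats::dist(act))
      if (min(d[upper.tri(d)]) >= 3 * noise_sd) break
    }
    tibble::tibble(
      gesture = HAND_GESTURES,
      activation = lapply(seq_len(4), function(i) act[i, ]),
      rise_ms = rise_ms,
      fall_ms = fall_ms
    )
  })
}

#' Apply per-subject activation jitter
#'
#' Emulates inter-subject variation with a multiplicative per-channel factor
#' drawn once per subject from `1 +/- jitter` and applied to every gesture's
#' activation vector. Channel geometry (and hence class separability) is
#' preserved.
#'
#' @param profiles A profile tibble from [gesture_profiles()].
#' @param subject_seed Integer seed identifying the synthetic subject.
#' @param jitter Half-width of the uniform multiplicative factor (default
#'   0.15, i.e. +/-15%).
#' @return A profile tibble of the same shape.
#' @export
jitter_profiles <- function(profiles, subject_seed, jitter = 0.15) {
  n_channels <- length(profiles$activation[[1]])
  fac <- with_local_seed(subject_seed,
                         runif(n_channels, 1 - jitter, 1 + jitter))
  profiles$activation <- lapply(profiles$activation, function(a) a * fac)
  profiles
}

#' The four-gesture action types used for multi-gesture evaluation
#'
#' @return A named list of four length-4 gesture sequences.
#' @export
four_gesture_actions <- function() {
  list(
    A1 = c("fist", "fingers_spread", "wrist_flexion", "fist"),
    A2 = c("wrist_flexion", "wrist_extension", "fist", "fingers_spread"),
    A3 = c("fingers_spread", "fist", "wrist_flexion", "wrist_extension"),
    A4 = c("wrist_extension", "fingers_spread", "fist", "wrist_flexion")
  )
}

#' Synthesize one continuous multi-gesture sEMG recording
#'
#' Generates a raw multichannel recording for an ordered gesture sequence.
#' The action's opening rise ramps the per-channel envelope linearly from a
#' rest level (5% of activation) up to the first profile's activation over
#' `rise_ms`; its closing decline ramps back down to rest over `fall_ms`.
#' Interior gesture boundaries are continuous hand-offs: the hand morphs
#' directly from one posture to the next without passing through rest, so
#' the front gesture's declining phase releases only to a partial engagement
#' level (`transition_level`, default 50% of its activation) and the rear
#' gesture's rising phase starts from the same partial level of its own
#' pattern (anticipatory activation of the incoming gesture). Gesture
#' segment durations carry human timing jitter (`timing_jitter`, uniform
#' fractional spread around `per_gesture_ms`), so state boundaries are not
#' locked to any decoding-window grid. The emitted
#' signal is the envelope modulating a unit-RMS in-band carrier (80 Hz
#' sinusoid with a random phase per channel) plus additive white Gaussian
#' noise, so the RMS of any 100 ms window tracks the envelope. Ground-truth
#' states (3 per gesture: rising, steady, declining) and gestures are
#' recorded per sample.
#'
#' @param profiles Profile tibble from [gesture_profiles()] (possibly
#'   jittered).
#' @param gestures Ordered character vector of gesture ids (length 2 or 4;
#'   consecutive gestures must differ).
#' @param per_gesture_ms Duration of each gesture segment in ms (default
#'   2500, giving ~5 s two-gesture and ~10 s four-gesture actions).
#' @param noise_sd Additive noise SD (same units as activations).
#' @param rate_hz Sampling rate (default 1000).
#' @param rest_ms Optional rest padding before and after the action, in ms
#'   (envelope at rest level, state 0); default 0.
#' @param seed Integer seed; deterministic given the seed.
#' @param carrier_hz Carrier frequency (default 80; inside the 20-150 Hz
#'   analysis band and an integer number of cycles per 100 ms window).
#' @param transition_level Fraction of a gesture's activation retained at an
#'   interior hand-off (default 0.5).
#' @param timing_jitter Half-width of the uniform fractional jitter on each
#'   gesture's segment duration (default 0.08, i.e. +/-8%, ~ +/-200 ms of a
#'   2500 ms segment).
#'
#' @return An object of class `semg_recording`: a list with `samples`
#'   (n_samples x n_channels matrix), `rate_hz`, `truth` (tibble with
#'   `sample`, `state`, `gesture`), and `meta`.
#' @export
synthesize_action <- function(profiles, gestures, per_gesture_ms = 2500,
                              noise_sd = 0.05, rate_hz = 1000, rest_ms = 0,
                              seed = 1, carrier_hz = 80,
                              transition_level = 0.5, timing_jitter = 0.08) {
  if (length(gestures) < 2)
    stop_invalid("`gestures` must contain at least 2 gestures")
  if (any(gestures[-1] == gestures[-length(gestures)]))
    stop_invalid("consecutive gestures must differ")
  missing <- setdiff(gestures, profiles$gesture)
  if (length(missing))
    stop_invalid("no profile for gesture(s): %s", paste(missing, collapse = ", "))
  assert_number(noise_sd, "noise_sd", min = 0)

  n_channels <- length(profiles$activation[[1]])
  rest_n <- round(rest_ms * rate_hz / 1000)
  prof <- function(g) profiles[match(g, profiles$gesture), ]
  K <- length(gestures)

  out <- with_local_seed(seed, {
    seg_ns <- round(per_gesture_ms *
                      (1 + runif(K, -timing_jitter, timing_jitter)) *
                      rate_hz / 1000)
    env <- matrix(0, nrow = 0, ncol = n_channels)
    state <- integer(0)
    gest <- character(0)
    for (k in seq_len(K)) {
      p <- prof(gestures[k])
      act <- p$activation[[1]]
      rise_n <- round(p$rise_ms * rate_hz / 1000)
      fall_n <- round(p$fall_ms * rate_hz / 1000)
      steady_n <- seg_ns[k] - rise_n - fall_n
      if (steady_n <= rise_n || steady_n <= fall_n)
        stop_invalid("transition phases must be shorter than the steady phase")
      rest <- 0.05 * act
      # opening rise comes up from rest; interior rises start at the partial
      # engagement level of this gesture's own pattern
      from_up <- if (k == 1) rest else transition_level * act
      ramp_up <- outer(seq_len(rise_n) / rise_n, act - from_up) +
        matrix(from_up, rise_n, n_channels, byrow = TRUE)
      hold <- matrix(act, steady_n, n_channels, byrow = TRUE)
      # closing decline returns to rest; interior declines release only to
      # the partial engagement level before the next gesture takes over
      to_dn <- if (k == K) rest else transition_level * act
      ramp_dn <- outer(1 - seq_len(fall_n) / fall_n, act - to_dn) +
        matrix(to_dn, fall_n, n_channels, byrow = TRUE)
      env <- rbind(env, ramp_up, hold, ramp_dn)
      state <- c(state, rep(3L * k - 2L, rise_n), rep(3L * k - 1L, steady_n),
                 rep(3L * k, fall_n))
      gest <- c(gest, rep(gestures[k], seg_ns[k]))
    }
    if (rest_n > 0) {
      lead <- matrix(0.05 * prof(gestures[1])$activation[[1]], rest_n,
                     n_channels, byrow = TRUE)
      trail <- matrix(0.05 * prof(tail(gestures, 1))$activation[[1]], rest_n,
                      n_channels, byrow = TRUE)
      env <- rbind(lead, env, trail)
      state <- c(rep(0L, rest_n), state, rep(0L, rest_n))
      gest <- c(rep(NA_character_, rest_n), gest, rep(NA_character_, rest_n))
    }

    n <- nrow(env)
    phase <- runif(n_channels, 0, 2 * pi)
    tt <- seq_len(n) / rate_hz
    carrier <- sqrt(2) * sin(outer(2 * pi * carrier_hz * tt, rep(1, n_channels)) +
                               matrix(phase, n, n_channels, byrow = TRUE))
    samples <- env * carrier + if (noise_sd > 0)
      matrix(rnorm(n * n_channels, sd = noise_sd), n, n_channels) else 0
    list(samples = samples, state = state, gest = gest)
  })
  samples <- out$samples
  colnames(samples) <- paste0("ch", seq_len(n_channels))

  structure(list(
    samples = samples,
    rate_hz = rate_hz,
    truth = tibble::tibble(sample = seq_len(nrow(samples)),
                           state = out$state, gesture = out$gest),
    meta = list(gestures = gestures, per_gesture_ms = per_gesture_ms,
                noise_sd = noise_sd, rest_ms = rest_ms, seed = seed,
                carrier_hz = carrier_hz)
  ), class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %d samples x %d channels @ %g Hz; gestures: %s\n",
              nrow(x$samples), ncol(x$samples), x$rate_hz,
              paste(x$meta$gestures, collapse = " > ")))
  invisible(x)
}

#' Generate a labeled synthetic dataset of continuous actions
#'
#' Emits `reps` recordings per action per synthetic subject. Each subject
#' seed perturbs the activation profiles once (multiplicative +/-15% channel
#' jitter); the repetition index perturbs only the noise/carrier draw.
#'
#' @param profiles Base profile tibble from [gesture_profiles()].
#' @param actions List of ordered gesture sequences; default all 12 ordered
#'   pairs of the four base gestures.
#' @param reps Repetitions per action per subject (>= 1).
#' @param subject_seeds Integer vector, one seed per synthetic subject.
#' @param seed Master seed for the per-recording noise streams.
#' @inheritParams synthesize_action
#' @return A tibble with columns `action_id`, `gestures` (list), `subject`,
#'   `rep`, `recording` (list of `semg_recording`).
#' @export
synth_dataset <- function(profiles, actions = NULL, reps = 20,
                          subject_seeds = c(101L, 202L), seed = 1,
                          per_gesture_ms = 2500, noise_sd = 0.05,
                          rest_ms = 0, jitter = 0.15) {
  assert_count(reps, "reps", min = 1)
  if (is.null(actions)) {
    grid <- expand.grid(rear = HAND_GESTURES, front = HAND_GESTURES,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$front != grid$rear, c("front", "rear")]
    actions <- Map(c, grid$front, grid$rear)
    names(actions) <- NULL
  }
  ids <- vapply(actions, paste, "", collapse = ">")
  rows <- list()
  for (s in seq_along(subject_seeds)) {
    prof_s <- jitter_profiles(profiles, subject_seeds[s], jitter = jitter)
    for (a in seq_along(actions)) {
      for (r in seq_len(reps)) {
        rec <- synthesize_action(
          prof_s, actions[[a]], per_gesture_ms = per_gesture_ms,
          noise_sd = noise_sd, rest_ms = rest_ms,
          seed = derive_seed(seed, s, a, r))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          action_id = ids[a], gestures = list(actions[[a]]),
          subject = s, rep = r, recording = list(rec))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Ground-truth state and gesture per feature frame
#'
#' Maps per-sample ground truth onto RMS feature frames (frame t covers
#' samples `[(t-1)*hop, (t-1)*hop + window)`), labeling each frame by the
#' state and gesture at its window center.
#'
#' @param recording A `semg_recording` with truth annotations.
#' @param window_ms,hop_ms RMS window length and hop in ms (defaults 100/50).
#' @return A tibble with `frame`, `state`, `gesture`.
#' @export
frame_truth <- function(recording, window_ms = 100, hop_ms = 50) {
  win <- round(window_ms * recording$rate_hz / 1000)
  hop <- round(hop_ms * recording$rate_hz / 1000)
  n <- nrow(recording$samples)
  n_frames <- floor((n - win) / hop) + 1
  centers <- pmin((seq_len(n_frames) - 1) * hop + floor(win / 2) + 1, n)
  tibble::tibble(
    frame = seq_len(n_frames),
    state = recording$truth$state[centers],
    gesture = recording$truth$gesture[centers]
  )
}
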