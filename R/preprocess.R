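# Preprocessing: band-pass + notch filtering, energy-based active-segment
# detection, and windowed RMS feature extraction.

# Narrow IIR notch (biquad) by pole-zero placement: zeros on the unit circle
# at +/-w0, poles at radius r inside; gain normalized to 1 at DC.
# r is set from the -3 dB bandwidth f0/Q.
design_notch <- function(notch_hz, rate_hz, q = 30) {
  w0 <- 2 * pi * notch_hz / rate_hz
  bw <- w0 / q
  r <- 1 - bw / 2
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

#' Band-pass and notch filter a raw recording
#'
#' Applies a 4th-order Butterworth band-pass (default 20-150 Hz) and a narrow
#' 50 Hz notch (quality factor 30) to every channel. Both filters are run
#' forward-backward ([signal::filtfilt()]), i.e. zero-phase, so ground-truth
#' sample alignment is preserved.
#'
#' @param recording A `semg_recording` (>= 100 samples).
#' @param band_low_hz,band_high_hz Band edges in Hz.
#' @param notch_hz Mains frequency to suppress (Hz).
#' @param notch_q Notch quality factor (center frequency / -3 dB bandwidth).
#' @return The filtered `semg_recording` (same shape and annotations).
#' @export
filter_semg <- function(recording, band_low_hz = 20, band_high_hz = 150,
                        notch_hz = 50, notch_q = 30) {
  n <- nrow(recording$samples)
  if (n < 100) stop_invalid("recording too short to filter (%d samples)", n)
  fs <- recording$rate_hz
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz && band_high_hz < fs / 2))
    stop_invalid("band edges must satisfy 0 < low < high < rate/2")
  bp <- signal::butter(4, c(band_low_hz, band_high_hz) / (fs / 2), type = "pass")
  nt <- design_notch(notch_hz, fs, q = notch_q)
  out <- apply(recording$samples, 2, function(x) {
    y <- signal::filtfilt(bp, x)
    signal::filtfilt(signal::Arma(b = nt$b, a = nt$a), y)
  })
  colnames(out) <- colnames(recording$samples)
  recording$samples <- out
  recording$meta$filtered <- list(band = c(band_low_hz, band_high_hz),
                                  notch_hz = notch_hz, notch_q = notch_q)
  recording
}

#' Energy-based active-segment detection
#'
#' Estimates baseline short-time energy (squared signal summed over channels,
#' 100 ms moving window) from the leading `baseline_ms` of the recording and
#' returns the half-open sample range in which energy exceeds
#' `mean + k * SD` of the baseline for at least `min_active_ms`.
#'
#' @param recording A `semg_recording` whose first `baseline_ms` are rest.
#' @param baseline_ms Leading rest duration used for baseline statistics.
#' @param k Threshold multiplier on the baseline SD.
#' @param min_active_ms Minimum supra-threshold run length to count as
#'   activity.
#' @param energy_window_ms Moving-energy window (default 100 ms).
#' @return A list with `start`, `end` (half-open sample range covering the
#'   first through last qualifying run) and `found`. When no run qualifies,
#'   `found` is `FALSE` and the range is empty (`start == end == 1`).
#' @export
active_segment <- function(recording, baseline_ms = 300, k = 3,
                           min_active_ms = 200, energy_window_ms = 100) {
  fs <- recording$rate_hz
  base_n <- round(baseline_ms * fs / 1000)
  n <- nrow(recording$samples)
  if (n < base_n)
    stop_invalid("recording shorter than baseline_ms")
  win <- round(energy_window_ms * fs / 1000)
  e <- rowSums(recording$samples^2)
  # centered moving average via cumulative sums
  cs <- c(0, cumsum(e))
  half <- floor(win / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  ste <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)

  base <- ste[seq_len(base_n)]
  thr <- mean(base) + k * sd(base)
  active <- ste > thr
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_n <- round(min_active_ms * fs / 1000)
  keep <- r$values & r$lengths >= min_n
  if (!any(keep))
    return(list(start = 1L, end = 1L, found = FALSE))
  list(start = as.integer(starts[which(keep)[1]]),
       end = as.integer(ends[tail(which(keep), 1)] + 1L),
       found = TRUE)
}

#' Extract windowed RMS features
#'
#' Computes the per-channel root-mean-square over overlapping windows
#' (default 100 ms length, 50 ms hop): frame t, channel c is the RMS of
#' samples `[(t-1)*hop + 1, (t-1)*hop + window]`.
#'
#' @param recording A `semg_recording` at least one window long.
#' @param window_ms,hop_ms Window length and hop in ms.
#' @param origin_sample Index of the first window's first sample in the
#'   source recording (bookkeeping after segmentation).
#' @return An object of class `semg_features`: list with `frames`
#'   (n_frames x n_channels matrix of RMS values), `window_ms`, `hop_ms`,
#'   `rate_hz`, `origin_sample`.
#' @export
extract_rms <- function(recording, window_ms = 100, hop_ms = 50,
                        origin_sample = 1L) {
  fs <- recording$rate_hz
  win <- round(window_ms * fs / 1000)
  hop <- round(hop_ms * fs / 1000)
  n <- nrow(recording$samples)
  if (n < win)
    stop_invalid("recording (%d samples) shorter than one window (%d)", n, win)
  n_frames <- floor((n - win) / hop) + 1
  sq <- recording$samples^2
  cs <- rbind(0, apply(sq, 2, cumsum))
  starts <- (seq_len(n_frames) - 1) * hop + 1
  frames <- sqrt((cs[starts + win, , drop = FALSE] -
                    cs[starts, , drop = FALSE]) / win)
  colnames(frames) <- colnames(recording$samples)
  structure(list(frames = frames, window_ms = window_ms, hop_ms = hop_ms,
                 rate_hz = fs, origin_sample = as.integer(origin_sample)),
            class = "semg_features")
}

#' @export
print.semg_features <- function(x, ...) {
  cat(sprintf("<semg_features> %d frames x %d channels (window %g ms, hop %g ms)\n",
              nrow(x$frames), ncol(x$frames), x$window_ms, x$hop_ms))
  invisible(x)
}

# Slice a feature sequence by frame indices, keeping metadata.
features_slice <- function(features, idx) {
  structure(list(frames = features$frames[idx, , drop = FALSE],
                 window_ms = features$window_ms, hop_ms = features$hop_ms,
                 rate_hz = features$rate_hz,
                 origin_sample = features$origin_sample),
            class = "semg_features")
}

#' Preprocess a dataset of recordings into labeled feature sequences
#'
#' Convenience pipeline over a [synth_dataset()] tibble: optional band-pass +
#' notch filtering, optional active-segment cropping, then RMS extraction.
#' Ground-truth rear-gesture onset frames (first frame at/after the onset of
#' each gesture after the first) are carried along for latency scoring.
#'
#' @param dataset Tibble with a `recording` list-column (plus label columns).
#' @param filter Apply [filter_semg()] first (default TRUE).
#' @param segment Apply [active_segment()] cropping (default FALSE; synthetic
#'   trials span exactly the action).
#' @param window_ms,hop_ms RMS windowing parameters.
#' @return The input tibble with `recording` replaced by `features`
#'   (list of `semg_features`) plus list-columns `onset_frames` (rear-gesture
#'   onset frame per transition) and `truth` (frame-level truth tibbles).
#' @export
prepare_trials <- function(dataset, filter = TRUE, segment = FALSE,
                           window_ms = 100, hop_ms = 50) {
  hop <- NULL # set per recording below (rates could differ in principle)
  out <- dataset
  feats <- vector("list", nrow(dataset))
  onsets <- vector("list", nrow(dataset))
  truths <- vector("list", nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    rec <- dataset$recording[[i]]
    if (filter) rec <- filter_semg(rec)
    origin <- 1L
    if (segment) {
      seg <- active_segment(rec)
      if (seg$found) {
        rec$samples <- rec$samples[seg$start:(seg$end - 1), , drop = FALSE]
        rec$truth <- rec$truth[seg$start:(seg$end - 1), ]
        origin <- seg$start
      }
    }
    f <- extract_rms(rec, window_ms, hop_ms, origin_sample = origin)
    hop_n <- round(hop_ms * rec$rate_hz / 1000)
    gestures <- dataset$gestures[[i]]
    # onset sample of each rear gesture = first sample of state 4, 7, 10, ...
    key_states <- 3 * seq_len(length(gestures) - 1) + 1
    onset_samples <- vapply(key_states, function(s)
      which(rec$truth$state == s)[1], numeric(1))
    onsets[[i]] <- floor((onset_samples - 1) / hop_n) + 1
    feats[[i]] <- f
    truths[[i]] <- frame_truth(rec, window_ms, hop_ms)
  }
  out$recording <- NULL
  out$features <- feats
  out$onset_frames <- onsets
  out$truth <- truths
  out
}
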