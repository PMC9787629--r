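# Filtering, active-segment detection and RMS extraction.

make_recording <- function(samples, rate_hz = 1000) {
  structure(list(samples = as.matrix(samples), rate_hz = rate_hz,
                 truth = tibble::tibble(sample = seq_len(nrow(as.matrix(samples))),
                                        state = NA_integer_,
                                        gesture = NA_character_),
                 meta = list()),
            class = "semg_recording")
}

sine_recording <- function(freq, n = 4000, rate = 1000) {
  make_recording(matrix(sin(2 * pi * freq * seq_len(n) / rate), ncol = 1), rate)
}

rms_mid <- function(rec) {
  x <- rec$samples[1001:3000, 1]
  sqrt(mean(x^2))
}

test_that("the notch suppresses 50 Hz by at least 20 dB", {
  rec <- sine_recording(50)
  out <- filter_semg(rec)
  att_db <- 20 * log10(rms_mid(out) / rms_mid(rec))
  expect_lte(att_db, -20)
})

test_that("in-band 100 Hz passes within 3 dB", {
  rec <- sine_recording(100)
  out <- filter_semg(rec)
  att_db <- 20 * log10(rms_mid(out) / rms_mid(rec))
  expect_gte(att_db, -3)
  expect_lte(att_db, 3)
})

test_that("filtering is linear-safe on degenerate input and validates", {
  rec <- make_recording(matrix(0, 500, 2))
  out <- filter_semg(rec)
  expect_equal(out$samples, rec$samples, ignore_attr = TRUE)
  expect_error(filter_semg(make_recording(matrix(0, 50, 1))), "short")
  expect_error(filter_semg(sine_recording(50), band_low_hz = 200,
                           band_high_hz = 100), "band")
})

test_that("zero-phase filtering preserves envelope timing", {
  p <- gesture_profiles(8, seed = 4)
  rec <- synthesize_action(p, c("fist", "wrist_flexion"), noise_sd = 0,
                           seed = 2, timing_jitter = 0)
  out <- filter_semg(rec)
  # short-time energy onset of the rear rise stays within one hop
  e_raw <- rowSums(rec$samples^2)
  e_flt <- rowSums(out$samples^2)
  onset <- which(rec$truth$state == 4)[1]
  win <- function(e, at) mean(e[at:(at + 99)])
  # energy ratio at matching positions nearly identical
  expect_equal(win(e_flt, onset) / win(e_raw, onset), 1, tolerance = 0.1)
})

test_that("active segmentation finds onsets within one hop", {
  p <- gesture_profiles(8, seed = 4)
  rec <- synthesize_action(p, c("fist", "wrist_flexion"), rest_ms = 500,
                           seed = 2)
  seg <- active_segment(rec)
  true_onset <- which(rec$truth$state == 1)[1]
  expect_true(seg$found)
  expect_lte(abs(seg$start - true_onset), 50)
  expect_gte(seg$end, which(rec$truth$state == 6)[1])
})

test_that("all-rest input yields an empty flagged range", {
  set.seed(1)
  rec <- make_recording(matrix(rnorm(2000 * 2, sd = 0.05), ncol = 2))
  seg <- active_segment(rec)
  expect_false(seg$found)
  expect_equal(seg$start, seg$end)
})

test_that("a zero threshold fires at the first energy fluctuation", {
  p <- gesture_profiles(8, seed = 4)
  rec <- synthesize_action(p, c("fist", "wrist_flexion"), rest_ms = 500,
                           seed = 2)
  seg <- active_segment(rec, k = 0, min_active_ms = 10)
  expect_true(seg$found)
  expect_lt(seg$start, 400) # inside the leading rest
})

test_that("RMS matches closed forms", {
  # constant signal
  rec <- make_recording(matrix(3, 1000, 1))
  f <- extract_rms(rec)
  expect_true(all(abs(f$frames - 3) < 1e-12))
  # two-sample window at a toy rate: sqrt((9 + 16) / 2)
  toy <- make_recording(matrix(c(3, 4), ncol = 1), rate_hz = 20)
  f2 <- extract_rms(toy, window_ms = 100, hop_ms = 50)
  expect_equal(f2$frames[1, 1], sqrt((9 + 16) / 2), tolerance = 1e-12)
  # frame count: floor((5000 - 100) / 50) + 1
  rec3 <- make_recording(matrix(rnorm(5000), ncol = 1))
  expect_equal(nrow(extract_rms(rec3)$frames), 99)
  expect_error(extract_rms(make_recording(matrix(1, 10, 1))), "window")
})

test_that("RMS is sign-invariant and homogeneous", {
  set.seed(2)
  rec <- make_recording(matrix(rnorm(3000 * 2), ncol = 2))
  f <- extract_rms(rec)
  neg <- rec
  neg$samples <- -neg$samples
  expect_equal(extract_rms(neg)$frames, f$frames)
  dbl <- rec
  dbl$samples <- 2 * dbl$samples
  expect_equal(extract_rms(dbl)$frames, 2 * f$frames, tolerance = 1e-12)
})

test_that("pipeline preserves channel-dominance alignment with ground truth", {
  p <- gesture_profiles(8, seed = 6)
  rec <- synthesize_action(p, c("wrist_extension", "fingers_spread"), seed = 8)
  tr <- prepare_trials(tibble::tibble(
    action_id = "wrist_extension>fingers_spread",
    gestures = list(c("wrist_extension", "fingers_spread")),
    subject = 1, rep = 1, recording = list(rec)))
  f <- tr$features[[1]]
  ft <- tr$truth[[1]]
  steady_front <- which(ft$state == 2)
  steady_front <- steady_front[3:(length(steady_front) - 2)]
  amax <- which.max(p$activation[[match("wrist_extension", p$gesture)]])
  for (i in steady_front)
    expect_equal(unname(which.max(f$frames[i, ])), amax)
  # onset frames recorded for the single transition
  expect_length(tr$onset_frames[[1]], 1)
})
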