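# Model bank construction, multi-gesture pruning, evaluation, experiment.

test_that("the bank has 4 groups of 3 models and tidy summaries", {
  fx <- small_fixture()
  bank <- fx$bank
  expect_s3_class(bank, "model_bank")
  expect_length(bank$models, 12)
  expect_length(bank$groups, 4)
  expect_true(all(lengths(bank$groups) == 3))
  for (g in names(bank$groups))
    for (lab in bank$groups[[g]])
      expect_equal(bank$models[[lab]]$front, g)
  td <- tidy(bank)
  expect_equal(nrow(td), 12)
  gl <- glance(bank)
  expect_equal(gl$n_models, 12)
  expect_true(gl$mean_val_accuracy >= 0 && gl$mean_val_accuracy <= 100)
})

test_that("bank building is deterministic and validates its inputs", {
  fx <- small_fixture()
  sub <- fx$trials[fx$trials$rep <= 5, ]
  b1 <- build_bank(sub, repeats = 1, seed = 7)
  b2 <- build_bank(sub, repeats = 1, seed = 7)
  expect_identical(b1$models[["fist>wrist_flexion"]]$means,
                   b2$models[["fist>wrist_flexion"]]$means)
  # a missing action label is rejected
  broken <- fx$trials[fx$trials$action_id != "fist>wrist_flexion", ]
  expect_error(build_bank(broken, repeats = 1), ">= 5")
})

test_that("training without validation data is flagged but succeeds", {
  fx <- small_fixture()
  sub <- fx$trials[fx$trials$rep <= 5, ]
  b <- build_bank(sub, train_frac = 1, repeats = 1, seed = 3)
  expect_true(b$no_validation)
  expect_true(is.na(b$mean_val_accuracy))
  expect_length(b$models, 12)
})

test_that("pruned decoding predicts four-gesture actions transition by transition", {
  fx <- small_fixture()
  four <- small_four_fixture()
  for (i in seq_len(nrow(four))) {
    ev <- predict_multi(four$features[[i]], fx$bank, window_config())
    true_rears <- four$gestures[[i]][-1]
    expect_gte(nrow(ev), 3)
    expect_equal(ev$predicted_gesture[1:3], true_rears)
    # events in strictly increasing trigger order
    expect_true(all(diff(ev$trigger_frame) > 0))
    # triggers within one window of the true boundaries
    expect_true(all(abs(ev$trigger_frame[1:3] - four$onset_frames[[i]]) <= 20))
    # group binding: each event's front gesture is the previous prediction
    expect_equal(ev$front[2:3], ev$predicted_gesture[1:2])
  }
})

test_that("a two-gesture action reduces predict_multi to predict_action", {
  fx <- small_fixture()
  f <- fx$held$features[[3]]
  single <- predict_action(f, fx$bank, window_config())
  multi <- predict_multi(f, fx$bank, window_config())
  expect_equal(multi$predicted_gesture[1], single$predicted_gesture)
  expect_equal(multi$trigger_frame[1], single$trigger_frame)
})

test_that("disabling pruning degrades later transitions", {
  fx <- small_fixture()
  four <- small_four_fixture()
  pruned <- evaluate_bank(fx$bank, four, window_config(), prune = TRUE)
  ablated <- evaluate_bank(fx$bank, four, window_config(), prune = FALSE)
  expect_gt(pruned$overall$transition_accuracy,
            ablated$overall$transition_accuracy + 30)
  expect_gte(pruned$overall$accuracy, 75)
})

test_that("evaluation bookkeeping conserves trials and counts N/G", {
  fx <- small_fixture()
  ev <- evaluate_bank(fx$bank, fx$held, window_config())
  expect_equal(sum(ev$confusion$count), nrow(fx$held))
  expect_equal(ev$overall$n_trials, nrow(fx$held))
  expect_equal(sum(ev$summary$n), nrow(fx$held))
  # a truncated front-only trial lands in the N/G column but stays in the
  # accuracy denominator
  cut <- fx$held[1, ]
  onset <- cut$onset_frames[[1]][1]
  cut$features[[1]] <- handhmm:::features_slice(cut$features[[1]],
                                                1:(onset - 8))
  both <- dplyr::bind_rows(fx$held[2, ], cut)
  e2 <- evaluate_bank(fx$bank, both, window_config())
  expect_true("N/G" %in% e2$confusion$predicted)
  expect_equal(e2$overall$n_trials, 2)
  expect_lte(e2$overall$accuracy, 50)
})

test_that("key state four triggers earlier than key state five", {
  fx <- small_fixture()
  e4 <- evaluate_bank(fx$bank, fx$held, window_config(key_state = 4))
  e5 <- evaluate_bank(fx$bank, fx$held, window_config(key_state = 5))
  expect_lt(e4$overall$mean_latency_ms, e5$overall$mean_latency_ms)
  expect_gte(e4$overall$accuracy, 95)
  expect_gte(e5$overall$accuracy, 95)
})

test_that("evaluation reports tidy, glance and plot without error", {
  fx <- small_fixture()
  ev <- evaluate_bank(fx$bank, fx$held[1:6, ], window_config())
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1)
  pl <- autoplot(ev)
  expect_s3_class(pl, "ggplot")
  pf <- autoplot(fx$held$features[[1]])
  expect_s3_class(pf, "ggplot")
})

test_that("run_experiment produces reproducible artifacts from a config", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- list(seed = 4, reps_two = 5, reps_four = 2, repeats = 1,
              subject_seeds = 11, run_no_pruning = TRUE)
  r1 <- run_experiment(c(cfg, list(out_dir = dir1)))
  r2 <- run_experiment(c(cfg, list(out_dir = dir2)))
  for (f in c("bank.txt", "two_gesture_summary.tsv", "four_gesture_summary.tsv",
              "two_gesture_confusion.tsv", "overall.tsv", "config_resolved.yaml"))
    expect_true(file.exists(file.path(dir1, f)))
  expect_identical(readLines(file.path(dir1, "overall.tsv")),
                   readLines(file.path(dir2, "overall.tsv")))
  expect_identical(readLines(file.path(dir1, "bank.txt")),
                   readLines(file.path(dir2, "bank.txt")))
  # malformed config fails before computing anything
  expect_error(run_experiment(list(bogus_key = 1)), "unknown config")
})
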