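# HMM core: emissions, forward likelihood, Viterbi, Baum-Welch.

test_that("emission log-densities match closed forms", {
  m <- handhmm:::new_action_model("a", "b", c(1, 0), diag(2),
                                  means = matrix(c(0, 5), 2, 1),
                                  variances = matrix(1, 2, 1),
                                  mask = matrix(TRUE, 2, 2))
  expect_equal(emission_logdensity(m, 1, 0), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  m$variances[1, 1] <- 2.5
  expect_equal(emission_logdensity(m, 1, 0), -0.5 * log(2 * pi * 2.5),
               tolerance = 1e-12)
  # diagonal 2-D density = sum of 1-D log-densities
  m2 <- handhmm:::new_action_model("a", "b", c(1, 0), diag(2),
                                   means = matrix(c(1, 2, -1, 0), 2, 2),
                                   variances = matrix(c(1, 2, 3, 4), 2, 2),
                                   mask = matrix(TRUE, 2, 2))
  obs <- c(0.3, -0.7)
  expect_equal(emission_logdensity(m2, 1, obs),
               dnorm(0.3, 1, 1, log = TRUE) + dnorm(-0.7, -1, sqrt(3), log = TRUE),
               tolerance = 1e-12)
  expect_error(emission_logdensity(m2, 1, c(1, 2, 3)), "length")
})

test_that("forward log-likelihood matches brute-force path enumeration", {
  set.seed(10)
  for (rep in 1:20) {
    N <- sample(2:3, 1)
    Tn <- sample(2:6, 1)
    m <- random_toy_model(N)
    obs <- matrix(rnorm(Tn, sd = 3), ncol = 1)
    expect_equal(sequence_loglik(m, obs), brute_loglik(m, obs),
                 tolerance = 1e-10)
  }
})

test_that("forward base cases reduce correctly", {
  m <- random_toy_model(3)
  o1 <- matrix(0.5, 1, 1)
  direct <- log(sum(m$pi * exp(vapply(1:3, function(i)
    emission_logdensity(m, i, 0.5), numeric(1)))))
  expect_equal(sequence_loglik(m, o1), direct, tolerance = 1e-12)
  # left-to-right pi: first-frame contribution is b_1(o_1) alone
  m$pi <- c(1, 0, 0)
  expect_equal(sequence_loglik(m, o1), emission_logdensity(m, 1, 0.5),
               tolerance = 1e-12)
})

test_that("Viterbi recovers the brute-force argmax path", {
  # the worked 2-state instance
  m <- handhmm:::new_action_model(
    "a", "b", pi = c(0.6, 0.4),
    trans = matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE),
    means = matrix(c(0, 5), 2, 1), variances = matrix(1, 2, 1),
    mask = matrix(TRUE, 2, 2))
  obs <- matrix(c(0.1, 4.9, 5.2), ncol = 1)
  v <- viterbi_decode(m, obs)
  expect_equal(v$path, c(1, 2, 2))
  bf <- brute_viterbi(m, obs)
  expect_equal(v$logprob, bf$logprob, tolerance = 1e-12)
  # T = 1 base case
  v1 <- viterbi_decode(m, matrix(0.2, 1, 1))
  expect_equal(v1$path, 1)
  # random instances
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(2:3, 1)
    Tn <- sample(2:6, 1)
    mr <- random_toy_model(N)
    o <- matrix(rnorm(Tn, sd = 3), ncol = 1)
    vr <- viterbi_decode(mr, o)
    br <- brute_viterbi(mr, o)
    expect_equal(vr$logprob, br$logprob, tolerance = 1e-10)
    expect_equal(vr$path, br$path)
  }
})

test_that("forward likelihood dominates the best path probability", {
  set.seed(12)
  for (rep in 1:15) {
    m <- random_toy_model(3)
    o <- matrix(rnorm(5, sd = 2), ncol = 1)
    expect_gte(sequence_loglik(m, o), viterbi_decode(m, o)$logprob - 1e-12)
  }
})

test_that("Baum-Welch respects topology, improves monotonically, and is deterministic", {
  fx <- small_fixture()
  rows <- which(fx$trials$action_id == "fist>wrist_flexion")
  seqs <- fx$trials$features[rows]
  m <- fit_action_hmm(seqs, front = "fist", rear = "wrist_flexion")
  # row-stochastic within tolerance, masked entries exactly zero
  expect_equal(rowSums(m$trans), rep(1, 6), tolerance = 1e-9)
  expect_true(all(m$trans[lower.tri(m$trans)] == 0))
  expect_equal(m$pi, c(1, 0, 0, 0, 0, 0))
  expect_true(all(m$variances > 0))
  # monotone non-decreasing log-likelihood trace
  expect_true(all(diff(m$loglik_trace) >= -1e-8 * abs(m$loglik_trace[-m$n_iter])))
  # determinism
  m2 <- fit_action_hmm(seqs, front = "fist", rear = "wrist_flexion")
  expect_identical(m$means, m2$means)
  expect_identical(m$trans, m2$trans)
  # sequential topology restricts jumps
  ms <- fit_action_hmm(seqs, transitions = "sequential")
  expect_true(all(ms$trans[col(ms$trans) - row(ms$trans) > 1] == 0))
  expect_error(fit_action_hmm(list()), "at least 2")
})

test_that("training recovers the generating state means", {
  fx <- small_fixture()
  rows <- which(fx$trials$action_id == "fingers_spread>wrist_extension")
  seqs <- fx$trials$features[rows]
  m <- fit_action_hmm(seqs, front = "fingers_spread", rear = "wrist_extension")
  # oracle: empirical per-state means of the frames grouped by ground truth
  truth_means <- matrix(0, 6, 8)
  counts <- rep(0, 6)
  for (r in rows) {
    ft <- fx$trials$truth[[r]]
    f <- fx$trials$features[[r]]
    for (s in 1:6) {
      idx <- which(ft$state == s)
      truth_means[s, ] <- truth_means[s, ] + colSums(f$frames[idx, , drop = FALSE])
      counts[s] <- counts[s] + length(idx)
    }
  }
  truth_means <- truth_means / counts
  for (s in 1:6) {
    rel <- sqrt(sum((m$means[s, ] - truth_means[s, ])^2)) /
      sqrt(sum(truth_means[s, ]^2))
    expect_lt(rel, 0.10)
  }
})

test_that("degenerate near-constant sequences engage the variance floor", {
  const <- lapply(1:3, function(i) matrix(2, 30, 2) + 1e-9 * i)
  m <- fit_action_hmm(const, n_states = 6)
  expect_true(all(is.finite(m$loglik)))
  expect_true(all(m$variances > 0))
})

test_that("models round-trip bit-exactly through text serialization", {
  fx <- small_fixture()
  path <- withr::local_tempfile(fileext = ".txt")
  write_model_bank(fx$bank, path)
  back <- read_model_bank(path)
  expect_identical(names(back$models), names(fx$bank$models))
  for (lab in names(back$models)) {
    expect_identical(back$models[[lab]]$means, fx$bank$models[[lab]]$means)
    expect_identical(back$models[[lab]]$variances,
                     fx$bank$models[[lab]]$variances)
    expect_identical(back$models[[lab]]$trans, fx$bank$models[[lab]]$trans)
    expect_identical(back$models[[lab]]$pi, fx$bank$models[[lab]]$pi)
  }
  expect_identical(lapply(back$groups, sort), lapply(fx$bank$groups, sort))
})

test_that("tidy and glance summarize fitted models", {
  fx <- small_fixture()
  m <- fx$bank$models[[1]]
  td <- tidy(m)
  expect_equal(nrow(td), 6 * 8)
  expect_true(all(c("state", "phase", "channel", "mean", "variance") %in% names(td)))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged %in% c(TRUE, FALSE))
})
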