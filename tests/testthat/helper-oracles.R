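# Independent brute-force oracles and shared fixtures.

# Log-probability of every one of the N^T state paths, by enumeration.
brute_path_logprobs <- function(model, obs) {
  obs <- if (is.matrix(obs)) obs else matrix(obs, ncol = model$n_channels)
  Tn <- nrow(obs)
  N <- model$n_states
  logB <- vapply(seq_len(N), function(i)
    vapply(seq_len(Tn), function(t)
      emission_logdensity(model, i, obs[t, ]), numeric(1)),
    numeric(Tn))
  logB <- matrix(logB, nrow = Tn)
  logA <- log(model$trans)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  lp <- log(model$pi[paths[, 1]]) + logB[cbind(1, paths[, 1])]
  for (t in seq_len(Tn - 1))
    lp <- lp + logA[cbind(paths[, t], paths[, t + 1])] +
      logB[cbind(t + 1, paths[, t + 1])]
  list(paths = paths, logprobs = lp)
}

# Exhaustive sum over all state paths: log P(O | model).
brute_loglik <- function(model, obs) {
  lp <- brute_path_logprobs(model, obs)$logprobs
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Exhaustive max over all state paths; ties resolved toward the
# lexicographically smallest path (matches lowest-state-index tie-breaking).
brute_viterbi <- function(model, obs) {
  bp <- brute_path_logprobs(model, obs)
  ord <- do.call(order, c(as.list(as.data.frame(bp$paths)),
                          list(decreasing = FALSE)))
  paths <- bp$paths[ord, , drop = FALSE]
  lp <- bp$logprobs[ord]
  best <- which(lp > max(lp) - 1e-12)[1]
  list(path = unname(paths[best, ]), logprob = lp[best])
}

# Random fully-parameterized toy model (no mask; all transitions positive).
random_toy_model <- function(n_states, n_channels = 1) {
  pi <- runif(n_states) + 0.05
  pi <- pi / sum(pi)
  A <- matrix(runif(n_states^2) + 0.05, n_states)
  A <- A / rowSums(A)
  means <- matrix(rnorm(n_states * n_channels, sd = 3), n_states)
  vars <- matrix(runif(n_states * n_channels, 0.3, 2), n_states)
  handhmm:::new_action_model("a", "b", pi, A, means, vars,
                             mask = matrix(TRUE, n_states, n_states))
}

# Session-cached fixtures (built once; reused across test files).
.fixtures <- new.env(parent = emptyenv())

# Small but complete pipeline fixture: 12 actions x 6 reps x 2 subjects,
# one training repeat. Enough data for end-to-end behavior without the
# acceptance-scale runtime.
small_fixture <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  profiles <- gesture_profiles(8, seed = 42)
  trials <- synth_dataset(profiles, reps = 6, subject_seeds = c(11L, 22L),
                          seed = 42) |>
    prepare_trials()
  bank <- build_bank(trials, repeats = 1, seed = 42)
  held <- trials[bank$held_out$row, ]
  .fixtures$small <- list(profiles = profiles, trials = trials, bank = bank,
                          held = held)
  .fixtures$small
}

# Four-gesture trials matching the small fixture's profiles.
small_four_fixture <- function() {
  if (!is.null(.fixtures$four)) return(.fixtures$four)
  fx <- small_fixture()
  actions <- four_gesture_actions()
  rows <- list()
  for (a in seq_along(actions)) {
    for (r in 1:4) {
      s <- (r - 1) %% 2 + 1
      prof_s <- jitter_profiles(fx$profiles, c(11L, 22L)[s])
      rec <- synthesize_action(prof_s, actions[[a]],
                               seed = 9000 + 10 * a + r)
      rows[[length(rows) + 1]] <- tibble::tibble(
        action_id = names(actions)[a], gestures = list(actions[[a]]),
        subject = s, rep = r, recording = list(rec))
    }
  }
  .fixtures$four <- prepare_trials(dplyr::bind_rows(rows))
  .fixtures$four
}
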