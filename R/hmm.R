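# Six-state left-to-right Gaussian-emission HMMs: model type, emission
# densities, Baum-Welch training, forward log-likelihood and Viterbi.
# All probability computation is in the log domain.

#' Left-to-right transition mask
#'
#' @param n_states Number of states.
#' @param transitions `"forward"` (self-transitions plus all forward jumps,
#'   i.e. the upper triangle — the default reading of a fully connected
#'   left-to-right topology) or `"sequential"` (self and next state only).
#' @return A logical n x n matrix of allowed transitions.
#' @export
lr_mask <- function(n_states = 6, transitions = c("forward", "sequential")) {
  transitions <- match.arg(transitions)
  m <- upper.tri(diag(n_states), diag = TRUE)
  if (transitions == "sequential")
    m <- m & (col(m) - row(m) <= 1)
  m
}

new_action_model <- function(front, rear, pi, trans, means, variances, mask,
                             loglik = NA_real_, loglik_trace = numeric(),
                             n_iter = NA_integer_, converged = NA) {
  structure(list(front = front, rear = rear,
                 n_states = nrow(trans), n_channels = ncol(means),
                 pi = pi, trans = trans, means = means, variances = variances,
                 mask = mask, loglik = loglik, loglik_trace = loglik_trace,
                 n_iter = n_iter, converged = converged),
            class = "action_model")
}

#' @export
print.action_model <- function(x, ...) {
  cat(sprintf("<action_model> %s > %s: %d states, %d channels, loglik %.2f (%s)\n",
              x$front, x$rear, x$n_states, x$n_channels, x$loglik,
              if (isTRUE(x$converged)) "converged" else "max_iter"))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (inherits(x, "semg_features")) x$frames
  else if (is.matrix(x)) x
  else stop_invalid("expected an `semg_features` object or a matrix")
}

# T x N matrix of diagonal-Gaussian emission log-densities.
emission_logB <- function(model, obs) {
  obs <- as_feature_matrix(obs)
  if (ncol(obs) != model$n_channels)
    stop_invalid("observation has %d channels, model expects %d",
                 ncol(obs), model$n_channels)
  N <- model$n_states
  out <- matrix(0, nrow(obs), N)
  for (i in seq_len(N)) {
    v <- model$variances[i, ]
    m <- model$means[i, ]
    const <- -0.5 * sum(log(2 * pi * v))
    quad <- sweep(obs, 2, m)^2
    out[, i] <- const - 0.5 * as.vector(quad %*% (1 / v))
  }
  out
}

#' Per-state Gaussian emission log-density
#'
#' Log of the diagonal-covariance Gaussian density of one observation vector
#' under one state of an action model.
#'
#' @param model An `action_model`.
#' @param state State index (1..n_states).
#' @param obs Numeric feature vector of length `n_channels`.
#' @return The log-density (scalar).
#' @export
emission_logdensity <- function(model, state, obs) {
  if (length(obs) != model$n_channels)
    stop_invalid("obs has length %d, model expects %d",
                 length(obs), model$n_channels)
  v <- model$variances[state, ]
  m <- model$means[state, ]
  sum(stats::dnorm(obs, m, sqrt(v), log = TRUE))
}

#' Forward log-likelihood of a feature sequence
#'
#' @param model An `action_model`.
#' @param features An `semg_features` object or frames matrix.
#' @return log P(O | model) via the forward algorithm.
#' @export
sequence_loglik <- function(model, features) {
  logB <- emission_logB(model, features)
  fb <- hmm_forward_backward(logB, log(model$trans), log(model$pi))
  fb$loglik
}

#' Classic Viterbi decoding of a full feature sequence
#'
#' Max-product decoding in the log domain. The returned final delta vector is
#' the per-state maximum-path log-probability at the last frame (the quantity
#' the windowed decoder hands across windows).
#'
#' @param model An `action_model`.
#' @param features An `semg_features` object or frames matrix.
#' @return A list with `path` (integer states), `logdelta_T` (length
#'   n_states), `logprob` (best-path log-probability).
#' @export
viterbi_decode <- function(model, features) {
  logB <- emission_logB(model, features)
  init <- log(model$pi) + logB[1, ]
  hmm_viterbi(logB, log(model$trans), init)
}

# Pooled segment-based initialization: each sequence is split into n_states
# contiguous blocks whose relative durations follow `fracs`; block k across
# all sequences initializes state k. The default fractions encode the
# temporal structure of the states: transition phases (rising/declining) are
# much shorter than stabilization, ~300 ms of a 2500 ms gesture segment,
# i.e. 12% / 76% / 12% of each half. Equal-duration initialization tends to
# converge to a local optimum in which the rear-rise state's variance
# engulfs near-rest amplitudes, which then mistakes any terminal decline
# for a rising transition; the phase-proportioned split avoids it.
init_fractions <- function(n_states) {
  if (n_states %% 3 == 0)
    rep(c(0.12, 0.76, 0.12), n_states / 3) / (n_states / 3)
  else rep(1 / n_states, n_states)
}

init_emissions <- function(mats, n_states, var_floor, fracs = NULL) {
  if (is.null(fracs)) fracs <- init_fractions(n_states)
  stopifnot(length(fracs) == n_states)
  bounds <- c(0, cumsum(fracs) / sum(fracs))
  C <- ncol(mats[[1]])
  means <- matrix(0, n_states, C)
  vars <- matrix(0, n_states, C)
  for (k in seq_len(n_states)) {
    blocks <- lapply(mats, function(m) {
      Tn <- nrow(m)
      idx <- seq.int(floor(bounds[k] * Tn) + 1, max(floor(bounds[k + 1] * Tn), floor(bounds[k] * Tn) + 1))
      m[idx, , drop = FALSE]
    })
    pooled <- do.call(rbind, blocks)
    means[k, ] <- colMeans(pooled)
    vars[k, ] <- pmax(apply(pooled, 2, var), var_floor)
  }
  list(means = means, variances = vars)
}

#' Fit a six-state left-to-right action model by Baum-Welch
#'
#' Expectation-maximization for a Gaussian-emission HMM on a masked
#' left-to-right topology. The initial state distribution is pinned to state
#' one (all actions start in the front gesture's rising transition) and is
#' not re-estimated. Emissions are initialized from equal-duration segment
#' statistics (matching the known temporal order of the states); allowed
#' transitions start uniform. Per-iteration total log-likelihood is monotone
#' non-decreasing; a variance floor prevents collapse on near-constant
#' steady phases.
#'
#' @param sequences List (>= 2) of `semg_features` objects or frame matrices,
#'   each at least `n_states` frames long.
#' @param front,rear Gesture labels of the modeled action.
#' @param n_states Number of hidden states (default 6).
#' @param transitions Topology, see [lr_mask()].
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood improvement below which EM stops.
#' @param var_floor_frac Variance floor as a fraction of the overall
#'   per-channel training variance.
#' @param init_fracs Optional per-state duration fractions for the
#'   segment-based initialization; defaults to a phase-proportioned split
#'   (12% rising / 76% steady / 12% declining per gesture half) when
#'   `n_states` is a multiple of 3, else equal durations.
#' @param seed Unused source of randomness kept for interface stability; the
#'   fit is fully deterministic.
#' @return An `action_model` with the fitted parameters, final total
#'   log-likelihood, its per-iteration trace, and convergence info.
#' @export
fit_action_hmm <- function(sequences, front = NA_character_,
                           rear = NA_character_, n_states = 6,
                           transitions = c("forward", "sequential"),
                           max_iter = 100, tol = 1e-6,
                           var_floor_frac = 1e-6, init_fracs = NULL,
                           seed = 1) {
  transitions <- match.arg(transitions)
  if (length(sequences) < 2)
    stop_invalid("need at least 2 training sequences")
  mats <- lapply(sequences, as_feature_matrix)
  if (any(vapply(mats, nrow, 0L) < n_states))
    stop_invalid("every sequence must have at least %d frames", n_states)

  C <- ncol(mats[[1]])
  pooled_var <- apply(do.call(rbind, mats), 2, var)
  var_floor <- pmax(var_floor_frac * pooled_var, 1e-10)

  mask <- lr_mask(n_states, transitions)
  trans <- mask / rowSums(mask)
  pi <- c(1, rep(0, n_states - 1))
  em <- init_emissions(mats, n_states, var_floor, fracs = init_fracs)
  means <- em$means
  variances <- em$variances

  logpi <- log(pi)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  model <- new_action_model(front, rear, pi, trans, means, variances, mask)

  for (iter in seq_len(max_iter)) {
    logA <- log(model$trans)
    ll_total <- 0
    g_sum <- rep(0, n_states)
    ob_sum <- matrix(0, n_states, C)
    sq_sum <- matrix(0, n_states, C)
    xi_tot <- matrix(0, n_states, n_states)
    for (m in mats) {
      logB <- emission_logB(model, m)
      fb <- hmm_forward_backward(logB, logA, logpi)
      ll_total <- ll_total + fb$loglik
      g <- fb$gamma
      g_sum <- g_sum + colSums(g)
      ob_sum <- ob_sum + t(g) %*% m
      sq_sum <- sq_sum + t(g) %*% (m^2)
      xi_tot <- xi_tot + fb$xi_sum
    }
    ll_trace <- c(ll_trace, ll_total)

    # M-step
    new_trans <- model$trans
    for (i in seq_len(n_states)) {
      tot <- sum(xi_tot[i, ])
      if (tot > 0) new_trans[i, ] <- xi_tot[i, ] / tot
    }
    new_trans[!mask] <- 0
    new_means <- model$means
    new_vars <- model$variances
    for (i in seq_len(n_states)) {
      if (g_sum[i] > 1e-8) {
        mu <- ob_sum[i, ] / g_sum[i]
        new_means[i, ] <- mu
        new_vars[i, ] <- pmax(sq_sum[i, ] / g_sum[i] - mu^2, var_floor)
      }
    }
    model$trans <- new_trans
    model$means <- new_means
    model$variances <- new_vars

    if (is.finite(ll_prev) &&
        (ll_total - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll_total
  }

  model$loglik <- tail(ll_trace, 1)
  model$loglik_trace <- ll_trace
  model$n_iter <- length(ll_trace)
  model$converged <- converged
  model
}

#' @rdname tidy.action_model
#' @export
glance.action_model <- function(x, ...) {
  tibble::tibble(front = x$front, rear = x$rear, n_states = x$n_states,
                 n_channels = x$n_channels, loglik = x$loglik,
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy an action model's emission parameters
#'
#' `tidy()` returns one row per (state, channel) with the fitted emission
#' mean and variance and the state's phase label; `glance()` returns a
#' one-row fit summary.
#'
#' @param x An `action_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.action_model <- function(x, ...) {
  N <- x$n_states
  C <- x$n_channels
  phases <- if (N == 6) STATE_PHASES else as.character(seq_len(N))
  tibble::tibble(
    state = rep(seq_len(N), each = C),
    phase = rep(phases, each = C),
    channel = rep(seq_len(C), N),
    mean = as.vector(t(x$means)),
    variance = as.vector(t(x$variances))
  )
}
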