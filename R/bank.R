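# Model bank: the 12 action models (all ordered pairs of the 4 gestures)
# organized into 4 gesture groups sharing the same front gesture.

#' Build a model bank from labeled two-gesture feature sequences
#'
#' For each of the 12 two-gesture actions, fits a six-state model on a random
#' `train_frac` split, repeated `repeats` times with reseeded splits, and
#' retains the repeat with the best mean validation log-likelihood. Each
#' repeat uses one shared partition of repetition indices across actions so
#' repeat-level validation accuracy (classification of held-out sequences by
#' maximum full-sequence likelihood over that repeat's 12 models) is well
#' defined; the mean over repeats is reported.
#'
#' @param trials A tibble from [prepare_trials()] with columns `action_id`,
#'   `gestures` (length-2 sequences) and `features`; every one of the 12
#'   action labels needs at least 5 sequences.
#' @param train_frac Fraction of each action's sequences used for training
#'   (default 0.8). With `train_frac = 1` the validation report is flagged
#'   empty and training proceeds on everything.
#' @param repeats Number of reseeded splits per action (default 10).
#' @param seed Integer seed driving all splits.
#' @param transitions,max_iter,tol Passed to [fit_action_hmm()].
#' @return A `model_bank`: named list of 12 `action_model`s, `groups`
#'   (front gesture -> model names), a `validation` tibble, `held_out`
#'   (rows of `trials` held out from their own action's chosen repeat) and
#'   `mean_val_accuracy`.
#' @export
build_bank <- function(trials, train_frac = 0.8, repeats = 10, seed = 1,
                       transitions = "forward", max_iter = 100, tol = 1e-6) {
  assert_count(repeats, "repeats", min = 1)
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac > 1)
    stop_invalid("`train_frac` must be in (0, 1]")
  if (any(lengths(trials$gestures) != 2))
    stop_invalid("bank training expects two-gesture actions")

  fronts <- vapply(trials$gestures, `[`, "", 1)
  rears <- vapply(trials$gestures, `[`, "", 2)
  labels <- paste(fronts, rears, sep = ">")
  grid <- expand.grid(rear = HAND_GESTURES, front = HAND_GESTURES,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$front != grid$rear, c("front", "rear")]
  wanted <- paste(grid$front, grid$rear, sep = ">")
  counts <- table(factor(labels, levels = wanted))
  if (any(counts < 5))
    stop_invalid("every action label needs >= 5 sequences; missing/short: %s",
                 paste(names(counts)[counts < 5], collapse = ", "))

  rows_by_label <- split(seq_len(nrow(trials)), factor(labels, levels = wanted))
  no_validation <- train_frac >= 1

  # one split per (repeat, action); candidate models + per-repeat accuracy
  candidates <- vector("list", repeats)
  val_rows <- list()
  for (r in seq_len(repeats)) {
    models_r <- vector("list", length(wanted))
    names(models_r) <- wanted
    val_idx_r <- vector("list", length(wanted))
    names(val_idx_r) <- wanted
    for (lab in wanted) {
      rows <- rows_by_label[[lab]]
      n <- length(rows)
      n_train <- if (no_validation) n else max(2, round(train_frac * n))
      perm <- with_local_seed(derive_seed(seed, r, match(lab, wanted)),
                              sample.int(n))
      tr_rows <- rows[perm[seq_len(n_train)]]
      val_rows_lab <- if (n_train < n) rows[perm[(n_train + 1):n]] else integer()
      lab_front <- strsplit(lab, ">", fixed = TRUE)[[1]][1]
      lab_rear <- strsplit(lab, ">", fixed = TRUE)[[1]][2]
      models_r[[lab]] <- fit_action_hmm(
        trials$features[tr_rows], front = lab_front, rear = lab_rear,
        transitions = transitions, max_iter = max_iter, tol = tol)
      val_idx_r[[lab]] <- val_rows_lab
    }
    # repeat-level validation: classify held-out sequences by max loglik
    all_val <- unlist(val_idx_r, use.names = FALSE)
    acc_r <- NA_real_
    if (length(all_val)) {
      pred <- vapply(all_val, function(i) {
        lls <- vapply(models_r, sequence_loglik,
                      numeric(1), features = trials$features[[i]])
        names(which.max(lls))
      }, "")
      acc_r <- mean(pred == labels[all_val]) * 100
    }
    vll <- vapply(wanted, function(lab) {
      vi <- val_idx_r[[lab]]
      if (!length(vi)) return(NA_real_)
      mean(vapply(vi, function(i)
        sequence_loglik(models_r[[lab]], trials$features[[i]]), numeric(1)))
    }, numeric(1))
    candidates[[r]] <- list(models = models_r, val_idx = val_idx_r,
                            val_loglik = vll, accuracy = acc_r)
    val_rows[[r]] <- tibble::tibble(repeat_id = r, action_id = wanted,
                                    val_loglik = vll, val_accuracy = acc_r)
  }

  validation <- dplyr::bind_rows(val_rows)
  models <- vector("list", length(wanted))
  names(models) <- wanted
  held_out <- list()
  for (lab in wanted) {
    vlls <- vapply(candidates, function(cc) cc$val_loglik[[lab]], numeric(1))
    best_r <- if (all(is.na(vlls))) 1L else which.max(vlls)
    models[[lab]] <- candidates[[best_r]]$models[[lab]]
    vi <- candidates[[best_r]]$val_idx[[lab]]
    if (length(vi))
      held_out[[lab]] <- tibble::tibble(action_id = lab, row = vi,
                                        repeat_id = best_r)
  }
  groups <- split(wanted, grid$front)

  structure(list(
    models = models,
    groups = groups,
    validation = validation,
    held_out = dplyr::bind_rows(held_out),
    mean_val_accuracy = if (no_validation) NA_real_
                        else mean(validation$val_accuracy[!duplicated(validation$repeat_id)]),
    no_validation = no_validation,
    config = list(train_frac = train_frac, repeats = repeats, seed = seed,
                  transitions = transitions)
  ), class = "model_bank")
}

#' @export
print.model_bank <- function(x, ...) {
  cat(sprintf("<model_bank> %d models in %d groups; mean validation accuracy %s\n",
              length(x$models), length(x$groups),
              if (is.na(x$mean_val_accuracy)) "n/a"
              else sprintf("%.1f%%", x$mean_val_accuracy)))
  invisible(x)
}

#' @rdname tidy.model_bank
#' @export
glance.model_bank <- function(x, ...) {
  tibble::tibble(n_models = length(x$models), n_groups = length(x$groups),
                 mean_val_accuracy = x$mean_val_accuracy,
                 repeats = x$config$repeats, train_frac = x$config$train_frac)
}

#' Tidy a model bank
#'
#' `tidy()` returns one row per model with its group and fit summary;
#' `glance()` a one-row bank summary.
#'
#' @param x A `model_bank`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.model_bank <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, glance)) |>
    dplyr::mutate(action_id = names(x$models),
                  group = .data$front, .before = 1)
}
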