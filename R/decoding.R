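#' Per-sequence target responses
#'
#' Element-wise mean of the binarized training states per sequence (the
#' supervised "target" response); values lie in `[0, 1]` per unit.
#'
#' @param train a [state_table()] with >= 1 repetition per sequence.
#' @return Matrix, one row per sequence id (row order = increasing id).
#' @export
target_responses <- function(train) {
  ids <- sort(unique(train$sequence_id))
  out <- t(vapply(ids, function(i)
    colMeans(train$binary[train$sequence_id == i, , drop = FALSE]),
    numeric(ncol(train$binary))))
  rownames(out) <- ids
  out
}

#' L1 nearest-target classification
#'
#' Predicts the sequence whose target response has the minimum L1 (taxicab)
#' distance to the given state; exact ties go to the lowest sequence id.
#'
#' @param state binary (or fractional) state vector.
#' @param targets matrix from [target_responses()].
#' @return The predicted sequence id (integer).
#' @export
classify_l1 <- function(state, targets) {
  if (is.null(dim(targets)) || nrow(targets) == 0) stop("data error: no targets")
  if (length(state) != ncol(targets))
    stop("structural error: state/target dimension mismatch")
  d <- rowSums(abs(sweep(targets, 2, state)))
  as.integer(rownames(targets)[which.min(d)])
}

#' Confusion matrix from a test table
#'
#' Column `j` holds the empirical distribution of predicted sequences over
#' the test repetitions of sequence `j`; every column sums to 1. Entry
#' `(i, j)` is the probability that test sequence `j` is predicted as target
#' sequence `i`.
#'
#' @param test a [state_table()].
#' @param targets matrix from [target_responses()].
#' @param use `"binary"` (default) or `"rates"`: which representation of the
#'   test states to classify.
#' @return A column-stochastic square matrix of class `confusion_matrix`.
#' @export
confusion <- function(test, targets, use = c("binary", "rates")) {
  use <- match.arg(use)
  ids <- as.integer(rownames(targets))
  C <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  X <- if (use == "binary") test$binary else test$rates
  for (j in seq_along(ids)) {
    rows <- which(test$sequence_id == ids[j])
    if (length(rows) == 0) stop("data error: sequence ", ids[j], " missing from test table")
    for (rr in rows) {
      pred <- classify_l1(X[rr, ], targets)
      C[match(pred, ids), j] <- C[match(pred, ids), j] + 1
    }
    C[, j] <- C[, j] / length(rows)
  }
  structure(C, class = c("confusion_matrix", "matrix"))
}

#' Discrimination ability
#'
#' Chance-corrected classification score derived from the confusion matrix:
#' `kappa = 1 - mean error rate / (1 - 1/N_seq)`, where the mean error rate
#' is one minus the mean of the diagonal. A perfect confusion matrix gives 1,
#' chance-level guessing gives 0; values are clipped to `[0, 1]`.
#'
#' @param C a square column-stochastic confusion matrix.
#' @return `kappa` in `[0, 1]`.
#' @export
kappa <- function(C) {
  n <- nrow(C)
  if (is.null(n) || n != ncol(C)) stop("parameter error: confusion matrix must be square")
  if (n < 2) stop("parameter error: kappa is undefined for a single sequence")
  mean_err <- 1 - mean(diag(C))
  min(1, max(0, 1 - mean_err / (1 - 1 / n)))
}

#' Rescale a confusion-matrix metric
#'
#' Affine rescaling `(F - F_chance) / (F_perfect - F_chance)`: 0 at chance,
#' 1 at a perfect (identity) confusion matrix.
#'
#' @param F_value metric value on the observed matrix.
#' @param F_chance metric value on the uniform (chance) matrix.
#' @param F_perfect metric value on the identity matrix.
#' @return The rescaled score.
#' @export
rescale_metric <- function(F_value, F_chance, F_perfect) {
  if (F_perfect == F_chance)
    stop("parameter error: degenerate rescaling (F_perfect == F_chance)")
  (F_value - F_chance) / (F_perfect - F_chance)
}

#' Train a perceptron readout
#'
#' Classic perceptron rule: zero-initialized weights and bias, fixed learning
#' rate, examples visited in a fixed shuffled order per epoch, updates
#' `w <- w + lr * y * x` on every misclassified example (labels recoded to
#' -1/+1), until an epoch with no updates or `max_epochs`. Deterministic
#' given the shuffle seed and data order.
#'
#' @param X numeric matrix of states (rows = examples).
#' @param y binary labels (0/1 or logical), one per row.
#' @param learning_rate positive step size.
#' @param max_epochs maximum passes over the data.
#' @param shuffle_seed seed fixing the within-epoch example order.
#' @return An object of class `perceptron`: `w`, `b`, `epochs`, `converged`.
#' @export
train_perceptron <- function(X, y, learning_rate = 1, max_epochs = 1000,
                             shuffle_seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("structural error: label/state count mismatch")
  if (length(unique(y)) < 2)
    stop("data error: perceptron training needs both classes present")
  ypm <- ifelse(y == 1L, 1, -1)
  w <- rep(0, ncol(X)); b <- 0
  ord <- with_rng_seed(shuffle_seed, sample.int(nrow(X)))
  epochs <- 0L; converged <- FALSE
  while (epochs < max_epochs) {
    epochs <- epochs + 1L
    updated <- FALSE
    for (i in ord) {
      sc <- sum(w * X[i, ]) + b
      if (ypm[i] * sc <= 0) {
        w <- w + learning_rate * ypm[i] * X[i, ]
        b <- b + learning_rate * ypm[i]
        updated <- TRUE
      }
    }
    if (!updated) { converged <- TRUE; break }
  }
  structure(list(w = w, b = b, epochs = epochs, converged = converged),
            class = "perceptron")
}

#' @rdname train_perceptron
#' @param model a trained `perceptron`.
#' @param newdata matrix of states to classify.
#' @return `predict_perceptron` returns 0/1 predictions (score > 0 maps
#'   to 1).
#' @export
predict_perceptron <- function(model, newdata) {
  as.integer(as.matrix(newdata) %*% model$w + model$b > 0)
}

#' Majority ("correct choice") labels for two-type sequences
#'
#' 1 if the sequence contains more type-1 ("left") stimuli, 2 if more type-2,
#' `NA` for tie sequences (equal counts), which are excluded from choice
#' training and scoring.
#'
#' @param sequences integer matrix of type ids in `{1, 2}`.
#' @return Integer vector with `NA` at ties.
#' @export
majority_labels <- function(sequences) {
  n1 <- rowSums(sequences == 1L)
  n2 <- rowSums(sequences == 2L)
  out <- ifelse(n1 > n2, 1L, ifelse(n2 > n1, 2L, NA_integer_))
  as.integer(out)
}

#' Two-choice decision accuracy of a perceptron readout
#'
#' Applies the readout to every non-tie test trial and scores it against the
#' majority label of its sequence. The perceptron convention is label 0 for
#' majority-type-1 ("left") sequences and 1 for majority-type-2.
#'
#' @param test a [state_table()].
#' @param model a trained [train_perceptron()] model.
#' @param sequences the sequence matrix indexed by sequence id.
#' @param use `"binary"` or `"rates"` representation.
#' @return List: `accuracy` (fraction of non-tie test trials correct),
#'   `per_trial` data frame (sequence_id, prediction, correct), and
#'   `per_sequence` accuracy.
#' @export
choice_accuracy <- function(test, model, sequences, use = c("binary", "rates")) {
  use <- match.arg(use)
  lab <- majority_labels(sequences)
  keep <- which(!is.na(lab[test$sequence_id]))
  X <- (if (use == "binary") test$binary else test$rates)[keep, , drop = FALSE]
  truth <- as.integer(lab[test$sequence_id[keep]] == 2L)
  pred <- predict_perceptron(model, X)
  per_trial <- data.frame(sequence_id = test$sequence_id[keep],
                          prediction = pred, truth = truth,
                          correct = as.integer(pred == truth))
  per_seq <- stats::aggregate(correct ~ sequence_id, per_trial, mean)
  list(accuracy = mean(per_trial$correct), per_trial = per_trial,
       per_sequence = per_seq)
}

#' Train the two-choice readout from a training table
#'
#' Convenience wrapper: drops tie sequences, trains the perceptron on the
#' remaining training states with the majority label.
#'
#' @inheritParams choice_accuracy
#' @param train a training [state_table()].
#' @param ... passed to [train_perceptron()].
#' @return A `perceptron` model.
#' @export
train_choice_readout <- function(train, sequences, use = c("binary", "rates"),
                                 ...) {
  use <- match.arg(use)
  lab <- majority_labels(sequences)
  keep <- which(!is.na(lab[train$sequence_id]))
  X <- (if (use == "binary") train$binary else train$rates)[keep, , drop = FALSE]
  y <- as.integer(lab[train$sequence_id[keep]] == 2L)
  train_perceptron(X, y, ...)
}

#' Psychometric curve
#'
#' Empirical probability of a "left" (type-1) choice as a function of the
#' number of left cues in the sequence (0..L). No fitting; proportions only.
#'
#' @param per_trial data frame from [choice_accuracy()] (`sequence_id`,
#'   `prediction` with 0 = left).
#' @param sequences sequence matrix indexed by sequence id.
#' @return Data frame: `n_left`, `p_left`, `n_trials`.
#' @export
psychometric <- function(per_trial, sequences) {
  L <- ncol(sequences)
  n_left_all <- rowSums(sequences == 1L)
  n_left <- n_left_all[per_trial$sequence_id]
  p_left <- tapply(per_trial$prediction == 0L, factor(n_left, levels = 0:L), mean)
  n_tr <- tapply(per_trial$prediction, factor(n_left, levels = 0:L), length)
  data.frame(n_left = 0:L, p_left = as.numeric(p_left),
             n_trials = as.integer(ifelse(is.na(n_tr), 0L, n_tr)))
}

#' Accuracy conditioned on one stimulus position
#'
#' Splits non-tie trials by whether the stimulus at `position` matches the
#' correct (majority) choice, and reports the accuracy of each group, their
#' difference, and a descriptive two-sample t-test over per-sequence
#' accuracies.
#'
#' @param per_trial data frame from [choice_accuracy()].
#' @param sequences sequence matrix indexed by sequence id.
#' @param position serial position to condition on.
#' @return List: `supports` / `opposes` group accuracies, `difference`,
#'   `t_test` (or NULL when a group has < 2 sequences), `per_sequence`.
#' @export
error_by_position <- function(per_trial, sequences, position) {
  if (position < 1 || position > ncol(sequences))
    stop("parameter error: position out of range")
  lab <- majority_labels(sequences)
  per_seq <- stats::aggregate(correct ~ sequence_id, per_trial, mean)
  supports <- sequences[per_seq$sequence_id, position] ==
    lab[per_seq$sequence_id]
  if (!any(supports) || all(supports))
    stop("data error: one of the position-support groups is empty")
  a_sup <- per_seq$correct[supports]
  a_opp <- per_seq$correct[!supports]
  tt <- if (length(a_sup) > 1 && length(a_opp) > 1 &&
            (stats::var(a_sup) > 0 || stats::var(a_opp) > 0))
    stats::t.test(a_sup, a_opp) else NULL
  list(supports = mean(a_sup), opposes = mean(a_opp),
       difference = mean(a_sup) - mean(a_opp), t_test = tt,
       per_sequence = data.frame(sequence_id = per_seq$sequence_id,
                                 supports = supports,
                                 accuracy = per_seq$correct))
}

#' Last-stimulus-only benchmark
#'
#' The accuracy of deciding purely from the final stimulus, enumerated over a
#' sequence set with ties excluded: correct exactly when the last stimulus
#' matches the majority type. Over all 64 six-item two-type sequences this
#' yields 32/44 (~73%), the no-memory reference level; it scores 1 on
#' unanimous sequences, 5/6 on 5-1 splits and 2/3 on 4-2 splits.
#'
#' @param sequences integer matrix of type ids in `{1, 2}`.
#' @return List: `accuracy`, `n_correct`, `n_scored`, and `by_margin`
#'   (accuracy split by the absolute count difference).
#' @export
last_stimulus_benchmark <- function(sequences) {
  lab <- majority_labels(sequences)
  keep <- !is.na(lab)
  last <- sequences[, ncol(sequences)]
  correct <- last[keep] == lab[keep]
  margin <- abs(rowSums(sequences == 1L) - rowSums(sequences == 2L))[keep]
  by_margin <- stats::aggregate(correct ~ margin,
                                data.frame(margin = margin, correct = correct),
                                mean)
  list(accuracy = mean(correct), n_correct = sum(correct),
       n_scored = sum(keep), by_margin = by_margin)
}
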