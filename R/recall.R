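#' Single-stimulus reference states
#'
#' Final binarized state after presenting each stimulus type once, alone,
#' from the settled baseline, under the standard measurement protocol. These
#' are the reference states against which post-sequence states are compared
#' to decide which item is "recalled first".
#'
#' @param baseline settled [network_state()].
#' @param W connectivity.
#' @param patterns list from [make_patterns()].
#' @param params,settings model and integration settings.
#' @param seed noise seed.
#' @param ... passed to [run_trial()].
#' @return List with `binary` and `rates` matrices (one row per type).
#' @export
single_stimulus_states <- function(baseline, W, patterns, params, settings,
                                   seed = 1L, ...) {
  n_units <- params$n_E + params$n_I
  seeds <- derive_seeds(seed, length(patterns))
  res <- lapply(seq_along(patterns), function(k) {
    applied <- realize_timecourse(patterns[[k]]$type_id, patterns, n_units,
                                  seed = seeds[k])
    run_trial(baseline, W, applied, params, settings, seed = seeds[k], ...)
  })
  list(binary = do.call(rbind, lapply(res, `[[`, "binary")),
       rates = do.call(rbind, lapply(res, `[[`, "rates")))
}

#' First-recalled item
#'
#' The stimulus type whose single-stimulus reference state is closest (L1) to
#' the post-sequence network state; exact ties go to the lowest type id. If
#' all reference states are identical the choice is degenerate and a warning
#' is issued.
#'
#' @param final_state binary state vector after the full sequence.
#' @param reference_states matrix of reference states, one row per type;
#'   rownames give type ids (defaults to row numbers).
#' @return The recalled type id (integer).
#' @export
first_recall <- function(final_state, reference_states) {
  if (is.null(dim(reference_states)) || nrow(reference_states) == 0)
    stop("data error: no reference states")
  if (nrow(reference_states) > 1 &&
      all(apply(reference_states, 2, function(col) length(unique(col)) == 1)))
    warning("all reference states are identical; first recall is degenerate")
  ids <- rownames(reference_states)
  if (is.null(ids)) ids <- seq_len(nrow(reference_states))
  d <- rowSums(abs(sweep(reference_states, 2, final_state)))
  as.integer(ids[which.min(d)])
}

#' Probability-of-first-recall curves
#'
#' For each list length, presents random lists of distinct stimulus types
#' (with optional per-presentation amplitude variability), compares the final
#' state with the single-stimulus reference states of the list's own items,
#' and tabulates which serial position is "recalled first". Also summarizes
#' the probability of first-recalling the first item versus any of the last
#' four (non-first) items as a function of list length.
#'
#' @param W connectivity.
#' @param patterns list from [make_patterns()]; needs at least
#'   `max(list_lengths)` types.
#' @param params,settings model and integration settings.
#' @param list_lengths integer vector of list lengths.
#' @param n_lists number of random lists per length.
#' @param seed master seed.
#' @param amplitude_mean,amplitude_sd per-presentation stimulus amplitude
#'   distribution (e.g. mean 0.9, sd 0.2).
#' @param use `"binary"` or `"rates"` states for the comparison.
#' @param ... passed to [run_trial()] / [settle()] via internals.
#' @return List: `pfr` (long data frame: list_length, position, probability),
#'   `summary` (list_length, p_first, p_late), `n_lists`.
#' @export
pfr_curves <- function(W, patterns, params, settings, list_lengths = 2:10,
                       n_lists = 10, seed = 1L, amplitude_mean = NULL,
                       amplitude_sd = 0, use = c("binary", "rates"), ...) {
  use <- match.arg(use)
  n_types <- length(patterns)
  if (max(list_lengths) > n_types)
    stop("parameter error: need at least ", max(list_lengths), " stimulus types")
  n_units <- params$n_E + params$n_I
  baseline <- settle(W, params, settings, seed = derive_seeds(seed, 1, salt = 7L))
  refs <- single_stimulus_states(baseline, W, patterns, params, settings,
                                 seed = derive_seeds(seed, 1, salt = 11L))
  ref_mat <- if (use == "binary") refs$binary else refs$rates
  pfr <- list(); summ <- list()
  for (L in list_lengths) {
    seeds <- matrix(derive_seeds(seed, 2 * n_lists, salt = L), n_lists, 2)
    pos_counts <- rep(0, L)
    for (li in seq_len(n_lists)) {
      items <- with_rng_seed(seeds[li, 1], sample.int(n_types, L))
      applied <- realize_timecourse(items, patterns, n_units,
                                    amplitude_mean = amplitude_mean,
                                    amplitude_sd = amplitude_sd,
                                    seed = seeds[li, 2])
      tr <- run_trial(baseline, W, applied, params, settings,
                      seed = seeds[li, 2], ...)
      st <- if (use == "binary") tr$binary else tr$mean_rates
      sub <- ref_mat[items, , drop = FALSE]
      rownames(sub) <- seq_len(L)   # positions within the list
      pos <- first_recall(st, sub)
      pos_counts[pos] <- pos_counts[pos] + 1
    }
    p <- pos_counts / n_lists
    pfr[[as.character(L)]] <- data.frame(list_length = L, position = seq_len(L),
                                         probability = p)
    late <- if (L >= 2) max(2, L - 3):L else integer(0)
    summ[[as.character(L)]] <- data.frame(list_length = L, p_first = p[1],
                                          p_late = sum(p[late]))
  }
  list(pfr = do.call(rbind, pfr), summary = do.call(rbind, summ),
       n_lists = n_lists)
}

#' Serial-position decoding accuracy
#'
#' Trains one perceptron per (stimulus type, serial position) pair - 49 for
#' the 7-item task - to report, from the final network state, whether that
#' type occupied that position. The per-position score `a_sp` is the mean
#' accuracy over types at that position, evaluated on the test table. The
#' sequence set must be position-balanced (each type occurs at each position)
#' so both classes are present for every perceptron.
#'
#' @param train,test [state_table()]s from the word-list experiment.
#' @param sequences the balanced sequence matrix indexed by sequence id.
#' @param use `"binary"` or `"rates"`.
#' @param ... passed to [train_perceptron()].
#' @return An object of class `serial_position_profile`: `a_sp` (per-position
#'   mean accuracy), `accuracy` (types x positions matrix), `n_models`,
#'   `list_length`.
#' @export
serial_position_accuracy <- function(train, test, sequences,
                                     use = c("binary", "rates"), ...) {
  use <- match.arg(use)
  L <- ncol(sequences)
  types <- sort(unique(as.vector(sequences)))
  for (p in seq_len(L)) {
    cnt <- table(factor(sequences[, p], levels = types))
    if (any(cnt == 0))
      stop("data error: unbalanced design - type missing at position ", p)
  }
  Xtr <- if (use == "binary") train$binary else train$rates
  Xte <- if (use == "binary") test$binary else test$rates
  acc <- matrix(NA_real_, length(types), L,
                dimnames = list(types, paste0("pos", seq_len(L))))
  for (p in seq_len(L)) {
    for (ti in seq_along(types)) {
      y_tr <- as.integer(sequences[train$sequence_id, p] == types[ti])
      y_te <- as.integer(sequences[test$sequence_id, p] == types[ti])
      m <- train_perceptron(Xtr, y_tr, ...)
      acc[ti, p] <- mean(predict_perceptron(m, Xte) == y_te)
    }
  }
  structure(list(a_sp = colMeans(acc), accuracy = acc,
                 n_models = length(types) * L, list_length = L),
            class = "serial_position_profile")
}

#' Primacy and recency scores
#'
#' The amount by which the serial-position decoding scores for the first and
#' final stimulus exceed the score for the middle stimulus (position 4 of a
#' 7-item list): `primacy = a_1 - a_mid`, `recency = a_L - a_mid`. For list
#' lengths other than 7 the middle index must be given explicitly.
#'
#' @param profile a [serial_position_accuracy()] result (or a bare numeric
#'   vector of per-position accuracies).
#' @param middle middle position index; defaults to 4 for 7-item lists.
#' @return List with `primacy` and `recency`, each in `[-1, 1]`.
#' @export
primacy_recency <- function(profile, middle = NULL) {
  a <- if (inherits(profile, "serial_position_profile")) profile$a_sp
       else as.numeric(profile)
  L <- length(a)
  if (is.null(middle)) {
    if (L != 7) stop("parameter error: middle position must be given for lists of length ", L)
    middle <- 4L
  }
  list(primacy = a[1] - a[middle], recency = a[L] - a[middle])
}
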