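#' Generate stimulus patterns
#'
#' Each stimulus type is a square current pulse delivered to a randomly
#' chosen subset of excitatory units of size `round(n_E * f_stim)`. Target
#' sets are drawn independently per type, so different types may overlap by
#' chance. A per-unit amplitude jitter (standard deviation `sigma_I`) is
#' drawn once at pattern construction; non-positive draws are redrawn. The
#' inhibitory unit is never targeted.
#'
#' @param n_types number of stimulus types.
#' @param f_stim fraction of excitatory units targeted per type, in `(0, 1]`.
#' @param I_stim base pulse amplitude (current units).
#' @param sigma_I per-unit amplitude jitter sd (0 = no jitter).
#' @param n_E number of excitatory units.
#' @param seed integer seed; deterministic given the seed.
#' @return A list of `stimulus_pattern` objects with fields `type_id`,
#'   `target_units`, `base_amplitude`, `unit_amplitudes`.
#' @export
make_patterns <- function(n_types, f_stim, I_stim, sigma_I = 0, n_E, seed) {
  if (f_stim <= 0) stop("parameter error: f_stim must be > 0 (empty patterns are not allowed)")
  if (f_stim > 1) stop("parameter error: f_stim must be <= 1")
  k <- round(n_E * f_stim)
  if (k < 1) stop("parameter error: round(n_E * f_stim) must be >= 1")
  with_rng_seed(seed, {
    lapply(seq_len(n_types), function(ti) {
      units <- sort(sample.int(n_E, k))
      amps <- rep(I_stim, k)
      if (sigma_I > 0) {
        amps <- stats::rnorm(k, I_stim, sigma_I)
        while (any(amps <= 0)) {
          bad <- amps <= 0
          amps[bad] <- stats::rnorm(sum(bad), I_stim, sigma_I)
        }
      }
      structure(list(type_id = ti, target_units = units,
                     base_amplitude = I_stim, unit_amplitudes = amps),
                class = "stimulus_pattern")
    })
  })
}

#' Enumerate all two-type sequences
#'
#' All `2^L` ordered sequences over the two stimulus types (1 = "left",
#' 2 = "right"), in lexicographic order. Sequence ids are row indices.
#'
#' @param L sequence length (>= 1).
#' @return A `2^L x L` integer matrix of type ids.
#' @export
enumerate_binary_sequences <- function(L) {
  if (L < 1) stop("parameter error: L must be >= 1")
  n <- 2L^L
  out <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    block <- 2L^(L - j)
    out[, j] <- rep(rep(1:2, each = block), length.out = n)
  }
  out
}

#' Balanced Latin-square sequence sampling
#'
#' Samples `n_lists` distinct permutations of `n_types` stimulus types such
#' that every type occupies every serial position exactly
#' `n_lists / n_types` times. Built by stacking `n_lists / n_types`
#' independently randomized Latin squares (a cyclic square with permuted
#' rows, columns and symbols); squares producing rows that duplicate earlier
#' ones are redrawn.
#'
#' @param n_types number of stimulus types (= sequence length).
#' @param n_lists number of sequences; must be divisible by `n_types`.
#' @param seed integer seed.
#' @return An `n_lists x n_types` integer matrix; each row is a permutation.
#' @export
latin_square_sequences <- function(n_types, n_lists, seed) {
  if (n_lists %% n_types != 0)
    stop("parameter error: n_lists must be divisible by n_types")
  if (n_lists > factorial(n_types))
    stop("parameter error: only ", factorial(n_types),
         " distinct permutations of ", n_types, " types exist")
  n_sq <- n_lists %/% n_types
  base <- outer(seq_len(n_types), seq_len(n_types),
                function(i, j) ((i + j - 2L) %% n_types) + 1L)
  with_rng_seed(seed, {
    rows <- matrix(0L, 0, n_types)
    tries <- 0
    while (nrow(rows) < n_lists) {
      sq <- base[sample.int(n_types), , drop = FALSE][, sample.int(n_types),
                                                      drop = FALSE]
      sq[] <- sample.int(n_types)[sq]
      key_old <- apply(rows, 1, paste, collapse = ",")
      key_new <- apply(sq, 1, paste, collapse = ",")
      if (!anyDuplicated(c(key_old, key_new))) rows <- rbind(rows, sq)
      tries <- tries + 1
      if (tries > 1000 * n_sq)
        stop("could not assemble ", n_lists, " distinct balanced sequences")
    }
    storage.mode(rows) <- "integer"
    rows
  })
}

#' Realize a stimulus sequence as an applied-current timecourse
#'
#' The k-th pulse starts at `(k - 1) * onset_interval` after sequence start
#' and lasts `duration` ms (250 ms at 1.5 s spacing leaves a 1250 ms silent
#' gap). Optional Gaussian variability: per-presentation durations
#' (`duration_sd`) and amplitudes (`amplitude_sd` around `amplitude_mean`)
#' are drawn independently per pulse; non-positive draws are redrawn with a
#' warning. Per-unit amplitude structure comes from the pattern.
#'
#' @param type_ids integer vector of stimulus types (one sequence).
#' @param patterns list from [make_patterns()]; must cover all `type_ids`.
#' @param n_units total unit count (`n_E + 1`).
#' @param onset_interval pulse onset spacing (ms).
#' @param duration nominal pulse duration (ms).
#' @param duration_sd per-presentation duration sd (ms).
#' @param amplitude_mean per-presentation amplitude mean; defaults to each
#'   pattern's base amplitude.
#' @param amplitude_sd per-presentation amplitude sd.
#' @param seed integer seed for the variability draws.
#' @return An [applied_current()]; attribute `"realized"` holds a data frame
#'   of per-presentation realized durations and amplitudes.
#' @export
realize_timecourse <- function(type_ids, patterns, n_units,
                               onset_interval = 1500, duration = 250,
                               duration_sd = 0, amplitude_mean = NULL,
                               amplitude_sd = 0, seed = 1L) {
  L <- length(type_ids)
  if (L < 1) stop("parameter error: sequence must have length >= 1")
  have <- vapply(patterns, function(p) p$type_id, integer(1))
  if (!all(type_ids %in% have))
    stop("parameter error: no pattern for type(s) ",
         paste(setdiff(type_ids, have), collapse = ", "))
  draw_pos <- function(n, mean, sd, what) {
    if (sd <= 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) {
      warning("redrew non-positive ", what, " draw")
      bad <- x <= 0
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  with_rng_seed(seed, {
    durs <- draw_pos(L, duration, duration_sd, "duration")
    onsets <- (seq_len(L) - 1) * onset_interval
    if (any(durs > onset_interval))
      stop("parameter error: realized duration exceeds onset interval")
    cur <- matrix(0, n_units, L)
    amps <- numeric(L)
    for (k in seq_len(L)) {
      p <- patterns[[match(type_ids[k], have)]]
      am <- if (is.null(amplitude_mean)) p$base_amplitude else amplitude_mean
      a <- draw_pos(1, am, amplitude_sd, "amplitude")
      cur[p$target_units, k] <- p$unit_amplitudes * (a / p$base_amplitude)
      amps[k] <- a
    }
    out <- applied_current(onsets, onsets + durs, cur)
    attr(out, "realized") <- data.frame(presentation = seq_len(L),
                                        type_id = type_ids,
                                        onset = onsets, duration = durs,
                                        amplitude = amps)
    out
  })
}

#' Export sequences to CSV
#'
#' One row per sequence: id plus the type at each serial position.
#'
#' @param sequences integer matrix (sequences x positions).
#' @param path output file.
#' @export
write_sequences_csv <- function(sequences, path) {
  df <- data.frame(sequence_id = seq_len(nrow(sequences)), sequences)
  names(df)[-1] <- paste0("pos", seq_len(ncol(sequences)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export stimulus patterns to CSV
#'
#' One row per (type, target unit) with its realized amplitude.
#'
#' @param patterns list from [make_patterns()].
#' @param path output file.
#' @export
write_patterns_csv <- function(patterns, path) {
  df <- do.call(rbind, lapply(patterns, function(p)
    data.frame(type_id = p$type_id, unit = p$target_units,
               amplitude = p$unit_amplitudes)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
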