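#' Settle the network to its baseline state
#'
#' Evolves the network with no external stimulus for at least 1.5 s and
#' returns the resulting state, used as the shared initial condition for all
#' trials of an experiment. The start is either quiescence (rates and gating
#' at zero, `D = 1`) or, with `f_start_on > 0`, a fixed subset of
#' `round(n_E * f_start_on)` excitatory units initialized active: rates at
#' `r_max_E` with `s` and `D` at their clamped-rate fixed points
#' (`D* = 1 / (1 + p0 r tau_D)`, `s* = x / (1 + x)` with
#' `x = alpha p0 r D* tau_s`).
#'
#' @param W connectivity.
#' @param params a [model_params()].
#' @param settings an [integration_settings()].
#' @param duration settling time (ms, >= 1500).
#' @param f_start_on fraction of E units initialized active.
#' @param seed seed for the active-subset draw and the settling noise.
#' @param clamp_D disable depression during settling (ablation).
#' @return The settled [network_state()] (with `t` reset to 0); attribute
#'   `"on_units"` records the initialized subset.
#' @export
settle <- function(W, params, settings, duration = 1500, f_start_on = 0,
                   seed = 1L, clamp_D = FALSE) {
  if (duration < 1500) stop("parameter error: settling duration must be >= 1500 ms")
  st <- quiescent_state(params)
  on_units <- integer(0)
  if (f_start_on > 0) {
    k <- round(params$n_E * f_start_on)
    on_units <- with_rng_seed(seed, sort(sample.int(params$n_E, k)))
    r_on <- params$r_max_E
    D_on <- 1 / (1 + params$p0_E * r_on * params$tau_D / 1000)
    x <- params$alpha_tilde * params$p0_E * r_on * D_on * params$tau_s_E / 1000
    st$r[on_units] <- r_on
    st$D[on_units] <- D_on
    st$s[on_units] <- x / (1 + x)
  }
  res <- simulate(st, W, NULL, t_end = duration, params = params,
                  settings = settings, seed = seed, clamp_D = clamp_D)
  out <- res$state
  out$t <- 0
  attr(out, "on_units") <- on_units
  out
}

#' Run one trial
#'
#' Simulates from the shared baseline through a realized stimulus sequence
#' plus 1250 ms past the final stimulus offset. Mean rates of the excitatory
#' units are averaged over `[offset + 250, offset + 1250]` ms and binarized
#' at a strict 30 Hz threshold (a unit is "on" only if its mean rate exceeds
#' 30 Hz).
#'
#' @param baseline settled [network_state()].
#' @param W connectivity.
#' @param applied an [applied_current()] (an empty one yields the binarized
#'   baseline).
#' @param params a [model_params()].
#' @param settings an [integration_settings()].
#' @param seed noise seed for this trial.
#' @param threshold binarization threshold (Hz).
#' @param post_wait,avg_delay,avg_len measurement protocol (ms): simulate
#'   `post_wait` past the final offset, average over
#'   `[offset + avg_delay, offset + avg_delay + avg_len]`.
#' @param clamp_D disable depression (ablation).
#' @return A `trial_result`: list with `mean_rates` and `binary` (excitatory
#'   units), the final `state`, and the `seed`.
#' @export
run_trial <- function(baseline, W, applied, params, settings, seed = 1L,
                      threshold = 30, post_wait = 1250, avg_delay = 250,
                      avg_len = 1000, clamp_D = FALSE) {
  n_E <- params$n_E
  if (length(applied$onsets) == 0) {
    rates <- baseline$r[seq_len(n_E)]
    return(structure(list(mean_rates = rates, binary = as.integer(rates > threshold),
                          state = baseline, seed = as.integer(seed)),
                     class = "trial_result"))
  }
  offset <- max(applied$offsets)
  if (avg_delay + avg_len > post_wait)
    stop("parameter error: measurement window extends past the simulated trial")
  t_end <- offset + post_wait
  res <- simulate(baseline, W, applied, t_end = t_end, params = params,
                  settings = settings, seed = seed,
                  avg_window = c(offset + avg_delay, offset + avg_delay + avg_len),
                  clamp_D = clamp_D)
  rates <- res$mean_rates[seq_len(n_E)]
  structure(list(mean_rates = rates, binary = as.integer(rates > threshold),
                 state = res$state, seed = as.integer(seed)),
            class = "trial_result")
}

#' State table
#'
#' The substrate of all decoding: binarized (and mean-rate) final network
#' states indexed by (sequence id, repetition).
#'
#' @param binary integer 0/1 matrix, rows = trials, columns = E units.
#' @param rates numeric matrix of matching shape (mean rates, Hz).
#' @param sequence_id,repetition integer vectors, one entry per row.
#' @param role `"train"` or `"test"`.
#' @param seeds per-row noise seeds (provenance).
#' @return An object of class `state_table`.
#' @export
state_table <- function(binary, rates, sequence_id, repetition,
                        role = c("train", "test"), seeds = NA_integer_) {
  role <- match.arg(role)
  binary <- as.matrix(binary); rates <- as.matrix(rates)
  n <- nrow(binary)
  if (length(sequence_id) != n || length(repetition) != n)
    stop("structural error: index columns must match row count")
  reps <- table(sequence_id)
  if (length(unique(reps)) > 1)
    stop("structural error: unequal repetitions per sequence")
  structure(list(binary = binary, rates = rates,
                 sequence_id = as.integer(sequence_id),
                 repetition = as.integer(repetition), role = role,
                 seeds = rep_len(as.integer(seeds), n)),
            class = "state_table")
}

#' @export
print.state_table <- function(x, ...) {
  cat("state_table (", x$role, "): ", nrow(x$binary), " trials, ",
      length(unique(x$sequence_id)), " sequences, ", ncol(x$binary),
      " units\n", sep = "")
  invisible(x)
}

#' Run a full experiment
#'
#' For every sequence, runs `n_train + n_test` independent trials from the
#' same settled baseline (fresh noise seed per trial) and collects the final
#' binarized states into train and test [state_table()]s, mirroring the
#' 10-train / 10-test repetition protocol. With `sigma = 0` and no stimulus
#' variability, repetitions are identical by construction; they are still
#' executed unless `dedup = TRUE`, which runs one trial per sequence and
#' replicates its row (valid only in the fully deterministic setting, where
#' it is provably equivalent).
#'
#' @param W connectivity.
#' @param patterns list from [make_patterns()].
#' @param sequences integer matrix (sequences x positions) of type ids.
#' @param params,settings model and integration settings.
#' @param n_train,n_test repetitions per sequence.
#' @param master_seed seed from which all per-trial seeds are derived.
#' @param onset_interval,duration,duration_sd,amplitude_mean,amplitude_sd
#'   stimulus realization parameters (see [realize_timecourse()]).
#' @param f_start_on,settle_duration baseline preparation (see [settle()]).
#' @param threshold,post_wait,avg_delay,avg_len measurement protocol
#'   (see [run_trial()]).
#' @param clamp_D disable depression (ablation).
#' @param dedup deterministic fast path (default off).
#' @param baseline optionally supply a pre-settled baseline state.
#' @return A list with `train` and `test` [state_table()]s and the `baseline`.
#' @export
run_experiment <- function(W, patterns, sequences, params, settings,
                           n_train = 10, n_test = 10, master_seed = 1L,
                           onset_interval = 1500, duration = 250,
                           duration_sd = 0, amplitude_mean = NULL,
                           amplitude_sd = 0, f_start_on = 0,
                           settle_duration = 1500, threshold = 30,
                           post_wait = 1250, avg_delay = 250, avg_len = 1000,
                           clamp_D = FALSE, dedup = FALSE, baseline = NULL) {
  if (nrow(sequences) < 1) stop("parameter error: no sequences supplied")
  n_seq <- nrow(sequences)
  n_units <- params$n_E + params$n_I
  deterministic <- params$sigma == 0 && duration_sd == 0 && amplitude_sd == 0
  if (dedup && !deterministic)
    stop("parameter error: dedup is only valid with sigma = 0 and no stimulus variability")
  if (is.null(baseline))
    baseline <- settle(W, params, settings, duration = settle_duration,
                       f_start_on = f_start_on,
                       seed = derive_seeds(master_seed, 1, salt = 99L),
                       clamp_D = clamp_D)
  n_rep <- n_train + n_test
  seeds <- matrix(derive_seeds(master_seed, n_seq * n_rep), n_seq, n_rep)
  one_trial <- function(i, k) {
    applied <- realize_timecourse(sequences[i, ], patterns, n_units,
                                  onset_interval = onset_interval,
                                  duration = duration, duration_sd = duration_sd,
                                  amplitude_mean = amplitude_mean,
                                  amplitude_sd = amplitude_sd,
                                  seed = seeds[i, k])
    run_trial(baseline, W, applied, params, settings, seed = seeds[i, k],
              threshold = threshold, post_wait = post_wait,
              avg_delay = avg_delay, avg_len = avg_len, clamp_D = clamp_D)
  }
  bin <- matrix(0L, n_seq * n_rep, params$n_E)
  rts <- matrix(0, n_seq * n_rep, params$n_E)
  for (i in seq_len(n_seq)) {
    if (dedup) {
      tr <- one_trial(i, 1L)
      for (k in seq_len(n_rep)) {
        bin[(i - 1) * n_rep + k, ] <- tr$binary
        rts[(i - 1) * n_rep + k, ] <- tr$mean_rates
      }
    } else {
      for (k in seq_len(n_rep)) {
        tr <- one_trial(i, k)
        bin[(i - 1) * n_rep + k, ] <- tr$binary
        rts[(i - 1) * n_rep + k, ] <- tr$mean_rates
      }
    }
  }
  idx_seq <- rep(seq_len(n_seq), each = n_rep)
  idx_rep <- rep(seq_len(n_rep), n_seq)
  is_train <- idx_rep <= n_train
  mk <- function(rows, role, rep_off = 0L)
    state_table(bin[rows, , drop = FALSE], rts[rows, , drop = FALSE],
                idx_seq[rows], idx_rep[rows] - rep_off, role = role,
                seeds = as.integer(t(seeds))[rows])
  list(train = mk(which(is_train), "train"),
       test = mk(which(!is_train), "test", rep_off = as.integer(n_train)),
       baseline = baseline)
}

#' Write / read a state table as CSV
#'
#' Wide format: id columns (`sequence_id`, `repetition`, `role`, `seed`)
#' followed by the binary state (`u1 ... u<n>`) and mean rates
#' (`r1 ... r<n>`).
#'
#' @param x a [state_table()].
#' @param path file path.
#' @return `read_state_table_csv` returns a [state_table()].
#' @export
write_state_table_csv <- function(x, path) {
  df <- data.frame(sequence_id = x$sequence_id, repetition = x$repetition,
                   role = x$role, seed = x$seeds)
  b <- as.data.frame(x$binary); names(b) <- paste0("u", seq_len(ncol(x$binary)))
  r <- as.data.frame(x$rates); names(r) <- paste0("r", seq_len(ncol(x$rates)))
  utils::write.csv(cbind(df, b, r), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_table_csv
#' @export
read_state_table_csv <- function(path) {
  df <- utils::read.csv(path)
  ucols <- grep("^u[0-9]+$", names(df)); rcols <- grep("^r[0-9]+$", names(df))
  state_table(unname(as.matrix(df[, ucols, drop = FALSE])),
              unname(as.matrix(df[, rcols, drop = FALSE])),
              df$sequence_id, df$repetition, role = df$role[1],
              seeds = df$seed)
}
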