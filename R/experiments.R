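# Sweepable parameter names and where they live
.sweep_param_schema <- c(
  w_self = "weights", sigma_w = "weights", w_cross_max = "weights",
  w_EI = "weights", w_IE = "weights",
  f_stim = "stim", I_stim = "stim", sigma_I = "stim",
  tau_r = "model", tau_s_E = "model", tau_s_I = "model", tau_D = "model",
  Theta_E = "model", Theta_I = "model", sigma = "model")

set_swept_param <- function(params, wcfg, stim, name, value) {
  where <- .sweep_param_schema[name]
  if (is.na(where)) stop("parameter error: unknown sweep parameter '", name, "'")
  if (where == "weights") wcfg[[name]] <- value
  else if (where == "stim") stim[[name]] <- value
  else params[[name]] <- value
  if (where == "weights") wcfg <- do.call(weight_config, unclass(wcfg))
  if (where == "model") params <- do.call(model_params, unclass(params))
  list(params = params, wcfg = wcfg, stim = stim)
}

default_stim_config <- function() {
  list(f_stim = 0.59, I_stim = 1.07, sigma_I = 0, onset_interval = 1500,
       duration = 250, duration_sd = 0, amplitude_sd = 0)
}

#' Run the full task pipeline at one parameter point
#'
#' Builds one network and its stimulus patterns, runs the complete trial
#' protocol for the chosen task, and returns the discrimination score
#' (`kappa`) and, for the two-choice task, the perceptron decision accuracy.
#'
#' @param task `"two_choice"` (64 six-item sequences of 2 types) or
#'   `"word_list"` (balanced 7-type permutation lists).
#' @param params,wcfg model and weight configuration.
#' @param stim stimulus configuration list (see `default_stim_config()`
#'   fields: `f_stim`, `I_stim`, `sigma_I`, `onset_interval`, `duration`,
#'   `duration_sd`, `amplitude_sd`).
#' @param settings integration settings.
#' @param network_seed seed for connectivity, patterns and trial noise.
#' @param n_train,n_test repetitions per sequence.
#' @param n_word_lists number of word-list sequences (default 70).
#' @param ablation `"none"`, `"no_depression"`, or `"no_cross_excitation"`.
#' @param dedup deterministic fast path for noiseless runs (see
#'   [run_experiment()]); ignored (forced off) when the run is stochastic.
#' @param sequences optionally override the task's sequence set.
#' @param keep_tables if TRUE, include the train/test state tables.
#' @return List: `kappa`, `accuracy` (two-choice; NA otherwise), `profile`
#'   (word list), `confusion`, plus tables if requested.
#' @export
run_task_point <- function(task = c("two_choice", "word_list"), params, wcfg,
                           stim = default_stim_config(), settings,
                           network_seed = 1L, n_train = 10, n_test = 10,
                           n_word_lists = 70,
                           ablation = c("none", "no_depression",
                                        "no_cross_excitation"),
                           dedup = FALSE, sequences = NULL,
                           keep_tables = FALSE) {
  task <- match.arg(task)
  ablation <- match.arg(ablation)
  seeds <- derive_seeds(network_seed, 4, salt = 17L)
  conn <- build_connectivity(wcfg, params, seed = seeds[1])
  if (ablation == "no_cross_excitation") conn <- remove_cross_excitation(conn)
  n_types <- if (task == "two_choice") 2L else 7L
  patterns <- make_patterns(n_types, stim$f_stim, stim$I_stim, stim$sigma_I,
                            params$n_E, seed = seeds[2])
  if (is.null(sequences))
    sequences <- if (task == "two_choice") enumerate_binary_sequences(6L)
                 else latin_square_sequences(7L, n_word_lists, seed = seeds[3])
  deterministic <- params$sigma == 0 && stim$duration_sd == 0 &&
    stim$amplitude_sd == 0
  exp <- run_experiment(conn, patterns, sequences, params, settings,
                        n_train = n_train, n_test = n_test,
                        master_seed = seeds[4],
                        onset_interval = stim$onset_interval,
                        duration = stim$duration,
                        duration_sd = stim$duration_sd,
                        amplitude_sd = stim$amplitude_sd,
                        clamp_D = (ablation == "no_depression"),
                        dedup = dedup && deterministic)
  targets <- target_responses(exp$train)
  C <- confusion(exp$test, targets)
  out <- list(kappa = kappa(C), accuracy = NA_real_, confusion = C,
              sequences = sequences, network_seed = as.integer(network_seed))
  if (task == "two_choice") {
    model <- train_choice_readout(exp$train, sequences)
    ca <- choice_accuracy(exp$test, model, sequences)
    out$accuracy <- ca$accuracy
    out$choice <- ca
    out$model <- model
  } else {
    out$profile <- serial_position_accuracy(exp$train, exp$test, sequences)
    out$scores <- primacy_recency(out$profile)
  }
  if (keep_tables) { out$train <- exp$train; out$test <- exp$test }
  out
}

#' Two-dimensional parameter sweep
#'
#' Runs the full task pipeline for every grid point of one or two swept
#' parameters, with `n_networks` independent networks per point (distinct
#' connectivity/stimulus seeds), recording `kappa` and the two-choice
#' accuracy per network. Deterministic given `master_seed`. With a
#' `cache_dir`, completed points are written to CSV and skipped on re-runs.
#'
#' @param axis1 list with `name` (a sweepable parameter) and `values`.
#' @param axis2 optional second axis (same form); NULL for a 1-D sweep.
#' @param n_networks networks per grid point.
#' @param task,params,wcfg,stim,settings,ablation,n_train,n_test,dedup see
#'   [run_task_point()].
#' @param master_seed master seed; per-network seeds are derived from it.
#' @param cache_dir optional directory for per-point resumable caching.
#' @return Long-format data frame: `axis1`, `axis2`, `network`, `seed`,
#'   `kappa`, `accuracy` (and `primacy`/`recency` for the word task).
#' @export
sweep_grid <- function(axis1, axis2 = NULL, n_networks = 10,
                       task = "two_choice", params = model_params(),
                       wcfg = weight_config(), stim = default_stim_config(),
                       settings = integration_settings(), master_seed = 1L,
                       n_train = 10, n_test = 10, ablation = "none",
                       dedup = FALSE, cache_dir = NULL) {
  stopifnot(is.list(axis1), length(axis1$values) >= 1)
  if (is.null(axis2)) axis2 <- list(name = NA_character_, values = NA_real_)
  grid <- expand.grid(v1 = axis1$values, v2 = axis2$values)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    tag <- sprintf("point_%g_%g", grid$v1[g], grid$v2[g])
    cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(tag, ".csv"))
    if (!is.null(cache_dir) && file.exists(cache_file)) {
      res[[g]] <- utils::read.csv(cache_file)
      next
    }
    cfg <- set_swept_param(params, wcfg, stim, axis1$name, grid$v1[g])
    if (!is.na(axis2$name))
      cfg <- set_swept_param(cfg$params, cfg$wcfg, cfg$stim, axis2$name,
                             grid$v2[g])
    seeds <- derive_seeds(master_seed, n_networks, salt = g)
    rows <- lapply(seq_len(n_networks), function(k) {
      pt <- tryCatch(
        run_task_point(task, cfg$params, cfg$wcfg, cfg$stim, settings,
                       network_seed = seeds[k], n_train = n_train,
                       n_test = n_test, ablation = ablation, dedup = dedup),
        error = function(e) {
          warning("sweep point ", tag, " network ", k, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(pt))
        return(data.frame(axis1 = grid$v1[g], axis2 = grid$v2[g], network = k,
                          seed = seeds[k], kappa = NA_real_,
                          accuracy = NA_real_, primacy = NA_real_,
                          recency = NA_real_))
      data.frame(axis1 = grid$v1[g], axis2 = grid$v2[g], network = k,
                 seed = seeds[k], kappa = pt$kappa, accuracy = pt$accuracy,
                 primacy = if (!is.null(pt$scores)) pt$scores$primacy else NA_real_,
                 recency = if (!is.null(pt$scores)) pt$scores$recency else NA_real_)
    })
    res[[g]] <- do.call(rbind, rows)
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(res[[g]], cache_file, row.names = FALSE)
    }
  }
  out <- do.call(rbind, res)
  names(out)[1:2] <- c(axis1$name, if (!is.na(axis2$name)) axis2$name else "axis2")
  attr(out, "axes") <- list(axis1 = axis1, axis2 = axis2)
  out
}

#' Ablation sweep
#'
#' Re-runs a sweep with one mechanism removed: `"no_depression"` clamps the
#' depression variable at 1 for entire trials (the depression equation
#' becomes inert); `"no_cross_excitation"` zeroes all off-diagonal E-to-E
#' weights. Everything else, including seeds, is identical to the matched
#' intact sweep, so results are directly comparable.
#'
#' @param mode `"no_depression"` or `"no_cross_excitation"`.
#' @param ... passed to [sweep_grid()].
#' @return As [sweep_grid()].
#' @export
ablate <- function(mode = c("no_depression", "no_cross_excitation"), ...) {
  mode <- match.arg(mode)
  sweep_grid(..., ablation = mode)
}

#' Train/test generalization
#'
#' Trains the choice perceptron only on a subset of sequences (e.g. only 4-2
#' count sequences) and/or under different stimulus conditions (e.g. a
#' 1500 ms onset interval), then evaluates on test states from possibly
#' different conditions, reporting accuracy separately for trained and
#' untrained sequences.
#'
#' @param conn connectivity (shared between conditions).
#' @param patterns shared stimulus patterns.
#' @param sequences sequence matrix.
#' @param params,settings model and integration settings.
#' @param train_subset logical vector over sequences: which are used for
#'   perceptron training (default: all non-tie sequences).
#' @param train_stim,test_stim stimulus configuration lists for the train and
#'   test runs (see `default_stim_config()`).
#' @param n_train,n_test repetitions.
#' @param master_seed seed.
#' @param dedup deterministic fast path.
#' @return List: `accuracy_overall`, `accuracy_trained`,
#'   `accuracy_untrained`, `per_trial`.
#' @export
generalization_test <- function(conn, patterns, sequences, params, settings,
                                train_subset = NULL,
                                train_stim = default_stim_config(),
                                test_stim = train_stim,
                                n_train = 10, n_test = 10, master_seed = 1L,
                                dedup = FALSE) {
  lab <- majority_labels(sequences)
  if (is.null(train_subset)) train_subset <- !is.na(lab)
  if (!any(train_subset & !is.na(lab)) ||
      length(unique(lab[train_subset & !is.na(lab)])) < 2)
    stop("data error: training subset must contain non-tie sequences of both classes")
  run_cond <- function(stim, n_tr, n_te, salt)
    run_experiment(conn, patterns, sequences, params, settings,
                   n_train = n_tr, n_test = n_te,
                   master_seed = derive_seeds(master_seed, 1, salt = salt),
                   onset_interval = stim$onset_interval,
                   duration = stim$duration, duration_sd = stim$duration_sd,
                   amplitude_sd = stim$amplitude_sd,
                   dedup = dedup && params$sigma == 0 &&
                     stim$duration_sd == 0 && stim$amplitude_sd == 0)
  tr_exp <- run_cond(train_stim, n_train, 0L, 1L)
  te_exp <- run_cond(test_stim, 0L, n_test, 2L)
  keep <- which(train_subset[tr_exp$train$sequence_id] &
                  !is.na(lab[tr_exp$train$sequence_id]))
  X <- tr_exp$train$binary[keep, , drop = FALSE]
  y <- as.integer(lab[tr_exp$train$sequence_id[keep]] == 2L)
  model <- train_perceptron(X, y)
  ca <- choice_accuracy(te_exp$test, model, sequences)
  trained <- train_subset[ca$per_trial$sequence_id]
  list(accuracy_overall = ca$accuracy,
       accuracy_trained = mean(ca$per_trial$correct[trained]),
       accuracy_untrained = if (any(!trained))
         mean(ca$per_trial$correct[!trained]) else NA_real_,
       per_trial = cbind(ca$per_trial, trained = trained),
       model = model)
}

#' Per-unit correlations with sequence properties
#'
#' Pearson correlation of each excitatory unit's final activity with (i) the
#' number of "left" (type-1) stimuli, (ii) a first-stimulus indicator, and
#' (iii) a last-stimulus indicator, plus the across-unit correlations between
#' these per-unit profiles (with descriptive p-values). Zero-variance units
#' yield `NA` with a warning and are excluded from the profile correlations.
#'
#' @param test a [state_table()].
#' @param sequences sequence matrix indexed by sequence id.
#' @param use `"rates"` (default) or `"binary"` activity.
#' @return List: `per_unit` data frame (`rho_count`, `rho_first`,
#'   `rho_last`), `profile_cor` data frame with the pairwise across-unit
#'   correlations and p-values.
#' @export
unit_correlations <- function(test, sequences, use = c("rates", "binary")) {
  use <- match.arg(use)
  X <- if (use == "rates") test$rates else test$binary
  sq <- test$sequence_id
  regs <- list(count = rowSums(sequences == 1L)[sq],
               first = as.numeric(sequences[sq, 1] == 1L),
               last = as.numeric(sequences[sq, ncol(sequences)] == 1L))
  for (nm in names(regs))
    if (length(unique(regs[[nm]])) < 2)
      stop("data error: regressor '", nm, "' has no variation")
  safe_cor <- function(x, y) if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  per_unit <- data.frame(
    unit = seq_len(ncol(X)),
    rho_count = apply(X, 2, safe_cor, y = regs$count),
    rho_first = apply(X, 2, safe_cor, y = regs$first),
    rho_last = apply(X, 2, safe_cor, y = regs$last))
  if (anyNA(per_unit[-1]))
    warning(sum(!stats::complete.cases(per_unit[-1])),
            " constant unit(s) excluded from profile correlations")
  ok <- stats::complete.cases(per_unit[-1])
  pairs <- list(c("rho_last", "rho_count"), c("rho_first", "rho_count"),
                c("rho_first", "rho_last"))
  prof <- do.call(rbind, lapply(pairs, function(pr) {
    ct <- stats::cor.test(per_unit[ok, pr[1]], per_unit[ok, pr[2]])
    data.frame(x = pr[1], y = pr[2], rho = unname(ct$estimate),
               p_value = ct$p.value)
  }))
  list(per_unit = per_unit, profile_cor = prof)
}

#' Intra- versus inter-cluster state distances
#'
#' Clusters are the sets of binarized final states produced by sequences with
#' the same number of "left" (type-1) stimuli. Reports the mean pairwise
#' Euclidean distance within clusters and across clusters, with a descriptive
#' two-sample t-test.
#'
#' @param test a [state_table()].
#' @param sequences sequence matrix indexed by sequence id.
#' @return List: `intra`, `inter` (mean distances), `t_test`, `n_pairs`.
#' @export
cluster_distances <- function(test, sequences) {
  counts <- rowSums(sequences == 1L)[test$sequence_id]
  tab <- table(counts)
  if (sum(tab >= 2) < 2)
    stop("data error: need at least 2 clusters with at least 2 states each")
  D <- as.matrix(stats::dist(test$binary))
  same <- outer(counts, counts, "==")
  ut <- upper.tri(D)
  intra <- D[ut & same]; inter <- D[ut & !same]
  tt <- if (length(intra) > 1 && length(inter) > 1 &&
            (stats::var(intra) > 0 || stats::var(inter) > 0))
    stats::t.test(intra, inter) else NULL
  list(intra = mean(intra), inter = mean(inter), t_test = tt,
       n_pairs = c(intra = length(intra), inter = length(inter)))
}

#' Trajectory PCA and divergence timecourse
#'
#' Fits principal components on the concatenated excitatory-rate trajectories
#' of two trials and returns the 3-component projections together with the
#' full-space Euclidean distance between the two trajectories over time.
#'
#' @param traj1,traj2 matrices (time x units) of excitatory rates sampled at
#'   matched times.
#' @param times optional sample times (ms).
#' @param n_components number of components to return (default 3; fewer are
#'   returned with a warning if the data are degenerate).
#' @return List: `proj1`, `proj2` (time x components), `distance`, `times`,
#'   `variance_explained`.
#' @export
pca_trajectories <- function(traj1, traj2, times = NULL, n_components = 3) {
  if (!all(dim(traj1) == dim(traj2)))
    stop("structural error: trajectories must have equal dimensions")
  both <- rbind(traj1, traj2)
  pc <- stats::prcomp(both, center = TRUE, scale. = FALSE)
  pos <- pc$sdev > 1e-12
  k <- min(n_components, sum(pos))
  if (k < n_components)
    warning("only ", k, " non-degenerate component(s) available")
  k <- max(k, 1)
  proj <- pc$x[, seq_len(k), drop = FALSE]
  n <- nrow(traj1)
  list(proj1 = proj[seq_len(n), , drop = FALSE],
       proj2 = proj[n + seq_len(n), , drop = FALSE],
       distance = sqrt(rowSums((traj1 - traj2)^2)),
       times = times,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}
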