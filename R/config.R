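# Published ranges used for soft validation (warnings, not errors)
.param_ranges <- list(
  w_self = c(71, 110), sigma_w = c(0, 0.2), w_cross_max = c(0, 0.56),
  w_EI = c(0.6, 0.72), w_IE = c(-580, -480), sigma = c(0, 0.002),
  f_stim = c(0, 1), I_stim = c(0.4, 1.8))

#' Default run configuration
#'
#' A flat key/value configuration covering the model parameters, weight
#' configuration, stimulus settings, task, protocol sizes and seeds, with
#' names mirroring the model's symbols. Values outside the documented ranges
#' trigger warnings, not errors.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    task = "two_choice",
    # model
    tau_r = 10, tau_s_E = 50, tau_s_I = 5, tau_D = 500,
    Theta_E = 6, Theta_I = 10, Delta_E = 1, Delta_I = 3,
    p0_E = 1, p0_I = 0.1, r_max_E = 100, r_max_I = 200,
    alpha_tilde = 1, sigma = 0, n_E = 100, n_I = 1,
    # weights
    w_self = 89, sigma_w = 0.1, w_cross_max = 0.346, w_EI = 0.665,
    w_IE = -540, w_II = 0,
    # stimuli
    f_stim = 0.59, I_stim = 1.07, sigma_I = 0, onset_interval = 1500,
    duration = 250, duration_sd = 0, amplitude_sd = 0,
    # protocol
    n_train = 10, n_test = 10, n_networks = 1, n_word_lists = 70,
    threshold = 30, f_start_on = 0,
    # integration
    dt = 0.5, noise_convention = "flat_spectrum",
    # orchestration
    master_seed = 1, ablation = "none", dedup = FALSE), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path file path.
#' @param config a configuration list.
#' @return `read_config` returns a validated `run_config` (unknown keys are
#'   an error; missing keys take defaults).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("invalid config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  validate_config(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_config
#' @export
validate_config <- function(config) {
  for (nm in names(.param_ranges)) {
    rng <- .param_ranges[[nm]]
    v <- config[[nm]]
    if (!is.null(v) && (v < rng[1] || v > rng[2]))
      warning("config value ", nm, " = ", v, " is outside the documented range [",
              rng[1], ", ", rng[2], "]")
  }
  if (!config$task %in% c("two_choice", "word_list"))
    stop("invalid config: task must be 'two_choice' or 'word_list'")
  # hard invariants delegated to the constructors
  invisible(config_objects(config))
  structure(config, class = "run_config")
}

# split a flat config into the constructor objects
config_objects <- function(config) {
  params <- model_params(tau_r = config$tau_r, tau_s_E = config$tau_s_E,
                         tau_s_I = config$tau_s_I, tau_D = config$tau_D,
                         Theta_E = config$Theta_E, Theta_I = config$Theta_I,
                         Delta_E = config$Delta_E, Delta_I = config$Delta_I,
                         p0_E = config$p0_E, p0_I = config$p0_I,
                         r_max_E = config$r_max_E, r_max_I = config$r_max_I,
                         alpha_tilde = config$alpha_tilde, sigma = config$sigma,
                         n_E = config$n_E, n_I = config$n_I)
  wcfg <- weight_config(w_self = config$w_self, sigma_w = config$sigma_w,
                        w_cross_max = config$w_cross_max, w_EI = config$w_EI,
                        w_IE = config$w_IE, w_II = config$w_II)
  stim <- list(f_stim = config$f_stim, I_stim = config$I_stim,
               sigma_I = config$sigma_I,
               onset_interval = config$onset_interval,
               duration = config$duration, duration_sd = config$duration_sd,
               amplitude_sd = config$amplitude_sd)
  settings <- integration_settings(dt = config$dt,
                                   noise_convention = config$noise_convention)
  list(params = params, wcfg = wcfg, stim = stim, settings = settings)
}

# small stable hash (FNV-1a over the serialized config) for manifests
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run a configured task end-to-end
#'
#' Executes the named task for `n_networks` networks (build, stimulate,
#' decode, score) and, if `out_dir` is given, writes the state tables,
#' confusion matrix, score table and a JSON manifest embedding the full
#' configuration, its hash and every seed used.
#'
#' @param config a `run_config` (see [default_config()], [read_config()]).
#' @param out_dir optional output directory.
#' @return List: per-network `results` (from [run_task_point()]) and a
#'   `scores` data frame; invisibly writes files when `out_dir` is set.
#' @export
run_task <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  obj <- config_objects(config)
  seeds <- derive_seeds(config$master_seed, config$n_networks)
  results <- lapply(seq_len(config$n_networks), function(k)
    run_task_point(config$task, obj$params, obj$wcfg, obj$stim, obj$settings,
                   network_seed = seeds[k], n_train = config$n_train,
                   n_test = config$n_test, n_word_lists = config$n_word_lists,
                   ablation = config$ablation, dedup = config$dedup,
                   keep_tables = !is.null(out_dir)))
  scores <- data.frame(
    network = seq_len(config$n_networks), seed = seeds,
    kappa = vapply(results, `[[`, numeric(1), "kappa"),
    accuracy = vapply(results, `[[`, numeric(1), "accuracy"))
  if (config$task == "word_list") {
    scores$primacy <- vapply(results, function(r) r$scores$primacy, numeric(1))
    scores$recency <- vapply(results, function(r) r$scores$recency, numeric(1))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    for (k in seq_along(results)) {
      utils::write.csv(as.data.frame(unclass(results[[k]]$confusion)),
                       file.path(out_dir, sprintf("confusion_net%02d.csv", k)),
                       row.names = FALSE)
      write_state_table_csv(results[[k]]$train,
                            file.path(out_dir, sprintf("train_net%02d.csv", k)))
      write_state_table_csv(results[[k]]$test,
                            file.path(out_dir, sprintf("test_net%02d.csv", k)))
    }
    write_sequences_csv(results[[1]]$sequences,
                        file.path(out_dir, "sequences.csv"))
    manifest <- list(config = unclass(config), config_hash = config_hash(config),
                     network_seeds = seeds,
                     package_version = as.character(utils::packageVersion("attractorseq")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, scores = scores, config = config)
}
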