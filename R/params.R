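#' Single-unit model parameters
#'
#' Bundles all single-unit constants of the firing-rate model: the rate time
#' constant, synaptic gating and depression time constants, the logistic f-I
#' curve thresholds and sensitivities, vesicle release probabilities, maximum
#' rates, the maximal open-receptor fraction, the white-noise current
#' amplitude, and the population sizes (n_E excitatory units plus a single
#' shared inhibitory unit).
#'
#' Times are in ms and rates in Hz; currents are in the dimensionless units of
#' the weight matrix. The defaults are the fiducial values of the model:
#' excitatory units are bistable under strong self-excitation, the inhibitory
#' unit provides global feedback. `tau_r` defaults to 10 ms (the value quoted
#' with the rate equation). `Theta_I` defaults to 10 (of the two listed values,
#' 10 and 12, only 10 keeps the quiescent baseline stable and yields the
#' perfect-discrimination regime; see the methods vignette). Both are
#' configurable.
#'
#' @param tau_r firing-rate time constant (ms).
#' @param tau_s_E,tau_s_I synaptic gating time constants (ms) for excitatory
#'   and inhibitory units.
#' @param tau_D synaptic depression time constant (ms).
#' @param Theta_E,Theta_I f-I threshold currents.
#' @param Delta_E,Delta_I f-I sensitivity currents (slope parameters).
#' @param p0_E,p0_I vesicle release probabilities, in `[0, 1]`.
#' @param r_max_E,r_max_I maximum firing rates (Hz).
#' @param alpha_tilde maximal open-receptor fraction, in `(0, 1]`.
#' @param sigma white-noise current amplitude (see
#'   [integration_settings()] for how it is discretized).
#' @param n_E number of excitatory units.
#' @param n_I number of inhibitory units (the model uses exactly 1).
#' @return An object of class `model_params`.
#' @export
model_params <- function(tau_r = 10, tau_s_E = 50, tau_s_I = 5, tau_D = 500,
                         Theta_E = 6, Theta_I = 10, Delta_E = 1, Delta_I = 3,
                         p0_E = 1, p0_I = 0.1, r_max_E = 100, r_max_I = 200,
                         alpha_tilde = 1, sigma = 0, n_E = 100, n_I = 1) {
  p <- list(tau_r = tau_r, tau_s_E = tau_s_E, tau_s_I = tau_s_I, tau_D = tau_D,
            Theta_E = Theta_E, Theta_I = Theta_I, Delta_E = Delta_E,
            Delta_I = Delta_I, p0_E = p0_E, p0_I = p0_I,
            r_max_E = r_max_E, r_max_I = r_max_I, alpha_tilde = alpha_tilde,
            sigma = sigma, n_E = as.integer(n_E), n_I = as.integer(n_I))
  for (nm in c("tau_r", "tau_s_E", "tau_s_I", "tau_D"))
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter error: ", nm, " must be a positive time constant (ms)")
  for (nm in c("p0_E", "p0_I"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("parameter error: ", nm, " must lie in [0, 1]")
  for (nm in c("r_max_E", "r_max_I", "Delta_E", "Delta_I"))
    if (p[[nm]] <= 0) stop("parameter error: ", nm, " must be > 0")
  if (p$alpha_tilde <= 0 || p$alpha_tilde > 1)
    stop("parameter error: alpha_tilde must lie in (0, 1]")
  if (p$sigma < 0) stop("parameter error: sigma must be >= 0")
  if (p$n_E < 1) stop("parameter error: n_E must be >= 1")
  if (p$n_I != 1L) stop("parameter error: the model uses exactly one inhibitory unit")
  structure(p, class = "model_params")
}

#' Connectivity configuration
#'
#' Scales and bounds of the random weight matrix. Excitatory self-weights are
#' drawn uniform i.i.d. in `[(1 - sigma_w) * w_self, w_self]`; excitatory
#' cross-weights uniform i.i.d. in `[0, w_cross_max]`; the E-to-I, I-to-E and
#' I-to-I weights are fixed constants. Defaults are the fiducial point
#' (`w_self = 89`, `w_cross_max = 0.346`, `w_EI = 0.665`, `w_IE = -540`).
#' `sigma_w` is not part of the published fiducial list; the default 0.1 is
#' the midpoint of its stated range `[0, 0.2]`.
#'
#' @param w_self excitatory self-weight scale (> 0).
#' @param sigma_w fractional spread of self-weights, in `[0, 1]`.
#' @param w_cross_max upper bound of E-to-E cross weights (>= 0).
#' @param w_EI E-to-I weight (>= 0).
#' @param w_IE I-to-E weight (<= 0).
#' @param w_II I-to-I weight (fixed at 0 in the model).
#' @return An object of class `weight_config`.
#' @export
weight_config <- function(w_self = 89, sigma_w = 0.1, w_cross_max = 0.346,
                          w_EI = 0.665, w_IE = -540, w_II = 0) {
  if (w_self <= 0) stop("parameter error: w_self must be > 0")
  if (sigma_w < 0 || sigma_w > 1) stop("parameter error: sigma_w must lie in [0, 1]")
  if (w_cross_max < 0) stop("parameter error: w_cross_max must be >= 0")
  if (w_EI < 0) stop("parameter error: w_EI must be >= 0")
  if (w_IE > 0) stop("parameter error: w_IE must be <= 0")
  if (w_II != 0) stop("parameter error: w_II is fixed at 0")
  structure(list(w_self = w_self, sigma_w = sigma_w, w_cross_max = w_cross_max,
                 w_EI = w_EI, w_IE = w_IE, w_II = w_II),
            class = "weight_config")
}

#' Integration settings
#'
#' Fixed-step Euler-Maruyama settings. `noise_convention` selects how the
#' noise amplitude `sigma` maps to the per-step current noise:
#' `"flat_spectrum"` (default) uses standard deviation `sigma / sqrt(dt)` with
#' `dt` in seconds, so that the rate fluctuations it produces are independent
#' of the step size; `"per_step"` adds noise with standard deviation `sigma`
#' at every step.
#'
#' @param dt step size in ms (must be in `(0, 1]`).
#' @param noise_convention `"flat_spectrum"` or `"per_step"`.
#' @return An object of class `integration_settings`.
#' @export
integration_settings <- function(dt = 0.5,
                                 noise_convention = c("flat_spectrum", "per_step")) {
  noise_convention <- match.arg(noise_convention)
  if (!is.numeric(dt) || dt <= 0) stop("parameter error: dt must be > 0")
  if (dt > 1) stop("parameter error: dt must be <= 1 ms for a stable Euler step")
  structure(list(dt = dt, noise_convention = noise_convention),
            class = "integration_settings")
}

# per-step current noise sd implied by (params, settings)
noise_sd_per_step <- function(params, settings) {
  if (params$sigma == 0) return(0)
  switch(settings$noise_convention,
         flat_spectrum = params$sigma / sqrt(settings$dt / 1000),
         per_step = params$sigma)
}

# expand kind-specific constants to per-unit vectors, E units first then I
unit_constants <- function(params) {
  kinds <- c(rep("E", params$n_E), rep("I", params$n_I))
  pick <- function(e, i) ifelse(kinds == "E", e, i)
  list(kinds = kinds,
       tau_s = pick(params$tau_s_E, params$tau_s_I),
       theta = pick(params$Theta_E, params$Theta_I),
       delta = pick(params$Delta_E, params$Delta_I),
       p0 = pick(params$p0_E, params$p0_I),
       r_max = pick(params$r_max_E, params$r_max_I))
}

# evaluate expr with a temporary RNG seed, restoring global RNG state after
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed streams: every random draw traces back to one master
derive_seeds <- function(master_seed, n, salt = 0L) {
  with_rng_seed(as.integer(master_seed %% 2147483647L) + as.integer(salt),
                sample.int(2147483646L, n))
}
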