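#' Build a random connectivity matrix
#'
#' Draws the signed weight matrix over `n_E` excitatory units plus the single
#' inhibitory unit. Entry `(i, j)` is the weight from source unit `i` to
#' target unit `j`, so the recurrent input to unit `j` is
#' `sum_i s_i * W[i, j]`. Excitatory self-weights (the diagonal of the E
#' block) are uniform i.i.d. in `[(1 - sigma_w) * w_self, w_self]`;
#' off-diagonal E-to-E weights are uniform i.i.d. in `[0, w_cross_max]`; all
#' E-to-I weights equal `w_EI`, all I-to-E weights equal `w_IE`, and the
#' I-to-I entry is 0. Strong self-weights render each excitatory unit
#' bistable.
#'
#' @param cfg a [weight_config()].
#' @param params a [model_params()] (supplies `n_E`, `n_I`).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return An object of class `connectivity`: a list with `weights`
#'   (the `(n_E + 1) x (n_E + 1)` matrix) and `unit_kinds` (`"E"`/`"I"`).
#' @export
build_connectivity <- function(cfg, params, seed) {
  stopifnot(inherits(cfg, "weight_config"), inherits(params, "model_params"))
  n_E <- params$n_E
  n <- n_E + params$n_I
  W <- matrix(0, n, n)
  with_rng_seed(seed, {
    self <- stats::runif(n_E, min = (1 - cfg$sigma_w) * cfg$w_self, max = cfg$w_self)
    cross <- stats::runif(n_E * n_E, min = 0, max = cfg$w_cross_max)
    W[seq_len(n_E), seq_len(n_E)] <- cross
    diag(W)[seq_len(n_E)] <- self
  })
  W[seq_len(n_E), n] <- cfg$w_EI
  W[n, seq_len(n_E)] <- cfg$w_IE
  W[n, n] <- cfg$w_II
  structure(list(weights = W,
                 unit_kinds = c(rep("E", n_E), rep("I", params$n_I)),
                 config = cfg, seed = as.integer(seed)),
            class = "connectivity")
}

#' Remove excitatory cross-connections
#'
#' Sets every off-diagonal entry of the E-to-E block to zero, leaving
#' self-weights and the inhibitory loop untouched. Used for the
#' cross-connection ablation.
#'
#' @param conn a [build_connectivity()] object.
#' @return A `connectivity` object without E-to-E cross weights.
#' @export
remove_cross_excitation <- function(conn) {
  stopifnot(inherits(conn, "connectivity"))
  n_E <- sum(conn$unit_kinds == "E")
  W <- conn$weights
  block <- W[seq_len(n_E), seq_len(n_E)]
  block[row(block) != col(block)] <- 0
  W[seq_len(n_E), seq_len(n_E)] <- block
  conn$weights <- W
  conn
}

#' Logistic f-I curve
#'
#' Steady-state firing rate as a function of input current:
#' `r_max / (1 + exp((theta - I) / delta))`. Strictly increasing in `I`, with
#' range `(0, r_max)`; the exponent is clamped at +/-500 so extreme currents
#' saturate instead of overflowing.
#'
#' @param I input current (vectorized).
#' @param theta threshold current.
#' @param delta sensitivity current (> 0).
#' @param r_max maximum rate (Hz).
#' @return Firing rate(s) in Hz.
#' @export
fi_curve <- function(I, theta, delta, r_max) {
  if (any(delta <= 0)) stop("parameter error: delta must be > 0")
  ex <- pmin(pmax((theta - I) / delta, -500), 500)
  r_max / (1 + exp(ex))
}

#' Network state
#'
#' One snapshot of the dynamical variables: per-unit firing rates `r` (Hz),
#' synaptic gating fractions `s` in `[0, 1]`, and depression fractions `D` in
#' `(0, 1]`, at time `t` (ms).
#'
#' @param r,s,D numeric vectors of equal length (E units first, inhibitory
#'   unit last).
#' @param t time in ms.
#' @return An object of class `network_state`.
#' @export
network_state <- function(r, s, D, t = 0) {
  n <- length(r)
  if (length(s) != n || length(D) != n)
    stop("structural error: r, s, D must have equal length")
  if (any(r < 0)) stop("state error: rates must be >= 0")
  if (any(s < 0 | s > 1)) stop("state error: s must lie in [0, 1]")
  if (any(D <= 0 | D > 1)) stop("state error: D must lie in (0, 1]")
  structure(list(r = as.numeric(r), s = as.numeric(s), D = as.numeric(D),
                 t = t), class = "network_state")
}

#' Quiescent initial state
#'
#' All rates and gating variables at zero, depression fully recovered
#' (`D = 1`).
#'
#' @param params a [model_params()].
#' @return A [network_state()].
#' @export
quiescent_state <- function(params) {
  n <- params$n_E + params$n_I
  network_state(rep(0, n), rep(0, n), rep(1, n), t = 0)
}

#' Time derivatives of the network dynamics
#'
#' Deterministic drift of the rate/gating/depression system at a given state
#' (noise excluded). The input current to unit `j` is
#' `I_j = sum_i s_i W[i, j] + I_app_j`; then
#' `dr/dt = (-r + f(I)) / tau_r`,
#' `ds/dt = (-s + alpha * p0 * r * D * tau_s * (1 - s)) / tau_s`, and
#' `dD/dt = (1 - D - p0 * r * tau_D * D) / tau_D`, with the kind-specific
#' constants (`tau_s`, `p0`, `Theta`, `Delta`, `r_max`) applied per unit.
#' Rates are in Hz, so rate-times-tau products convert `tau` to seconds.
#'
#' @param state a [network_state()].
#' @param W a [build_connectivity()] object (or bare weight matrix).
#' @param I_app per-unit applied current (defaults to 0).
#' @param params a [model_params()].
#' @return A list with `dr`, `ds`, `dD` (per ms).
#' @export
drift <- function(state, W, I_app = NULL, params) {
  Wm <- if (inherits(W, "connectivity")) W$weights else W
  n <- length(state$r)
  if (nrow(Wm) != n || ncol(Wm) != n)
    stop("structural error: weight matrix is ", nrow(Wm), "x", ncol(Wm),
         " but state has ", n, " units")
  if (is.null(I_app)) I_app <- rep(0, n)
  if (length(I_app) != n) stop("structural error: I_app has wrong length")
  u <- unit_constants(params)
  I <- as.numeric(crossprod(Wm, state$s)) + I_app
  f <- fi_curve(I, u$theta, u$delta, u$r_max)
  x <- params$alpha_tilde * u$p0 * state$r * state$D * (u$tau_s / 1000)
  list(dr = (-state$r + f) / params$tau_r,
       ds = (-state$s + x * (1 - state$s)) / u$tau_s,
       dD = (1 - state$D - u$p0 * state$r * (params$tau_D / 1000) * state$D) /
         params$tau_D)
}
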