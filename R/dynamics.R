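#' Applied current timecourse
#'
#' Piecewise-constant map from time to a per-unit current vector, represented
#' as a set of non-overlapping pulses. Only excitatory units ever receive
#' applied current; the inhibitory unit's row is always zero.
#'
#' @param onsets,offsets pulse start/end times (ms), sorted, non-overlapping.
#' @param currents matrix with one column per pulse and one row per unit
#'   (E units then the inhibitory unit).
#' @return An object of class `applied_current`.
#' @export
applied_current <- function(onsets, offsets, currents) {
  onsets <- as.numeric(onsets); offsets <- as.numeric(offsets)
  if (length(onsets) != length(offsets))
    stop("structural error: onsets/offsets length mismatch")
  if (any(offsets <= onsets)) stop("structural error: pulses must have positive duration")
  if (length(onsets) > 1 && any(diff(onsets) < 0))
    stop("structural error: pulses must be sorted by onset")
  if (length(onsets) > 1 && any(onsets[-1] < offsets[-length(offsets)]))
    stop("structural error: pulses must not overlap")
  if (!is.matrix(currents) || ncol(currents) != length(onsets))
    stop("structural error: currents must be a units x pulses matrix")
  structure(list(onsets = onsets, offsets = offsets, currents = currents),
            class = "applied_current")
}

empty_current <- function(n_units) {
  applied_current(numeric(0), numeric(0), matrix(0, n_units, 0))
}

# current vector at time t (ms)
current_at <- function(applied, t, n_units) {
  if (is.null(applied) || length(applied$onsets) == 0) return(rep(0, n_units))
  k <- which(applied$onsets <= t & t < applied$offsets)
  if (length(k) == 0) rep(0, n_units) else applied$currents[, k[1]]
}

#' Total charge delivered per unit
#'
#' Sum over pulses of amplitude times duration, per unit. Useful as a
#' conservation check on realized stimulus timecourses.
#'
#' @param applied an [applied_current()].
#' @return Numeric vector of per-unit charge (current x ms).
#' @export
applied_charge <- function(applied) {
  if (length(applied$onsets) == 0) return(rep(0, nrow(applied$currents)))
  as.numeric(applied$currents %*% (applied$offsets - applied$onsets))
}

#' One Euler-Maruyama step (reference implementation)
#'
#' Advances the state by `dt`: the deterministic [drift()] is applied to all
#' variables, and independent Gaussian noise is added to each unit's input
#' current according to the noise convention in `settings`. This plain-R
#' stepper is the reference route; [simulate()] uses a compiled kernel with
#' identical update rules.
#'
#' @param state a [network_state()].
#' @param W connectivity.
#' @param I_app per-unit applied current vector (or NULL).
#' @param params a [model_params()].
#' @param settings an [integration_settings()].
#' @return The updated [network_state()].
#' @export
step <- function(state, W, I_app = NULL, params, settings) {
  Wm <- if (inherits(W, "connectivity")) W$weights else W
  n <- length(state$r)
  if (is.null(I_app)) I_app <- rep(0, n)
  sd_step <- noise_sd_per_step(params, settings)
  if (sd_step > 0) I_app <- I_app + stats::rnorm(n, 0, sd_step)
  d <- drift(state, Wm, I_app, params)
  dt <- settings$dt
  r <- state$r + dt * d$dr
  s <- state$s + dt * d$ds
  D <- state$D + dt * d$dD
  s <- clip_tiny(s, 0, 1, "gating variable s")
  D <- clip_tiny(D, 0, 1, "depression variable D")
  network_state(r, s, D, t = state$t + dt)
}

clip_tiny <- function(x, lo, hi, name, tol = 1e-9) {
  over <- x > hi; under <- x < lo
  if (any(x[over] - hi >= tol) || any(lo - x[under] >= tol)) {
    bad <- which((over & x - hi >= tol) | (under & lo - x >= tol))[1]
    stop("integration error: ", name, " of unit ", bad, " left [", lo, ", ",
         hi, "] (value ", x[bad], ")")
  }
  x[over] <- hi; x[under] <- lo
  x
}

#' Simulate the network
#'
#' Fixed-step integration from `state0` for `t_end` ms under an optional
#' applied-current timecourse, with optional trajectory sampling and
#' averaging of rates over a time window. Reproducible given `seed`; with
#' `sigma = 0` the trajectory is deterministic and seed-independent.
#'
#' @param state0 initial [network_state()].
#' @param W connectivity.
#' @param applied an [applied_current()] or NULL for no stimulus.
#' @param t_end simulation length (ms, > 0).
#' @param params a [model_params()].
#' @param settings an [integration_settings()].
#' @param seed integer seed for the noise stream.
#' @param record_stride sample the trajectory every `record_stride` steps
#'   (0 = no trajectory).
#' @param avg_window optional `c(start, end)` in ms: average rates over
#'   sampled steps with `start <= t < end`.
#' @param clamp_D if TRUE, depression is disabled (`D` held at its initial
#'   value, normally 1) - the depression ablation.
#' @param engine `"cpp"` (compiled kernel) or `"r"` (reference stepper; slow,
#'   intended for cross-checking).
#' @return A list with the final `state`, `mean_rates` (all units; NULL if no
#'   window), and if recorded `times` plus `r`, `s`, `D` trajectory matrices
#'   (time in rows, units in columns).
#' @export
simulate <- function(state0, W, applied = NULL, t_end, params, settings,
                     seed = 1L, record_stride = 0L, avg_window = NULL,
                     clamp_D = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (t_end <= 0) stop("parameter error: t_end must be > 0")
  Wm <- if (inherits(W, "connectivity")) W$weights else W
  n <- length(state0$r)
  u <- unit_constants(params)
  if (is.null(applied)) applied <- empty_current(n)
  if (nrow(applied$currents) != n && length(applied$onsets) > 0)
    stop("structural error: applied current has wrong number of units")
  if (is.null(avg_window)) avg_window <- c(0, -1)
  sd_step <- noise_sd_per_step(params, settings)

  if (engine == "cpp") {
    res <- .simulate_kernel(t(Wm), state0$r, state0$s, state0$D,
                            u$tau_s, u$theta, u$delta, u$p0, u$r_max,
                            params$tau_r, params$tau_D, params$alpha_tilde,
                            applied$onsets, applied$offsets,
                            if (length(applied$onsets)) applied$currents
                            else matrix(0, n, 0),
                            settings$dt, t_end, sd_step,
                            as.integer(seed) %% 2147483647L,
                            as.integer(record_stride),
                            avg_window[1], avg_window[2], isTRUE(clamp_D))
    out <- list(state = network_state(res$r, res$s, res$D,
                                      t = state0$t + res$t),
                mean_rates = if (length(res$mean_r)) as.numeric(res$mean_r)
                             else NULL)
    if (record_stride > 0) {
      out$times <- state0$t + res$traj_t
      out$r <- t(res$traj_r); out$s <- t(res$traj_s); out$D <- t(res$traj_D)
    }
    return(out)
  }

  # reference R route
  n_steps <- round(t_end / settings$dt)
  st <- state0
  t0 <- state0$t
  rec_t <- numeric(0); rec_r <- NULL; rec_s <- NULL; rec_D <- NULL
  rate_sum <- rep(0, n); n_avg <- 0
  with_rng_seed(seed, {
    for (k in 0:n_steps) {
      tk <- k * settings$dt
      if (record_stride > 0 && k %% record_stride == 0) {
        rec_t <- c(rec_t, t0 + tk)
        rec_r <- rbind(rec_r, st$r); rec_s <- rbind(rec_s, st$s)
        rec_D <- rbind(rec_D, st$D)
      }
      if (avg_window[2] > avg_window[1] && tk >= avg_window[1] &&
          tk < avg_window[2]) {
        rate_sum <- rate_sum + st$r; n_avg <- n_avg + 1
      }
      if (k == n_steps) break
      I_app <- current_at(applied, tk, n)
      st2 <- step(st, Wm, I_app, params, settings)
      if (clamp_D) st2$D <- st$D
      st <- st2
    }
  })
  out <- list(state = st,
              mean_rates = if (n_avg > 0) rate_sum / n_avg else NULL)
  if (record_stride > 0) {
    out$times <- rec_t; out$r <- rec_r; out$s <- rec_s; out$D <- rec_D
  }
  out
}
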