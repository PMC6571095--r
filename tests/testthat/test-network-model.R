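test_that("fi_curve matches the logistic closed form and saturates safely", {
  # midpoint: I = theta gives r_max / 2
  expect_equal(fi_curve(6, 6, 1, 100), 50)
  # analytic point: I = theta + ln 9 gives 0.9 * r_max
  expect_equal(fi_curve(6 + log(9), 6, 1, 100), 90)
  # saturation without overflow at extreme currents
  expect_equal(fi_curve(-1e6, 6, 1, 100), 0, tolerance = 1e-12)
  expect_equal(fi_curve(1e6, 6, 1, 100), 100)
  expect_true(is.finite(fi_curve(-1e308, 6, 1, 100)))
  # strictly increasing
  I <- seq(-20, 20, by = 0.5)
  expect_true(all(diff(fi_curve(I, 6, 1, 100)) > 0))
  expect_error(fi_curve(0, 6, 0, 100), "delta")
})

test_that("connectivity obeys its structural invariants", {
  p <- tiny_params()
  cfg <- weight_config(w_self = 88, sigma_w = 0.15, w_cross_max = 0.476)
  conn <- build_connectivity(cfg, p, seed = 42)
  W <- conn$weights
  nE <- p$n_E
  d <- diag(W)[1:nE]
  expect_true(all(d >= (1 - cfg$sigma_w) * cfg$w_self & d <= cfg$w_self))
  off <- W[1:nE, 1:nE][row(diag(nE)) != col(diag(nE))]
  expect_true(all(off >= 0 & off <= cfg$w_cross_max))
  expect_true(all(W[1:nE, nE + 1] == cfg$w_EI))
  expect_true(all(W[nE + 1, 1:nE] == cfg$w_IE))
  expect_identical(W[nE + 1, nE + 1], 0)
  # deterministic given seed, different across seeds
  expect_identical(W, build_connectivity(cfg, p, seed = 42)$weights)
  expect_false(identical(W, build_connectivity(cfg, p, seed = 43)$weights))
  # zero-spread degenerate case: every self-weight exactly w_self
  c0 <- build_connectivity(weight_config(w_self = 89, sigma_w = 0), p, seed = 1)
  expect_true(all(diag(c0$weights)[1:nE] == 89))
  # invalid configurations are rejected
  expect_error(weight_config(w_IE = 5), "w_IE")
  expect_error(weight_config(sigma_w = -0.1), "sigma_w")
  expect_error(weight_config(w_cross_max = -1), "w_cross_max")
})

test_that("connectivity draws match their declared uniform distributions", {
  p <- model_params()  # 100 E units -> 9900 cross weights per draw
  cfg <- weight_config(w_self = 88, sigma_w = 0.2, w_cross_max = 0.476)
  nE <- p$n_E
  cross <- unlist(lapply(1:2, function(s) {
    W <- build_connectivity(cfg, p, seed = s)$weights[1:nE, 1:nE]
    W[row(W) != col(W)]
  }))
  expect_gte(length(cross), 1e4)
  ks1 <- stats::ks.test(cross, "punif", 0, cfg$w_cross_max)
  expect_gt(ks1$p.value, 0.01)
  selfs <- unlist(lapply(1:100, function(s)
    diag(build_connectivity(cfg, p, seed = s)$weights)[1:nE]))
  ks2 <- stats::ks.test(selfs, "punif", (1 - cfg$sigma_w) * cfg$w_self,
                        cfg$w_self)
  expect_gt(ks2$p.value, 0.01)
})

test_that("drift reproduces the algebraic fixed points of s and D", {
  p <- tiny_params()
  n <- p$n_E + 1
  # depression nullcline at clamped rate: D* = 1 / (1 + p0 r tau_D)
  r_clamp <- 100
  D_star <- 1 / (1 + p$p0_E * r_clamp * p$tau_D / 1000)
  expect_equal(D_star, 1 / 51)
  # gating nullcline: s* = x / (1 + x), x = alpha p0 r D tau_s
  x <- p$alpha_tilde * p$p0_E * r_clamp * D_star * p$tau_s_E / 1000
  s_star <- x / (1 + x)
  st <- network_state(rep(r_clamp, n), rep(s_star, n), rep(D_star, n))
  W0 <- matrix(0, n, n)
  d <- drift(st, W0, NULL, p)
  expect_equal(d$ds[1:p$n_E], rep(0, p$n_E), tolerance = 1e-12)
  expect_equal(d$dD[1:p$n_E], rep(0, p$n_E), tolerance = 1e-12)
  # dimension mismatches are structural errors
  expect_error(drift(st, matrix(0, 2, 2), NULL, p), "structural")
  expect_error(drift(st, W0, rep(0, 3), p), "structural")
})

test_that("simulated D and s converge to their clamped-rate closed forms", {
  # integrate the gating/depression subsystem with the rate pinned by a
  # strong applied current, then compare against the closed forms
  p <- model_params(n_E = 1)
  W0 <- matrix(0, 2, 2)
  st <- network_state(c(100, 0), c(0, 0), c(1, 1))
  # hold r at r_max via a saturating applied current
  ac <- applied_current(0, 10 * p$tau_D, matrix(c(1e4, 0), 2, 1))
  res <- simulate(st, W0, ac, t_end = 10 * p$tau_D, params = p,
                  settings = integration_settings(dt = 0.1))
  r_eff <- res$state$r[1]
  D_expect <- 1 / (1 + p$p0_E * r_eff * p$tau_D / 1000)
  x <- p$alpha_tilde * p$p0_E * r_eff * D_expect * p$tau_s_E / 1000
  expect_equal(res$state$D[1], D_expect, tolerance = 1e-6)
  expect_equal(res$state$s[1], x / (1 + x), tolerance = 1e-6)
})

test_that("noiseless integration is deterministic and seed-independent", {
  fx <- fiducial_point(n_E = 12)
  conn <- build_connectivity(fx$wcfg, fx$params, seed = 5)
  st <- quiescent_state(fx$params)
  pat <- make_patterns(1, 0.5, 1.07, 0, 12, seed = 1)
  ac <- realize_timecourse(1, pat, 13, onset_interval = 300, duration = 100)
  a <- simulate(st, conn, ac, t_end = 500, params = fx$params,
                settings = fx$settings, seed = 1)
  b <- simulate(st, conn, ac, t_end = 500, params = fx$params,
                settings = fx$settings, seed = 999)
  expect_identical(a$state$r, b$state$r)
  expect_identical(a$state$s, b$state$s)
  expect_identical(a$state$D, b$state$D)
})

test_that("Euler integration converges at first order in dt", {
  fx <- fiducial_point(n_E = 12)
  conn <- build_connectivity(fx$wcfg, fx$params, seed = 5)
  st <- quiescent_state(fx$params)
  pat <- make_patterns(1, 0.5, 1.07, 0, 12, seed = 1)
  ac <- realize_timecourse(1, pat, 13, onset_interval = 300, duration = 100)
  final_r <- function(dt)
    simulate(st, conn, ac, t_end = 400, params = fx$params,
             settings = integration_settings(dt = dt))$state$r
  e1 <- max(abs(final_r(0.5) - final_r(0.125)))
  e2 <- max(abs(final_r(0.25) - final_r(0.125)))
  # halving dt should roughly halve the error against a finer reference
  expect_lt(e2, e1)
  expect_lt(e2 / e1, 0.8)
})

test_that("noise produces rate fluctuations that grow with sigma", {
  # a decoupled unit below threshold, integrated under two noise levels
  base <- function(sigma) {
    p <- model_params(n_E = 1, sigma = sigma)
    st <- network_state(c(0, 0), c(0, 0), c(1, 1))
    vapply(1:60, function(s)
      simulate(st, matrix(0, 2, 2), NULL, t_end = 200, params = p,
               settings = integration_settings(), seed = s)$state$r[1],
      numeric(1))
  }
  v_small <- stats::var(base(0.0005))
  v_big <- stats::var(base(0.002))
  expect_gt(v_big, v_small)
  # and sigma = 0 gives zero variance across seeds
  expect_equal(stats::var(base(0)), 0)
})

test_that("compiled kernel and plain-R stepper agree", {
  fx <- fiducial_point(n_E = 8)
  conn <- build_connectivity(fx$wcfg, fx$params, seed = 3)
  st <- quiescent_state(fx$params)
  pat <- make_patterns(1, 0.5, 1.07, 0, 8, seed = 2)
  ac <- realize_timecourse(1, pat, 9, onset_interval = 300, duration = 100)
  a <- simulate(st, conn, ac, t_end = 300, params = fx$params,
                settings = fx$settings, engine = "cpp",
                avg_window = c(150, 300), record_stride = 100)
  b <- simulate(st, conn, ac, t_end = 300, params = fx$params,
                settings = fx$settings, engine = "r",
                avg_window = c(150, 300), record_stride = 100)
  expect_equal(a$state$r, b$state$r, tolerance = 1e-10)
  expect_equal(a$state$s, b$state$s, tolerance = 1e-10)
  expect_equal(a$state$D, b$state$D, tolerance = 1e-10)
  expect_equal(a$mean_rates, b$mean_rates, tolerance = 1e-10)
  expect_equal(a$times, b$times)
  expect_equal(a$r[nrow(a$r), ], unname(b$r[nrow(b$r), ]), tolerance = 1e-10)
})

test_that("state bounds hold along trajectories across random parameter draws", {
  # property test over configurations drawn inside the documented ranges
  for (k in 1:5) {
    cfg <- withr::with_seed(k, weight_config(
      w_self = runif(1, 71, 110), sigma_w = runif(1, 0, 0.2),
      w_cross_max = runif(1, 0, 0.56), w_EI = runif(1, 0.6, 0.72),
      w_IE = -runif(1, 480, 580)))
    p <- model_params(n_E = 12, sigma = withr::with_seed(k + 100, runif(1, 0, 0.002)))
    conn <- build_connectivity(cfg, p, seed = k)
    pat <- make_patterns(2, 0.59, withr::with_seed(k + 200, runif(1, 0.4, 1.8)),
                         0, 12, seed = k)
    ac <- realize_timecourse(c(1, 2, 1), pat, 13, onset_interval = 300,
                             duration = 100)
    res <- simulate(quiescent_state(p), conn, ac, t_end = 1000, params = p,
                    settings = integration_settings(), seed = k,
                    record_stride = 20)
    expect_true(all(res$r >= 0))
    expect_true(all(res$r[, 1:12] <= p$r_max_E))
    expect_true(all(res$r[, 13] <= p$r_max_I))
    expect_true(all(res$s >= 0 & res$s <= 1))
    expect_true(all(res$D > 0 & res$D <= 1))
  }
})

test_that("trajectory sampling stride does not affect the dynamics", {
  fx <- fiducial_point(n_E = 10)
  conn <- build_connectivity(fx$wcfg, fx$params, seed = 7)
  st <- quiescent_state(fx$params)
  pat <- make_patterns(1, 0.5, 1.07, 0, 10, seed = 4)
  ac <- realize_timecourse(1, pat, 11, onset_interval = 300, duration = 100)
  a <- simulate(st, conn, ac, t_end = 400, params = fx$params,
                settings = fx$settings, record_stride = 10)
  b <- simulate(st, conn, ac, t_end = 400, params = fx$params,
                settings = fx$settings, record_stride = 77)
  expect_identical(a$state$r, b$state$r)
  expect_identical(a$state$D, b$state$D)
})

test_that("an isolated bistable unit stays active long after a pulse; a weak one does not", {
  p <- model_params(n_E = 1)
  set <- integration_settings()
  persists <- function(w_self) {
    W <- matrix(0, 2, 2); W[1, 1] <- w_self
    st <- network_state(c(0, 0), c(0, 0), c(1, 1))
    ac <- applied_current(0, 250, matrix(c(1.07, 0), 2, 1))
    res <- simulate(st, W, ac, t_end = 250 + 1250, params = p, settings = set,
                    record_stride = 100)
    post <- res$r[res$times >= 250, 1]
    all(post > 30)
  }
  expect_true(persists(89))   # fiducial self-excitation sustains activity
  expect_false(persists(20))  # weak self-excitation decays back
})
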