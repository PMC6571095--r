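test_that("ablations alter exactly the targeted mechanism", {
  fx <- fiducial_point(n_E = 12)
  conn <- build_connectivity(fx$wcfg, fx$params, seed = 1)
  # cross-excitation removal zeroes the off-diagonal E block only
  cut <- remove_cross_excitation(conn)
  nE <- 12
  off <- cut$weights[1:nE, 1:nE][row(diag(nE)) != col(diag(nE))]
  expect_true(all(off == 0))
  expect_identical(diag(cut$weights)[1:nE], diag(conn$weights)[1:nE])
  expect_identical(cut$weights[, nE + 1], conn$weights[, nE + 1])
  # depression clamp keeps D at exactly 1 for an entire stimulated trial
  pats <- make_patterns(1, 0.5, 1.07, 0, 12, seed = 2)
  ac <- realize_timecourse(1, pats, 13, onset_interval = 300, duration = 100)
  res <- simulate(quiescent_state(fx$params), conn, ac, t_end = 400,
                  params = fx$params, settings = fx$settings,
                  record_stride = 10, clamp_D = TRUE)
  expect_true(all(res$D == 1))
  # and matches a reduced model without depression: same trajectory as a
  # parameter set whose depression is inert (p0 enters r*D product only
  # through D's equation; with D clamped the gating drive uses D = 1)
  res2 <- simulate(quiescent_state(fx$params), conn, ac, t_end = 400,
                   params = fx$params, settings = fx$settings,
                   record_stride = 10, clamp_D = TRUE, engine = "r")
  expect_equal(res$r[nrow(res$r), ], unname(res2$r[nrow(res2$r), ]),
               tolerance = 1e-10)
})

test_that("sweeps are pure functions of their grid and master seed", {
  fx <- fiducial_point(n_E = 12)
  ax <- list(name = "w_self", values = c(85, 89))
  run <- function() sweep_grid(ax, NULL, n_networks = 2, task = "two_choice",
                               params = fx$params, wcfg = fx$wcfg,
                               stim = c(list(f_stim = 0.5, I_stim = 1.07,
                                             sigma_I = 0),
                                        tiny_stim,
                                        list(duration_sd = 0, amplitude_sd = 0)),
                               settings = fx$settings, master_seed = 5,
                               n_train = 2, n_test = 2, dedup = TRUE)
  a <- run(); b <- run()
  expect_equal(a, b, ignore_attr = TRUE)
  expect_identical(nrow(a), 4L)   # 2 points x 2 networks
  expect_true(all(a$kappa >= 0 & a$kappa <= 1))
  expect_true(all(a$accuracy >= 0 & a$accuracy <= 1))
  expect_identical(names(a)[1], "w_self")
})

test_that("sweep caching resumes without recomputation", {
  fx <- fiducial_point(n_E = 12)
  ax <- list(name = "w_self", values = c(89))
  dir <- withr::local_tempdir()
  stim <- c(list(f_stim = 0.5, I_stim = 1.07, sigma_I = 0), tiny_stim,
            list(duration_sd = 0, amplitude_sd = 0))
  a <- sweep_grid(ax, NULL, n_networks = 1, params = fx$params,
                  wcfg = fx$wcfg, stim = stim, settings = fx$settings,
                  master_seed = 5, n_train = 1, n_test = 1, dedup = TRUE,
                  cache_dir = dir)
  # poison the cache: a resumed run must read it rather than recompute
  cached <- list.files(dir, full.names = TRUE)
  expect_length(cached, 1)
  tab <- utils::read.csv(cached); tab$kappa <- 0.123
  utils::write.csv(tab, cached, row.names = FALSE)
  b <- sweep_grid(ax, NULL, n_networks = 1, params = fx$params,
                  wcfg = fx$wcfg, stim = stim, settings = fx$settings,
                  master_seed = 5, n_train = 1, n_test = 1, dedup = TRUE,
                  cache_dir = dir)
  expect_equal(b$kappa, 0.123)
})

test_that("generalization splits accuracy by trained and untrained sequences", {
  fx <- fiducial_point(n_E = 12)
  conn <- build_connectivity(fx$wcfg, fx$params, seed = 4)
  pats <- make_patterns(2, 0.5, 1.07, 0, 12, seed = 3)
  seqs <- enumerate_binary_sequences(4)
  lab <- majority_labels(seqs)
  margin <- abs(rowSums(seqs == 1) - rowSums(seqs == 2))
  stim <- c(list(f_stim = 0.5, I_stim = 1.07, sigma_I = 0), tiny_stim,
            list(duration_sd = 0, amplitude_sd = 0))
  # train only on 3-1 sequences, evaluate everywhere
  gt <- generalization_test(conn, pats, seqs, fx$params, fx$settings,
                            train_subset = margin == 2,
                            train_stim = stim, test_stim = stim,
                            n_train = 2, n_test = 2, master_seed = 6,
                            dedup = TRUE)
  expect_true(all(c("accuracy_overall", "accuracy_trained",
                    "accuracy_untrained") %in% names(gt)))
  expect_true(all(gt$per_trial$trained == (margin[gt$per_trial$sequence_id] == 2)))
  # train = test conditions on all non-ties equals the standard accuracy
  pt <- run_task_point("two_choice", fx$params, fx$wcfg, stim, fx$settings,
                       network_seed = 99, n_train = 2, n_test = 2,
                       sequences = seqs, dedup = TRUE)
  expect_true(is.finite(pt$accuracy))
  expect_error(generalization_test(conn, pats, seqs, fx$params, fx$settings,
                                   train_subset = rep(FALSE, 16),
                                   train_stim = stim, n_train = 1, n_test = 1),
               "both classes")
})

test_that("unit correlations match closed-form Pearson values", {
  seqs <- enumerate_binary_sequences(4)
  n_left <- rowSums(seqs == 1)
  # synthetic table: unit 1 copies the last-stimulus indicator, unit 2 is
  # proportional to the left count, unit 3 is constant, unit 4 copies the
  # first-stimulus indicator, unit 5 mixes count and noise
  X <- cbind(as.numeric(seqs[, 4] == 1), n_left * 10, rep(5, 16),
             as.numeric(seqs[, 1] == 1),
             n_left + withr::with_seed(1, rnorm(16)))
  tab <- state_table((X > 0) + 0L, X, seq_len(16), rep(1L, 16), role = "test")
  expect_warning(uc <- unit_correlations(tab, seqs), "constant unit")
  expect_equal(uc$per_unit$rho_last[1], 1)
  expect_equal(uc$per_unit$rho_count[2], 1)
  expect_equal(uc$per_unit$rho_first[4], 1)
  expect_true(is.na(uc$per_unit$rho_count[3]))
  expect_identical(nrow(uc$profile_cor), 3L)
  expect_true(all(is.finite(uc$profile_cor$rho)))
  # closed form for unit 1 against the count regressor
  expect_equal(uc$per_unit$rho_count[1],
               stats::cor(as.numeric(seqs[, 4] == 1), n_left))
})

test_that("cluster distances separate constructed clusters exactly", {
  # two clusters (by left-count) at Hamming distance 4, no within-spread
  seqs <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L), c(2L, 2L))
  states <- rbind(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 1, 0, 0),
                  c(0, 0, 1, 1, 1, 1), c(0, 0, 1, 1, 1, 1))
  tab <- state_table(states, states, 1:4, rep(1L, 4), role = "test")
  cd <- cluster_distances(tab, seqs)
  expect_equal(cd$intra, 0)
  expect_equal(cd$inter, 2)          # sqrt(4)
  # identical states everywhere: intra = inter = 0
  same <- state_table(states[c(1, 1, 1, 1), ], states[c(1, 1, 1, 1), ],
                      1:4, rep(1L, 4), role = "test")
  cd0 <- cluster_distances(same, seqs)
  expect_equal(cd0$intra, 0)
  expect_equal(cd0$inter, 0)
  # random independent states: intra ~ inter
  seqs6 <- enumerate_binary_sequences(6)
  rnd <- random_states(64, 60, seed = 13)
  tabr <- state_table(rnd, rnd, 1:64, rep(1L, 64), role = "test")
  cdr <- cluster_distances(tabr, seqs6)
  expect_lt(abs(cdr$intra - cdr$inter) / cdr$inter, 0.05)
})

test_that("trajectory PCA reports divergence only after sequences differ", {
  fx <- fiducial_point()
  conn <- build_connectivity(fx$wcfg, fx$params, seed = 6)
  b0 <- settle(conn, fx$params, fx$settings)
  pats <- make_patterns(2, 0.59, 1.07, 0, 100, seed = 5)
  sim_seq <- function(ids) {
    ac <- realize_timecourse(ids, pats, 101)
    simulate(b0, conn, ac, t_end = max(ac$offsets) + 1250, params = fx$params,
             settings = fx$settings, record_stride = 20)
  }
  a <- sim_seq(c(1, 2, 1))
  b <- sim_seq(c(2, 2, 1))   # differs at the first stimulus
  pc <- pca_trajectories(a$r[, 1:100], b$r[, 1:100], times = a$times)
  expect_identical(ncol(pc$proj1), 3L)
  expect_identical(nrow(pc$proj1), nrow(a$r))
  # distance is 0 before the first stimulus and positive soon after onset
  expect_equal(pc$distance[pc$times == 0], 0)
  expect_gt(max(pc$distance[pc$times <= 250]), 0)
  expect_gt(pc$distance[length(pc$distance)], 0)
  # identical sequences give identically zero distance
  pc0 <- pca_trajectories(a$r[, 1:100], a$r[, 1:100])
  expect_true(all(pc0$distance == 0))
  # on synthetic rank-3 trajectories the 3-component projection preserves
  # pairwise distances (up to rotation), hence their ranking exactly
  withr::with_seed(17, {
    B <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))
    z1 <- apply(matrix(rnorm(60 * 3), 60, 3), 2, cumsum)
    z2 <- apply(matrix(rnorm(60 * 3), 60, 3), 2, cumsum)
  })
  low1 <- z1 %*% t(B); low2 <- z2 %*% t(B)
  pcl <- pca_trajectories(low1, low2)
  full_d <- sqrt(rowSums((low1 - low2)^2))
  proj_d <- sqrt(rowSums((pcl$proj1 - pcl$proj2)^2))
  expect_equal(proj_d, full_d, tolerance = 1e-8)
})

test_that("no-depression ablation makes the depression equation inert", {
  fx <- fiducial_point(n_E = 12)
  conn <- build_connectivity(fx$wcfg, fx$params, seed = 7)
  pats <- make_patterns(2, 0.5, 1.07, 0, 12, seed = 6)
  seqs <- enumerate_binary_sequences(2)
  exp_ab <- tiny_experiment(conn, pats, seqs, fx$params, fx$settings,
                            n_train = 1, n_test = 1, master_seed = 8,
                            clamp_D = TRUE)
  # rebuild via run_task_point ablation flag: same clamp path
  expect_true(all(exp_ab$baseline$D == 1))
})
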