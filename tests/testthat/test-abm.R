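test_that("event-free dynamics are frozen and reproducible", {
  p <- abm_params(K_A = 400, T_con = 3, s = 0,
                  rho_G1_S = 0, rho_S_G2 = 0, rho_G2_M = 0, rho_M_G1 = 0)
  e1 <- simulate_abm(p, lattice_size = 20, n_initial = 10, seed = 4)
  tot <- rowSums(ens_mean(e1))
  expect_equal(tot, rep(10, 7))
  expect_equal(ens_mean(e1)[1, ], ens_mean(e1)[7, ]) # no phase drift either
  e2 <- simulate_abm(p, lattice_size = 20, n_initial = 10, seed = 4)
  expect_identical(e1$counts, e2$counts)
  # deterministic limit: with a fixed initial configuration and no possible
  # events, every replicate is identical and the ensemble SD is zero
  init <- cbind(1:10, 1:10, rep(1:4, length.out = 10))
  ens <- run_ensemble(p, n_replicates = 3, base_seed = 9,
                      lattice_size = 20, init_cells = init)
  expect_equal(max(ens_sd(ens)), 0)
})

test_that("an uncrowded M-phase cell divides into two G1 cells", {
  p <- abm_params(K_A = 121, T_con = 8, s = 0,
                  rho_G1_S = 0, rho_S_G2 = 0, rho_G2_M = 0, rho_M_G1 = 500)
  e <- simulate_abm(p, lattice_size = 11, record_times = c(0, 0.2), t_end = 0.2,
                    seed = 1, init_cells = matrix(c(6L, 6L, 4L), 1))
  expect_equal(e$counts[1, 1, ], c(N_G1S = 0, N_G2M = 1))
  expect_equal(e$counts[1, 2, ], c(N_G1S = 2, N_G2M = 0))
})

test_that("total count never exceeds min(K_A, lattice capacity)", {
  p_fast <- list(rho_G1_S = 6, rho_S_G2 = 6, rho_G2_M = 6, rho_M_G1 = 6)
  for (seed in 1:12) {
    pk <- do.call(abm_params, c(list(K_A = 30, T_con = 8, s = 20), p_fast))
    e <- simulate_abm(pk, lattice_size = 8, n_initial = 10, seed = seed)
    expect_lte(max(rowSums(ens_mean(e))), 30)
    pl <- do.call(abm_params, c(list(K_A = 64, T_con = 8, s = 20), p_fast))
    e <- simulate_abm(pl, lattice_size = 8, n_initial = 10, seed = seed)
    expect_lte(max(rowSums(ens_mean(e))), 64)
  }
})

test_that("pure-transition ensemble mean follows the linear Markov chain", {
  # no divisions (rho_M_G1 = 0), no arrest (T_con = 8): a linear cascade
  # G1 -> S -> G2 -> M whose expectation has a closed matrix-exponential form
  rates <- c(1.5, 0.8, 1.2, 0)
  p <- abm_params(K_A = 900, T_con = 8, s = 5,
                  rho_G1_S = rates[1], rho_S_G2 = rates[2],
                  rho_G2_M = rates[3], rho_M_G1 = rates[4])
  init <- cbind(rep(1:10, each = 5), rep(seq(1, 28, by = 3), times = 5),
                rep(c(1L, 2L, 3L, 4L), length.out = 50))
  reps <- lapply(1:200, function(s)
    simulate_abm(p, lattice_size = 30, seed = s, init_cells = init,
                 record_times = c(0, 1, 2, 3)))
  counts <- vapply(reps, function(e) e$counts[1, , ], matrix(0, 4, 2))
  Q <- rbind(c(-rates[1], 0, 0, 0),
             c(rates[1], -rates[2], 0, 0),
             c(0, rates[2], -rates[3], 0),
             c(0, 0, rates[3], 0))
  p0 <- as.numeric(table(factor(init[, 3], levels = 1:4)))
  for (ti in 1:4) {
    expect_n <- expm_eig(Q, c(0, 1, 2, 3)[ti]) %*% p0
    for (v in 1:2) {
      obs <- counts[ti, v, ]
      se <- max(sd(obs) / sqrt(length(obs)), 1e-9)
      want <- if (v == 1) sum(expect_n[1:2]) else sum(expect_n[3:4])
      expect_lt(abs(mean(obs) - want), 3 * se + 1e-9)
    }
  }
})

test_that("saturating cultures accumulate cells in G1/S", {
  p <- abm_params(K_A = 1500, T_con = 1, s = 0,
                  rho_G1_S = 4, rho_S_G2 = 4, rho_G2_M = 4, rho_M_G1 = 4)
  ens <- run_ensemble(p, n_replicates = 4, base_seed = 7)
  m <- ens_mean(ens)
  tot <- rowSums(m)
  expect_gte(tot[7], 0.9 * 1500) # reaches the capacity regime by day 3
  frac <- m[, 1] / tot
  expect_gt(frac[7], frac[2]) # day 3 G1/S fraction exceeds day 0.5
})

test_that("capacity and validation errors are raised", {
  expect_error(abm_params(rho_G1_S = -1), "rates")
  expect_error(abm_params(T_con = 9), "T_con")
  expect_error(simulate_abm(abm_params(K_A = 500), lattice_size = 10,
                            n_initial = 200), "capacity")
  expect_error(simulate_abm(abm_params(K_A = 5000), lattice_size = 10),
               "capacity")
})

test_that("grid designs enumerate corners and levels exactly", {
  sp <- parameter_space(c(a = 0, b = 10), c(a = 1, b = 20))
  X <- sample_parameter_space(sp, "grid", levels = 2)
  expect_equal(nrow(X), 4)
  expect_setequal(apply(X, 1, paste, collapse = ","),
                  c("0,10", "1,10", "0,20", "1,20"))
  sp1 <- parameter_space(c(a = 0), c(a = 1))
  X1 <- sample_parameter_space(sp1, "grid", levels = 3)
  expect_equal(sort(X1[, 1]), c(0, 0.5, 1))
  expect_error(parameter_space(c(a = 1), c(a = 0)), "inverted")
})

test_that("LHS designs stratify each margin and append the corners", {
  sp <- unit_space(3)
  X <- sample_parameter_space(sp, "lhs", n_points = 10, seed = 3)
  expect_equal(nrow(X), 10 + 8)
  interior <- X[1:10, ]
  for (j in 1:3) {
    deciles <- floor(interior[, j] * 10)
    expect_setequal(deciles, 0:9) # exactly one point per decile
  }
  corners <- X[11:18, ]
  expect_true(all(corners %in% c(0, 1)))
  expect_true(all(X >= 0 & X <= 1))
})

test_that("mock growth ensembles reduce to the growth law and honour noise", {
  times <- seq(0, 4, by = 0.5)
  tp <- list(r = 1.2, K = 4000, N0 = 200)
  exact <- mock_growth_ensemble("logistic", tp, noise_sd = 0,
                                times = times, n_replicates = 3, seed = 2)
  sol <- solve_growth(growth_params("logistic", tp), 200, times)
  for (r in 1:3) expect_equal(exact$counts[r, , 1], sol$values[, 1])
  atk <- mock_growth_ensemble("logistic", list(r = 2, K = 1000, N0 = 1000),
                              noise_sd = 0.05, times = times,
                              n_replicates = 5, seed = 3)
  expect_true(all(abs(atk$counts / 1000 - 1) < 0.3))
  noisy <- mock_growth_ensemble("logistic", tp, noise_sd = 0.1,
                                times = times, n_replicates = 500, seed = 4)
  expect_true(all(abs(ens_mean(noisy)[, 1] / sol$values[, 1] - 1) < 0.02))
  expect_error(mock_growth_ensemble("gompertz", tp), "arg")
})

test_that("a one-replicate ensemble equals a single simulation", {
  p <- abm_params(K_A = 1500)
  e1 <- run_ensemble(p, n_replicates = 1, base_seed = 5,
                     lattice_size = 40, n_initial = 160)
  e2 <- simulate_abm(p, seed = 5, lattice_size = 40, n_initial = 160)
  expect_identical(e1$counts[1, , ], e2$counts[1, , ])
})
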