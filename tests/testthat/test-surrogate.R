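test_that("cell-cycle surrogate solutions honour fixed points and equilibria", {
  par <- c(lambda_C = 1.3, alpha_C = 0.9, K_C = 2500)
  zero <- solve_cellcycle(par, c(0, 0), seq(0, 5, by = 1))
  expect_equal(max(abs(zero$values)), 0)
  # total converges to K_C: at steady state the two transition fluxes balance
  # and the logistic yield factor forces N1S + N2M = K_C
  eq <- solve_cellcycle(par, c(50, 30), seq(0, 100, by = 5))
  tot <- rowSums(eq$values)
  expect_lt(abs(tot[length(tot)] / 2500 - 1), 1e-3)
})

test_that("cell-cycle dynamics match the linear system when K_C is huge", {
  lam <- 1.1; alp <- 0.7
  par <- c(lambda_C = lam, alpha_C = alp, K_C = 1e9)
  init <- c(120, 80)
  times <- seq(0, 1, by = 0.1)
  sol <- solve_cellcycle(par, init, times)
  A <- rbind(c(-lam, 2 * alp), c(lam, -alp))
  for (ti in seq_along(times)) {
    want <- expm_eig(A, times[ti]) %*% init
    expect_lt(max(abs(sol$values[ti, ] / want - 1)), 0.01)
  }
})

test_that("fixed-step integration agrees with an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  par <- c(lambda_C = 2.4, alpha_C = 1.6, K_C = 1800)
  init <- c(700, 300)
  times <- seq(0, 3, by = 0.5)
  mine <- solve_cellcycle(par, init, times)
  ref <- deSolve::lsoda(
    y = init, times = times,
    func = function(t, y, p) {
      list(c(-p[1] * y[1] + p[2] * (2 - sum(y) / p[3]) * y[2],
             p[1] * y[1] - p[2] * y[2]))
    }, parms = unname(par), rtol = 1e-10, atol = 1e-8)
  expect_lt(max(abs(mine$values - ref[, 2:3])), 1e-4 * max(ref[, 2:3]))

  vb <- growth_params("vonB", list(alpha = 6, beta = 1.2, nu = 3))
  tv <- seq(0, 10, by = 0.5)
  mv <- solve_growth(vb, 10, tv)
  rv <- deSolve::lsoda(y = 10, times = tv,
                       func = function(t, y, p)
                         list(p[1] * max(y, 0)^p[4] - p[2] * y),
                       parms = c(6, 1.2, 3, 1 - 1 / 3),
                       rtol = 1e-10, atol = 1e-8)
  expect_lt(max(abs(mv$values[, 1] - rv[, 2])), 1e-4 * max(rv[, 2]))
})

test_that("growth laws use their closed forms and limits", {
  t <- seq(0, 6, by = 0.5)
  flat <- solve_growth(growth_params("exponential", list(lambda = 0)), 42, t)
  expect_equal(flat$values[, 1], rep(42, length(t)))
  ex <- solve_growth(growth_params("exponential", list(lambda = 0.7)), 10, t)
  expect_lt(max(abs(ex$values[, 1] - 10 * exp(0.7 * t))), 1e-8 * max(ex$values))
  lg <- solve_growth(growth_params("logistic", list(r = 1.1, K = 900)), 30, t)
  want <- 900 / (1 + (900 - 30) / 30 * exp(-1.1 * t))
  expect_lt(max(abs(lg$values[, 1] - want)), 1e-8 * 900)
  atk <- solve_growth(growth_params("logistic", list(r = 2, K = 500)), 500, t)
  expect_equal(atk$values[, 1], rep(500, length(t)))
  # von Bertalanffy equilibrium (alpha/beta)^nu
  vb <- solve_growth(growth_params("vonB", list(alpha = 4, beta = 0.8, nu = 2.5)),
                     50, seq(0, 100, by = 1))
  expect_lt(abs(vb$values[101, 1] / (4 / 0.8)^2.5 - 1), 1e-3)
  expect_error(growth_params("vonB", list(alpha = 1, beta = 1, nu = 0.9)), "nu")
})

test_that("fitting recovers generating parameters from exact data", {
  truth <- c(lambda_C = 1.2, alpha_C = 0.8, K_C = 3000)
  ens <- exact_cellcycle_ensemble(truth)
  fit <- fit_sm("cellcycle", ens, seed = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$par / truth - 1)), 1e-4)
  expect_lt(fit$rss, 1e-8)

  tg <- exact_growth_ensemble("logistic", list(r = 1.5, K = 5000), 100)
  fg <- fit_sm("logistic", tg, seed = 1)
  expect_lt(max(abs(fg$par / c(r = 1.5, K = 5000) - 1)), 1e-4)
})

test_that("a nested model never beats the true one on weighted RSS", {
  mock <- mock_growth_ensemble("logistic", list(r = 1.5, K = 5000, N0 = 100),
                               noise_sd = 0.1, times = seq(0, 5, length.out = 8),
                               n_replicates = 10, seed = 11)
  fl <- fit_sm("logistic", mock, seed = 1)
  fe <- fit_sm("exponential", mock, seed = 1)
  expect_gte(fe$rss, fl$rss)
})

test_that("fits are invariant to replicate order", {
  mock <- mock_growth_ensemble("logistic", list(r = 1.5, K = 5000, N0 = 100),
                               noise_sd = 0.1, times = seq(0, 5, length.out = 8),
                               n_replicates = 6, seed = 12)
  perm <- mock
  perm$counts <- mock$counts[c(4, 2, 6, 1, 5, 3), , , drop = FALSE]
  f1 <- fit_sm("logistic", mock, seed = 1)
  f2 <- fit_sm("logistic", perm, seed = 1)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$rss, f2$rss)
})

test_that("fitted carrying capacity tracks the observed plateau", {
  p <- abm_params(K_A = 2000, T_con = 2, s = 10,
                  rho_G1_S = 3, rho_S_G2 = 3, rho_G2_M = 3, rho_M_G1 = 3)
  ens <- run_ensemble(p, n_replicates = 6, base_seed = 21)
  fit <- fit_sm("cellcycle", ens, seed = 1)
  plateau <- sum(ens_mean(ens)[7, ])
  expect_gte(fit$par[["K_C"]], 0.5 * plateau)
  expect_lte(fit$par[["K_C"]], 2 * plateau)
})

test_that("sm_fit methods expose coefficients, predictions and residuals", {
  ens <- exact_cellcycle_ensemble()
  fit <- fit_sm("cellcycle", ens, seed = 1)
  expect_named(coef(fit), c("lambda_C", "alpha_C", "K_C"))
  pred <- predict(fit)
  expect_s3_class(pred, "sm_trajectory")
  expect_equal(dim(pred$values), c(7, 2))
  expect_lt(max(abs(residuals(fit))), 1e-3)
  expect_output(print(fit), "cellcycle")
  expect_s3_class(summary(fit), "summary.sm_fit")
})
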