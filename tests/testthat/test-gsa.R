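test_that("Morris trajectories perturb one coordinate at a time on the grid", {
  sp <- unit_space(4)
  des <- morris_design(sp, r = 5, levels = 4, seed = 3)
  expect_equal(des$delta, 4 / (2 * 3))
  expect_equal(nrow(des$X), 5 * 5)
  grid_vals <- (0:3) / 3
  expect_true(all(apply(des$U, 1, function(u)
    all(vapply(u, function(v) any(abs(v - grid_vals) < 1e-12), TRUE)))))
  for (t in 1:5) {
    rows <- (t - 1) * 5 + 1:5
    steps <- diff(des$U[rows, ])
    # each consecutive pair differs in exactly one coordinate, by +/- delta
    expect_true(all(rowSums(abs(steps) > 1e-12) == 1))
    expect_true(all(abs(abs(steps[abs(steps) > 1e-12]) - des$delta) < 1e-12))
    # every parameter is perturbed exactly once per trajectory
    expect_setequal(apply(abs(steps) > 1e-12, 1, which), 1:4)
  }
  expect_error(morris_design(sp, r = 2, levels = 3), "even")
  # m = 1: a trajectory is just two points differing by delta
  d1 <- morris_design(unit_space(1), r = 1, levels = 4, seed = 1)
  expect_equal(nrow(d1$X), 2)
  expect_equal(abs(diff(d1$U[, 1])), d1$delta)
})

test_that("elementary effects of a linear metric are exact and degenerate", {
  sp <- unit_space(3)
  f <- function(p) 3 * p[1] + p[2] - 2 * p[3]
  res <- run_gsa("moat", f, sp, options = list(r = 7, levels = 4), seed = 5)
  tab <- res$table
  expect_equal(tab$mu, c(3, 1, -2), tolerance = 1e-12)
  expect_equal(tab$mu_star, c(3, 1, 2), tolerance = 1e-12)
  expect_equal(tab$sigma, c(0, 0, 0), tolerance = 1e-10)
  # constant metric: everything is zero
  rc <- run_gsa("moat", function(p) 4.2, sp, options = list(r = 3), seed = 1)
  expect_true(all(abs(as.matrix(rc$table[, c("mu", "mu_star", "sigma")])) < 1e-12))
})

test_that("mu* of a product metric matches direct enumeration of the design", {
  sp <- unit_space(2)
  des <- morris_design(sp, r = 50, levels = 4, seed = 9)
  y <- apply(des$X, 1, function(p) p[1] * p[2])
  res <- morris_indices(des, y)
  # oracle: EE for x1 is the value of x2 at the step where x1 moves
  ee1 <- vapply(1:50, function(t) {
    rows <- (t - 1) * 3 + 1:3
    j <- which(des$orders[t, ] == 1)
    des$U[rows[j], 2] # x2 is unchanged across x1's step
  }, 0)
  expect_equal(res$table$mu_star[1], mean(abs(ee1)), tolerance = 1e-12)
  expect_equal(res$table$mu[1], mean(ee1 * sign(1)), tolerance = 1e-12)
})

test_that("eFAST search curves stay in bounds and sweep each range", {
  sp <- parameter_space(c(a = -2, b = 10, c = 0), c(a = 2, b = 30, c = 1))
  des <- efast_design(sp, Ns = 65, M = 4, Nr = 2, seed = 4)
  expect_equal(des$omega_max, 8) # floor((65-1)/(2*4))
  expect_equal(nrow(des$X), 3 * 2 * 65)
  expect_true(all(des$X[, "a"] >= -2 & des$X[, "a"] <= 2))
  expect_true(all(des$X[, "b"] >= 10 & des$X[, "b"] <= 30))
  # the parameter of interest covers its range within 2%
  for (i in 1:3) {
    rows <- (i - 1) * 2 * 65 + 1:65
    v <- des$X[rows, i]
    rng <- c(sp$lower[i], sp$upper[i])
    expect_lt((min(v) - rng[1]) / diff(rng), 0.02)
    expect_lt((rng[2] - max(v)) / diff(rng), 0.02)
  }
  # distinct parameters of interest get distinct designs
  expect_false(isTRUE(all.equal(des$X[1:65, ], des$X[131:195, ])))
  expect_error(efast_design(sp, Ns = 7, M = 4), "Ns too small")
  expect_error(efast_design(unit_space(1), Ns = 65), "m >= 2")
})

test_that("eFAST attributes all variance of a single active input to it", {
  sp <- unit_space(3)
  res <- run_gsa("efast", function(p) p[1],
                 sp, options = list(Ns = 65, M = 4, Nr = 4), seed = 2)
  expect_gt(res$table$S_i[1], 0.95)
  expect_lt(res$table$S_Ti[2], 0.05)
  expect_lt(res$table$S_Ti[3], 0.05)
  # S_i <= S_Ti (+ small estimator slack)
  expect_true(all(res$table$S_i <= res$table$S_Ti + 0.02))
  # constant output: zero indices with a warning
  expect_warning(
    rz <- run_gsa("efast", function(p) 1, sp,
                  options = list(Ns = 65, M = 4, Nr = 2), seed = 2),
    "zero")
  expect_true(all(rz$table$S_i == 0) && all(rz$table$S_Ti == 0))
})

test_that("additive metrics keep the main-effect budget below one", {
  sp <- unit_space(3)
  res <- run_gsa("efast", function(p) p[1] + 2 * p[2] + 0.5 * p[3],
                 sp, options = list(Ns = 65, M = 4, Nr = 16), seed = 6)
  expect_lte(sum(res$table$S_i), 1.05)
  expect_true(all(res$table$S_i <= res$table$S_Ti + 0.02))
})

test_that("surrogate-transfer metrics average the box and stay deterministic", {
  # degenerate field (lo = hi): no Monte Carlo variance at all
  pts <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "a"))
  sb <- sampled_bounds(pts, cbind(r = c(1, 2), K = c(1000, 2000)),
                       cbind(r = c(1, 2), K = c(1000, 2000)))
  field <- build_field(sb, "grid")
  times <- seq(0, 3, by = 0.5)
  f <- surrogate_metric(field, list(model = "logistic", init = 100,
                                    times = times), "final",
                        n_mc = 7, seed = 1)
  got <- f(c(a = 0.5))
  sol <- solve_growth(growth_params("logistic", list(r = 1.5, K = 1500)),
                      100, times)
  expect_equal(got, unname(sol$values[7, 1]), tolerance = 1e-12)
  expect_identical(f(c(a = 0.5)), got) # per-point seeding is stable
  expect_equal(evaluation_count(f), 2L)
  # a constant metric integrates to itself whatever the field
  fc <- surrogate_metric(field, list(model = "logistic", init = 100,
                                     times = times),
                         function(tr) 13.5, n_mc = 5, seed = 1)
  expect_equal(fc(c(a = 0.2)), 13.5)
})

test_that("the box-mean estimator converges to tensor-grid quadrature", {
  pts <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "a"))
  low <- cbind(lambda_C = c(0.8, 0.8), alpha_C = c(0.5, 0.5), K_C = c(2000, 2000))
  up <- cbind(lambda_C = c(1.6, 1.6), alpha_C = c(1.5, 1.5), K_C = c(4000, 4000))
  field <- build_field(sampled_bounds(pts, low, up), "grid")
  times <- seq(0, 3, by = 0.5)
  metric <- metric_fn("final")
  # deterministic midpoint quadrature over the 3D box as the oracle
  gr <- lapply(1:3, function(j) {
    lo <- low[1, j]; hi <- up[1, j]
    lo + (hi - lo) * (seq_len(12) - 0.5) / 12
  })
  quad <- mean(apply(as.matrix(expand.grid(gr)), 1, function(ps) {
    sol <- solve_cellcycle(setNames(ps, colnames(low)), c(600, 400), times)
    metric(trajectory(times, rowSums(sol$values)))
  }))
  n_mc <- 4000
  f <- surrogate_metric(field, list(model = "cellcycle", init = c(600, 400),
                                    times = times), "final",
                        n_mc = n_mc, seed = 3)
  est <- f(c(a = 0.4))
  # spread of the metric over the box, for a 3-SE band
  spread <- sd(apply(sample_hyperrectangle(query(field, c(a = 0.4)), 500, 8), 1,
                     function(ps) {
                       sol <- solve_cellcycle(setNames(ps, colnames(low)),
                                              c(600, 400), times)
                       metric(trajectory(times, rowSums(sol$values)))
                     }))
  expect_lt(abs(est - quad), 3 * spread / sqrt(n_mc) + 0.01 * abs(quad))
})

test_that("direct ABM metrics are seeded, cached and ledgered", {
  f <- abm_metric(abm_params(), "final", n_replicates = 2, seed = 5,
                  sim_options = list(lattice_size = 30, n_initial = 90))
  p <- c(K_A = 600, T_con = 2.4, s = 5,
         rho_G1_S = 2, rho_S_G2 = 2, rho_G2_M = 2, rho_M_G1 = 2)
  v1 <- f(p)
  expect_equal(evaluation_count(f), 1L)
  v2 <- f(p)
  expect_identical(v1, v2)
  expect_equal(evaluation_count(f), 2L)
  # deterministic limit: all-zero rates leave the seeded count unchanged
  fz <- abm_metric(abm_params(), "final", n_replicates = 2, seed = 5,
                   sim_options = list(lattice_size = 30, n_initial = 90))
  pz <- c(K_A = 600, T_con = 3, s = 0,
          rho_G1_S = 0, rho_S_G2 = 0, rho_G2_M = 0, rho_M_G1 = 0)
  expect_equal(fz(pz), 90)
})

test_that("identical seeds reproduce entire GSA runs bit for bit", {
  sp <- unit_space(3)
  f <- function(p) p[1]^2 + p[2] * p[3]
  r1 <- run_gsa("moat", f, sp, options = list(r = 10), seed = 11)
  r2 <- run_gsa("moat", f, sp, options = list(r = 10), seed = 11)
  expect_identical(r1$table, r2$table)
  e1 <- run_gsa("efast", f, sp, options = list(Ns = 65, Nr = 2), seed = 11)
  e2 <- run_gsa("efast", f, sp, options = list(Ns = 65, Nr = 2), seed = 11)
  expect_identical(e1$table, e2$table)
})

test_that("surrogate and direct screening coincide when the surrogate is exact", {
  # mock system whose "ABM parameters" are the logistic parameters themselves;
  # the field pins each box to the true point, so the transfer is exact
  sp <- parameter_space(c(r = 0.8, K = 2000), c(r = 2, K = 6000))
  pts <- sample_parameter_space(sp, "grid", levels = 3)
  sb <- sampled_bounds(pts, cbind(r = pts[, "r"], K = pts[, "K"]),
                       cbind(r = pts[, "r"], K = pts[, "K"]))
  field <- build_field(sb, "grid")
  times <- seq(0, 3, by = 0.5)
  f_sur <- surrogate_metric(field, list(model = "logistic", init = 100,
                                        times = times), "final",
                            n_mc = 1, seed = 2)
  f_dir <- function(p) {
    sol <- solve_growth(growth_params("logistic", as.list(p)), 100, times)
    final_value(trajectory(times, sol$values[, 1]))
  }
  rs <- run_gsa("moat", f_sur, sp, options = list(r = 8), seed = 3)
  rd <- run_gsa("moat", f_dir, sp, options = list(r = 8), seed = 3)
  expect_equal(rs$table$mu_star, rd$table$mu_star, tolerance = 1e-10)
  expect_identical(order(-rs$table$mu_star), order(-rd$table$mu_star))
})
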