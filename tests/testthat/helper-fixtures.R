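# shared fixtures: small parameter spaces and ensembles built in code

abm_space_7d <- function() {
  parameter_space(
    lower = c(K_A = 1000, T_con = 1, s = 0,
              rho_G1_S = 0.5, rho_S_G2 = 0.5, rho_G2_M = 0.5, rho_M_G1 = 0.5),
    upper = c(K_A = 8000, T_con = 7, s = 50,
              rho_G1_S = 4, rho_S_G2 = 4, rho_G2_M = 4, rho_M_G1 = 4))
}

unit_space <- function(m, prefix = "x") {
  parameter_space(setNames(rep(0, m), paste0(prefix, seq_len(m))),
                  setNames(rep(1, m), paste0(prefix, seq_len(m))))
}

# deterministic two-replicate ensemble holding exact surrogate solutions,
# so the SD floor carries the weights and the fit is self-consistent
exact_cellcycle_ensemble <- function(par = c(lambda_C = 1.2, alpha_C = 0.8, K_C = 3000),
                                     init = c(600, 400),
                                     times = seq(0, 3, by = 0.5)) {
  sol <- solve_cellcycle(par, init, times)
  counts <- array(0, dim = c(2, length(times), 2))
  counts[1, , ] <- sol$values
  counts[2, , ] <- sol$values
  ensemble_ts(times, counts, c("N_G1S", "N_G2M"))
}

exact_growth_ensemble <- function(model, par, N0, times = seq(0, 5, length.out = 8)) {
  sol <- solve_growth(growth_params(model, par), N0, times)
  counts <- array(0, dim = c(2, length(times), 1))
  counts[1, , 1] <- sol$values[, 1]
  counts[2, , 1] <- sol$values[, 1]
  ensemble_ts(times, counts, "N")
}

# matrix exponential via eigendecomposition (oracle for linear compartment
# systems; avoids depending on the solver under test)
expm_eig <- function(A, t) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values * t), nrow(A)) %*% solve(e$vectors))
}

# fit-like list for a 1-parameter linear-Gaussian model y = a x + eps,
# known unit sigma, normalized weighted-RSS objective
linear_gaussian_fit <- function(x, y, bounds = c(0.01, 100)) {
  n <- length(y)
  obj <- function(par) sum((y - par[["a"]] * x)^2) / n
  ahat <- sum(x * y) / sum(x^2)
  b <- matrix(bounds, 2, 1)
  colnames(b) <- "a"
  list(par = c(a = ahat), rss = obj(c(a = ahat)), n_obs = n,
       bounds = b, objective = obj)
}
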