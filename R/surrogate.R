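#' Surrogate-model trajectory container
#'
#' @param times numeric times (days), strictly increasing.
#' @param values matrix (times x variables) of model states.
#' @param variables character variable names.
#' @return Object of class `sm_trajectory`.
#' @export
sm_trajectory <- function(times, values, variables) {
  values <- as.matrix(values)
  colnames(values) <- variables
  structure(list(times = as.numeric(times), values = values, variables = variables),
            class = "sm_trajectory")
}

#' @export
print.sm_trajectory <- function(x, ...) {
  cat(sprintf("<sm_trajectory> %d times, variables: %s\n",
              length(x$times), paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' Growth-law parameter container
#'
#' Normalizes a parameter list for one of the three single-variable growth
#' surrogates: exponential (`lambda`), logistic (`r`, `K`) or von Bertalanffy
#' (`alpha`, `beta`, `nu` with `nu > 1`; the exponent `theta = 1 - 1/nu` is
#' derived).
#'
#' @param model `"exponential"`, `"logistic"` or `"vonB"`.
#' @param params named list (or vector) with the fields of the active model.
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(model = c("exponential", "logistic", "vonB"), params) {
  model <- match.arg(model)
  p <- as.list(params)
  out <- switch(model,
    exponential = {
      if (is.null(p$lambda)) stop("exponential model needs lambda")
      list(lambda = p$lambda)
    },
    logistic = {
      if (is.null(p$r) || is.null(p$K)) stop("logistic model needs r and K")
      if (p$K <= 0) stop("K must be > 0")
      list(r = p$r, K = p$K)
    },
    vonB = {
      if (is.null(p$alpha) || is.null(p$beta) || is.null(p$nu))
        stop("vonB model needs alpha, beta, nu")
      if (p$nu <= 1) stop("vonB exponent nu must be > 1")
      list(alpha = p$alpha, beta = p$beta, nu = p$nu, theta = 1 - 1 / p$nu)
    })
  structure(c(out, list(model = model)), class = "growth_params")
}

#' Solve the two-compartment cell-cycle surrogate
#'
#' Integrates the G1/S -- G2/M pool model
#' \deqn{dN_{1S}/dt = -\lambda_C N_{1S} + \alpha_C (2 - (N_{1S}+N_{2M})/K_C) N_{2M}}
#' \deqn{dN_{2M}/dt = \lambda_C N_{1S} - \alpha_C N_{2M}}
#' with a fixed-step classical Runge-Kutta scheme (`dt` days per step;
#' local error O(dt^5), so the default `dt = 0.01` resolves rates up to
#' ~100/day to well below the fitting weights). The total `N1S + N2M`
#' equilibrates at `K_C` for positive parameters.
#'
#' @param params named list/vector with `lambda_C`, `alpha_C`, `K_C` (all > 0).
#' @param init length-2 nonnegative initial condition `(N1S0, N2M0)`.
#' @param times output times, strictly increasing.
#' @param dt integration step (days).
#' @return An [sm_trajectory()] with variables `N_G1S`, `N_G2M`.
#' @export
solve_cellcycle <- function(params, init, times, dt = 0.01) {
  p <- as.list(params)
  if (any(unlist(p[c("lambda_C", "alpha_C", "K_C")]) <= 0))
    stop("cell-cycle surrogate parameters must be > 0")
  if (any(init < 0)) stop("initial condition must be nonnegative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sol <- cpp_solve_cellcycle(p$lambda_C, p$alpha_C, p$K_C,
                             init[1], init[2], as.numeric(times), dt)
  if (any(!is.finite(sol))) stop("integration error: non-finite cell-cycle solution")
  sm_trajectory(times, sol, c("N_G1S", "N_G2M"))
}

#' Solve a single-variable growth surrogate
#'
#' Exponential and logistic laws use their closed forms; von Bertalanffy
#' growth `dN/dt = alpha N^theta - beta N` is integrated with fixed-step RK4.
#'
#' @param params a [growth_params()] object (or a list accepted by it plus a
#'   `model` entry).
#' @param N0 nonnegative initial size.
#' @param times output times.
#' @param dt RK4 step for the von Bertalanffy law (days).
#' @return An [sm_trajectory()] with the single variable `N`.
#' @export
solve_growth <- function(params, N0, times, dt = 0.01) {
  if (!inherits(params, "growth_params"))
    params <- growth_params(params$model, params)
  if (N0 < 0) stop("N0 must be >= 0")
  times <- as.numeric(times)
  vals <- switch(params$model,
    exponential = N0 * exp(params$lambda * (times - times[1])),
    logistic = {
      if (N0 == 0) rep(0, length(times))
      else params$K / (1 + ((params$K - N0) / N0) * exp(-params$r * (times - times[1])))
    },
    vonB = as.numeric(cpp_solve_vonb(params$alpha, params$beta, params$nu,
                                     N0, times, dt)))
  if (any(!is.finite(vals))) stop("integration error: non-finite growth solution")
  sm_trajectory(times, matrix(vals, ncol = 1), "N")
}

# ---- model registry ---------------------------------------------------------

sm_model_info <- function(model) {
  switch(model,
    cellcycle = list(par = c("lambda_C", "alpha_C", "K_C"), k = 3L,
                     vars = c("N_G1S", "N_G2M"),
                     lower = c(1e-3, 1e-3, 1), upper = c(100, 100, 1e6)),
    exponential = list(par = "lambda", k = 1L, vars = "N",
                       lower = 1e-3, upper = 100),
    logistic = list(par = c("r", "K"), k = 2L, vars = "N",
                    lower = c(1e-3, 1), upper = c(100, 1e6)),
    vonB = list(par = c("alpha", "beta", "nu"), k = 3L, vars = "N",
                lower = c(1e-6, 1e-3, 1.001), upper = c(1e6, 100, 20)),
    stop("unknown surrogate model: ", model))
}

# solve any registered model at a named parameter vector; returns matrix
solve_sm_matrix <- function(model, par, init, times, dt = 0.01) {
  if (model == "cellcycle") {
    cpp_solve_cellcycle(par[["lambda_C"]], par[["alpha_C"]], par[["K_C"]],
                        init[1], init[2], as.numeric(times), dt)
  } else {
    gp <- growth_params(model, as.list(par))
    tr <- tryCatch(solve_growth(gp, init[1], times, dt),
                   error = function(e) NULL)
    if (is.null(tr)) matrix(NaN, length(times), 1) else tr$values
  }
}

#' Fit a surrogate model to ensemble output by weighted least squares
#'
#' Minimizes the normalized weighted residual sum of squares
#' \deqn{RSS = (1/n_{obs}) \sum_{t,v} [(SM(t,v) - mean(t,v)) / SD(t,v)]^2}
#' where the weights are per-point ensemble standard deviations floored at
#' `max(1% of the final-time mean total, 1 cell)` to avoid division by zero.
#' A well-specified model therefore yields RSS near 1. The surrogate initial
#' condition is fixed to the ensemble mean at the first recording time (not
#' fitted). Optimization is a derivative-free Nelder-Mead search on
#' log-transformed parameters, restarted from `n_starts` Latin-hypercube
#' points inside the (log) parameter bounds; ties are broken by lowest RSS
#' then lexicographically smallest parameter vector.
#'
#' @param model `"cellcycle"`, `"exponential"`, `"logistic"` or `"vonB"`.
#' @param data an [ensemble_ts()]; needs >= 2 replicates for SD weights
#'   (a single replicate is allowed, with the SD floor carrying all weight)
#'   and more time points than free parameters.
#' @param n_starts number of multistart points.
#' @param seed RNG seed for the multistart design.
#' @param bounds optional 2 x k matrix (rows lower/upper, columns named by
#'   parameter) overriding the default search bounds.
#' @param dt ODE integration step.
#'
#' @return An object of class `sm_fit` with components `par`, `rss`
#'   (normalized), `rss_unnorm`, `n_obs`, `k`, `converged`, an `objective`
#'   closure over full parameter vectors (used by the profiling machinery),
#'   and the weighted data it was fitted to. Methods: `print`, `coef`,
#'   `summary`, `predict`, `plot`, `residuals`.
#' @export
fit_sm <- function(model, data, n_starts = 10, seed = 1, bounds = NULL, dt = 0.01) {
  info <- sm_model_info(model)
  stopifnot(inherits(data, "ensemble_ts"))
  if (!all(info$vars %in% data$variables))
    stop(sprintf("model '%s' needs ensemble variables: %s", model,
                 paste(info$vars, collapse = ", ")))
  if (length(data$times) < info$k + 1)
    stop("need more time points than free parameters")

  vidx <- match(info$vars, data$variables)
  obs <- ens_mean(data)[, vidx, drop = FALSE]
  sdm <- ens_sd(data)[, vidx, drop = FALSE]
  sdm[is.na(sdm)] <- 0
  plateau <- sum(obs[nrow(obs), ])
  floor_sd <- max(0.01 * plateau, 1)
  sdm <- pmax(sdm, floor_sd)
  init <- obs[1, ]
  times <- data$times
  n_obs <- length(times) * length(info$vars)

  if (is.null(bounds)) {
    bounds <- rbind(info$lower, info$upper)
    colnames(bounds) <- info$par
  }
  lb <- bounds[1, info$par]; ub <- bounds[2, info$par]

  objective <- if (model == "cellcycle") {
    function(par) cpp_rss_cellcycle(par[[1]], par[[2]], par[[3]],
                                    init[1], init[2], times, dt, obs, sdm)
  } else {
    function(par) {
      pred <- solve_sm_matrix(model, setNames(as.numeric(par), info$par),
                              init, times, dt)
      v <- sum(((pred - obs) / sdm)^2) / n_obs
      if (!is.finite(v)) 1e300 else v
    }
  }

  opt <- multistart_optimize(objective, lb, ub, n_starts, seed)
  structure(list(model = model, par = setNames(opt$par, info$par),
                 rss = opt$value, rss_unnorm = opt$value * n_obs,
                 n_obs = n_obs, k = info$k, converged = opt$converged,
                 init = init, times = times, obs_mean = obs, obs_sd = sdm,
                 bounds = bounds, dt = dt, objective = objective,
                 variables = info$vars),
            class = "sm_fit")
}

# derivative-free bounded multistart: Nelder-Mead in log space with an
# out-of-bounds penalty (1-D models use golden-section search instead)
multistart_optimize <- function(objective, lb, ub, n_starts, seed,
                                start = NULL) {
  k <- length(lb)
  llb <- log(lb); lub <- log(ub)
  objz <- function(z) {
    p <- pmin(pmax(exp(z), lb), ub)
    pen <- sum(pmax(z - lub, 0)^2 + pmax(llb - z, 0)^2)
    objective(p) + 100 * pen
  }
  if (n_starts > 0) {
    set.seed(as.integer(seed))
    U <- lhs::randomLHS(n_starts, k)
    Z <- sweep(sweep(U, 2, lub - llb, "*"), 2, llb, "+")
  } else {
    Z <- matrix(numeric(0), 0, k)
  }
  if (!is.null(start)) Z <- rbind(pmin(pmax(log(start), llb), lub), Z)
  if (nrow(Z) == 0) stop("no optimization starts")
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(Z))) {
    res <- if (k == 1) {
      o <- optimize(objz, c(llb, lub), tol = 1e-10)
      # polish around the 1-D optimum found from this start's neighbourhood
      list(par = o$minimum, value = o$objective, convergence = 0)
    } else {
      tryCatch(optim(Z[i, ], objz, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-12)),
               error = function(e) NULL)
    }
    if (is.null(res) || !is.finite(res$value)) next
    p <- pmin(pmax(exp(res$par), lb), ub)
    v <- objective(p)
    if (res$convergence == 0) conv <- TRUE
    if (is.null(best) || v < best$value - 1e-12 ||
        (abs(v - best$value) <= 1e-12 && lex_less(p, best$par))) {
      best <- list(par = p, value = v)
    }
    if (k == 1) break # golden-section on the full interval is start-independent
  }
  if (is.null(best)) stop("all optimization starts failed")
  c(best, list(converged = conv))
}

lex_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 0)[1]
  !is.na(i) && d[i] < 0
}

# ---- sm_fit methods ---------------------------------------------------------

#' @export
print.sm_fit <- function(x, ...) {
  cat(sprintf("<sm_fit> %s surrogate, weighted RSS = %.4g (n_obs = %d, k = %d)%s\n",
              x$model, x$rss, x$n_obs, x$k,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(signif(x$par, 6))
  invisible(x)
}

#' @export
coef.sm_fit <- function(object, ...) object$par

#' @export
summary.sm_fit <- function(object, ...) {
  structure(list(fit = object,
                 aic = aic(object$rss_unnorm, object$n_obs, object$k)),
            class = "summary.sm_fit")
}

#' @export
print.summary.sm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("AIC = %.4g\n", x$aic))
  invisible(x)
}

#' @export
predict.sm_fit <- function(object, times = object$times, ...) {
  sol <- solve_sm_matrix(object$model, object$par, object$init, times, object$dt)
  sm_trajectory(times, sol, object$variables)
}

#' @export
residuals.sm_fit <- function(object, ...) {
  pred <- predict(object)$values
  (pred - object$obs_mean) / object$obs_sd
}

#' @export
plot.sm_fit <- function(x, ...) {
  pred <- predict(x, times = seq(min(x$times), max(x$times), length.out = 100))
  matplot(x$times, x$obs_mean, pch = 16, col = seq_along(x$variables),
          xlab = "time (days)", ylab = "count", ...)
  matlines(pred$times, pred$values, lty = 1, col = seq_along(x$variables))
  legend("topleft", legend = x$variables, col = seq_along(x$variables),
         pch = 16, lty = 1, bty = "n")
  invisible(x)
}
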