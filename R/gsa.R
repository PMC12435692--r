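#' ABM parameter space for global sensitivity analysis
#'
#' A box in parameter space with (for now) the uniform sampling
#' distribution.
#'
#' @param lower,upper named finite numeric vectors of bounds.
#' @param names optional parameter names (default from `lower`).
#' @return Object of class `parameter_space`.
#' @export
parameter_space <- function(lower, upper, names = NULL) {
  if (is.null(names)) names <- base::names(lower)
  if (is.null(names)) names <- paste0("x", seq_along(lower))
  if (length(lower) != length(upper)) stop("bounds length mismatch")
  if (any(!is.finite(lower)) || any(!is.finite(upper))) stop("bounds must be finite")
  if (any(lower >= upper)) stop("empty or inverted bounds")
  structure(list(names = names, lower = setNames(as.numeric(lower), names),
                 upper = setNames(as.numeric(upper), names),
                 m = length(lower), distribution = "uniform"),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("<parameter_space> %d parameters (uniform)\n", x$m))
  print(rbind(lower = x$lower, upper = x$upper))
  invisible(x)
}

scale_to_native <- function(U, space) {
  X <- sweep(sweep(U, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  colnames(X) <- space$names
  X
}

#' Morris one-at-a-time (MOAT) screening design
#'
#' Standard Morris trajectories on a `levels`-level grid of the unit
#' hypercube with step `Delta = levels / (2 (levels - 1))`, mapped to native
#' bounds. Each of the `r` trajectories starts from a random grid point and
#' perturbs every parameter exactly once, in random order and with random
#' sign, giving `r * (m + 1)` design points.
#'
#' @param space a [parameter_space()].
#' @param r number of trajectories.
#' @param levels number of grid levels (even).
#' @param seed RNG seed.
#' @return Object of class `morris_design` containing the native-unit design
#'   matrix `X` (`r*(m+1)` rows) and perturbation bookkeeping.
#' @export
morris_design <- function(space, r = 30, levels = 4, seed = 1) {
  stopifnot(inherits(space, "parameter_space"))
  if (levels %% 2 != 0) stop("levels must be even")
  if (r < 1) stop("r must be >= 1")
  m <- space$m
  delta <- levels / (2 * (levels - 1))
  grid_vals <- (0:(levels - 1)) / (levels - 1)
  low_half <- grid_vals[grid_vals + delta <= 1 + 1e-12]
  set.seed(as.integer(seed))
  U <- matrix(0, r * (m + 1), m)
  orders <- matrix(0L, r, m)
  signs <- matrix(0L, r, m)
  for (t in seq_len(r)) {
    d <- sample(c(-1L, 1L), m, replace = TRUE)
    base <- vapply(d, function(di) {
      v <- sample(low_half, 1)
      if (di == 1L) v else 1 - v
    }, 0)
    ord <- sample.int(m)
    rows <- (t - 1L) * (m + 1L) + 1L
    x <- base
    U[rows, ] <- x
    for (j in seq_len(m)) {
      i <- ord[j]
      x[i] <- x[i] + d[i] * delta
      U[rows + j, ] <- x
    }
    orders[t, ] <- ord
    signs[t, ] <- d
  }
  structure(list(X = scale_to_native(U, space), U = U, r = r, levels = levels,
                 delta = delta, orders = orders, signs = signs, space = space),
            class = "morris_design")
}

#' Elementary-effect summaries from a Morris design
#'
#' Elementary effects are computed in normalized parameter units
#' (`EE = (f(x + Delta e_i) - f(x)) / (sign * Delta)`), so an effect is the
#' metric change caused by traversing the parameter's full range and is in
#' the units of the metric. Per parameter, `mu` is the mean effect,
#' `mu_star` the mean absolute effect and `sigma` the standard deviation
#' over trajectories.
#'
#' @param design a [morris_design()].
#' @param y metric values aligned with `design$X` rows (no missing values).
#' @return Object of class `moat_result`: data.frame-like with columns
#'   `parameter`, `mu`, `mu_star`, `sigma`, plus the raw elementary-effect
#'   matrix.
#' @export
morris_indices <- function(design, y) {
  stopifnot(inherits(design, "morris_design"))
  r <- design$r; m <- design$space$m
  if (length(y) != r * (m + 1)) stop("y misaligned with design")
  if (any(!is.finite(y))) stop("y contains non-finite values")
  EE <- matrix(NA_real_, r, m)
  for (t in seq_len(r)) {
    rows <- (t - 1L) * (m + 1L) + 1L
    for (j in seq_len(m)) {
      i <- design$orders[t, j]
      EE[t, i] <- (y[rows + j] - y[rows + j - 1]) /
        (design$signs[t, i] * design$delta)
    }
  }
  colnames(EE) <- design$space$names
  tab <- data.frame(parameter = design$space$names,
                    mu = colMeans(EE),
                    mu_star = colMeans(abs(EE)),
                    sigma = apply(EE, 2, sd),
                    row.names = NULL)
  structure(list(table = tab, ee = EE, r = r), class = "moat_result")
}

#' @export
print.moat_result <- function(x, ...) {
  cat(sprintf("<moat_result> r = %d trajectories\n", x$r))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
plot.moat_result <- function(x, ...) {
  ord <- order(-x$table$mu_star)
  barplot(x$table$mu_star[ord], names.arg = x$table$parameter[ord],
          ylab = "mu*", las = 2, ...)
  invisible(x)
}

#' eFAST search-curve design
#'
#' For each parameter in turn as the parameter of interest, drives it along
#' a sinusoidal search curve at the maximal frequency
#' `omega_max = floor((Ns - 1) / (2 M))` (so that all `M` harmonics stay
#' below the Nyquist limit of the `Ns`-point curve) while complementary
#' parameters oscillate at low frequencies
#' (`1..max(1, floor(omega_max / (2 M)))`, cycled). Each of the `Nr`
#' resampling repeats uses independent random phase shifts. Points are
#' mapped to the unit cell via `x = 0.5 + (1/pi) * asin(sin(omega s + phi))`
#' and then to native bounds.
#'
#' @param space a [parameter_space()] with `m >= 2`.
#' @param Ns points per search curve (needs `omega_max >= 1`).
#' @param M number of harmonics.
#' @param Nr number of resampling repeats.
#' @param seed RNG seed.
#' @return Object of class `efast_design` with design matrix `X`
#'   (`m * Nr * Ns` rows, blocks ordered by parameter of interest then
#'   resampling) and the frequency table.
#' @export
efast_design <- function(space, Ns = 65, M = 4, Nr = 4, seed = 1) {
  stopifnot(inherits(space, "parameter_space"))
  m <- space$m
  if (m < 2) stop("eFAST needs m >= 2 parameters")
  omega_max <- floor((Ns - 1) / (2 * M))
  if (omega_max < 1) stop("Ns too small for M harmonics (need Ns >= 2*M + 1)")
  omega_c_max <- max(1, floor(omega_max / (2 * M)))
  s <- -pi + 2 * pi * (seq_len(Ns) - 0.5) / Ns
  set.seed(as.integer(seed))
  X <- matrix(0, m * Nr * Ns, m)
  meta <- data.frame(poi = integer(0), resample = integer(0))
  row0 <- 0L
  freq <- matrix(0L, m, m) # freq[i, ] = frequencies when i is the poi
  for (i in seq_len(m)) {
    om <- integer(m)
    om[i] <- omega_max
    om[-i] <- rep_len(seq_len(omega_c_max), m - 1)
    freq[i, ] <- om
    for (rr in seq_len(Nr)) {
      phi <- runif(m, 0, 2 * pi)
      U <- vapply(seq_len(m), function(j)
        0.5 + asin(sin(om[j] * s + phi[j])) / pi, numeric(Ns))
      X[row0 + seq_len(Ns), ] <- scale_to_native(U, space)
      meta <- rbind(meta, data.frame(poi = i, resample = rr))
      row0 <- row0 + Ns
    }
  }
  colnames(X) <- space$names
  structure(list(X = X, Ns = Ns, M = M, Nr = Nr, omega_max = omega_max,
                 omega_c_max = omega_c_max, s = s, freq = freq,
                 blocks = meta, space = space),
            class = "efast_design")
}

#' eFAST main- and total-effect indices
#'
#' Per search curve, Fourier amplitudes are estimated at the parameter of
#' interest's frequency and its `M` harmonics (main-effect variance `V_i`)
#' and over the low-frequency complement (`k <= omega_max / 2`, variance
#' `V_ci`); the indices are `S_i = V_i / V` and `S_Ti = 1 - V_ci / V`,
#' averaged over the `Nr` resampling repeats. A zero-variance output yields
#' all-zero indices with a warning.
#'
#' @param design an [efast_design()].
#' @param y metric values aligned with `design$X` rows.
#' @return Object of class `efast_result` with per-parameter `S_i`, `S_Ti`.
#' @export
efast_indices <- function(design, y) {
  stopifnot(inherits(design, "efast_design"))
  Ns <- design$Ns; M <- design$M; Nr <- design$Nr; m <- design$space$m
  if (length(y) != nrow(design$X)) stop("y misaligned with design")
  if (any(!is.finite(y))) stop("y contains non-finite values")
  omx <- design$omega_max
  K <- floor((Ns - 1) / 2)
  s <- design$s
  cosb <- vapply(seq_len(K), function(k) cos(k * s), numeric(Ns))
  sinb <- vapply(seq_len(K), function(k) sin(k * s), numeric(Ns))
  # pooled-ratio estimator: spectra are summed over the Nr resampling
  # repeats before forming the ratios, which suppresses the upward bias a
  # fluctuating per-curve variance denominator would otherwise induce
  Vi_s <- Vc_s <- V_s <- matrix(0, Nr, m)
  row0 <- 0L
  for (i in seq_len(m)) {
    for (rr in seq_len(Nr)) {
      yb <- y[row0 + seq_len(Ns)]
      row0 <- row0 + Ns
      A <- crossprod(cosb, yb) * 2 / Ns
      B <- crossprod(sinb, yb) * 2 / Ns
      lambda <- (A^2 + B^2) / 2
      V_s[rr, i] <- sum(lambda)
      Vi_s[rr, i] <- sum(lambda[seq_len(M) * omx])
      Vc_s[rr, i] <- sum(lambda[seq_len(max(1, floor(omx / 2)))])
    }
  }
  V_tot <- colSums(V_s)
  zero <- V_tot < 1e-12 * max(1, mean(y)^2)
  if (any(zero)) warning("zero output variance on some search curves; indices set to 0")
  Si <- ifelse(zero, 0, colSums(Vi_s) / pmax(V_tot, 1e-300))
  STi <- ifelse(zero, 0, 1 - colSums(Vc_s) / pmax(V_tot, 1e-300))
  tab <- data.frame(parameter = design$space$names,
                    S_i = pmax(Si, 0),
                    S_Ti = pmax(STi, 0),
                    row.names = NULL)
  structure(list(table = tab, Ns = Ns, M = M, Nr = Nr,
                 omega_max = omx, freq = design$freq),
            class = "efast_result")
}

#' @export
print.efast_result <- function(x, ...) {
  cat(sprintf("<efast_result> Ns = %d, M = %d, Nr = %d, omega_max = %d\n",
              x$Ns, x$M, x$Nr, x$omega_max))
  print(x$table, digits = 4)
  invisible(x)
}

# deterministic per-point seed derived from (seed, p); stays below 2^31
stable_seed <- function(seed, p) {
  ch <- utf8ToInt(paste(sprintf("%.10g", as.numeric(p)), collapse = ","))
  h <- sum(ch * seq_along(ch))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

new_ledger <- function() {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  env
}

#' Number of metric evaluations performed by a metric function
#'
#' @param f a [surrogate_metric()] or [abm_metric()] closure.
#' @return Integer evaluation count.
#' @export
evaluation_count <- function(f) attr(f, "ledger")$count

#' Surrogate-transfer metric over ABM parameter space
#'
#' Implements the core estimator of the framework: the metric at an ABM
#' parameter vector is approximated by the mean of the surrogate-side metric
#' over `n_mc` uniform samples of the hyperrectangle
#' `Omega_SM(p_ABM)` returned by the confidence-hypersurface field. Sampling
#' at each point is seeded deterministically from `(seed, p_abm)`, so
#' repeated evaluation at the same point returns the same value.
#'
#' @param field a [build_field()] result.
#' @param sm list describing the surrogate evaluation: `model` (registry
#'   name), `init` (initial condition), `times` (solution times), optional
#'   `dt`.
#' @param metric a metric function on [trajectory()] objects, or a name
#'   accepted by [metric_fn()]. Applied to the total (summed-variable)
#'   surrogate solution.
#' @param n_mc Monte Carlo samples per evaluation.
#' @param seed base seed.
#' @return A function `p_abm -> value` (class `metric_function`) with an
#'   evaluation ledger ([evaluation_count()]).
#' @export
surrogate_metric <- function(field, sm, metric, n_mc = 100, seed = 1) {
  if (is.character(metric)) metric <- metric_fn(metric)
  if (n_mc < 1) stop("n_mc must be >= 1")
  dt <- if (is.null(sm$dt)) 0.01 else sm$dt
  ledger <- new_ledger()
  f <- function(p_abm) {
    ledger$count <- ledger$count + 1L
    rect <- query(field, p_abm)
    S <- sample_hyperrectangle(rect, n_mc, seed = stable_seed(seed, p_abm))
    vals <- apply(S, 1, function(ps) {
      sol <- solve_sm_matrix(sm$model, setNames(ps, colnames(S)), sm$init,
                             sm$times, dt)
      metric(trajectory(sm$times, rowSums(sol)))
    })
    mean(vals)
  }
  structure(f, ledger = ledger, mode = "surrogate-transfer",
            class = c("metric_function", "function"))
}

#' Direct ABM metric over ABM parameter space
#'
#' Maps an ABM parameter vector to the metric of the mean total-count
#' trajectory of an `n_replicates` ensemble simulated at that vector.
#' Integer-valued parameters (`T_con`) are rounded here. Results are cached
#' per (point, seed) so a design that revisits a point does not rerun the
#' ABM.
#'
#' @param template an [abm_params()] giving values for parameters not in the
#'   queried vector.
#' @param metric metric function or name (see [metric_fn()]).
#' @param n_replicates replicates per evaluation.
#' @param seed base seed (per-point seeds are derived deterministically).
#' @param sim_options list of extra arguments to [simulate_abm()]
#'   (lattice_size, record_times, ...).
#' @return A function `p_abm -> value` (class `metric_function`) with an
#'   evaluation ledger.
#' @export
abm_metric <- function(template, metric, n_replicates = 5, seed = 1,
                       sim_options = list()) {
  if (is.character(metric)) metric <- metric_fn(metric)
  stopifnot(inherits(template, "abm_params"))
  ledger <- new_ledger()
  cache <- new.env(parent = emptyenv())
  f <- function(p_abm) {
    ledger$count <- ledger$count + 1L
    key <- paste(sprintf("%.10g", as.numeric(p_abm)), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    pl <- as.list(p_abm)
    if (!is.null(pl$T_con)) pl$T_con <- round(pl$T_con)
    params <- do.call(abm_params, modifyList(unclass(template), pl))
    ens <- do.call(run_ensemble,
                   c(list(params = params, n_replicates = n_replicates,
                          base_seed = stable_seed(seed, p_abm)), sim_options))
    val <- metric(mean_trajectory(ens))
    cache[[key]] <- val
    val
  }
  structure(f, ledger = ledger, mode = "direct-ABM",
            class = c("metric_function", "function"))
}

#' Run a global sensitivity analysis
#'
#' Generates the design for the requested method, evaluates the metric at
#' every design point, and computes the indices. The metric may be a direct
#' ABM metric, a surrogate-transfer metric, or any function of a named
#' parameter vector.
#'
#' @param method `"moat"` or `"efast"`.
#' @param f metric function over the space.
#' @param space a [parameter_space()].
#' @param options method options: `r`, `levels` (moat); `Ns`, `M`, `Nr`
#'   (efast).
#' @param seed design seed.
#' @return A `moat_result` or `efast_result`, with the design and the number
#'   of metric evaluations attached.
#' @export
run_gsa <- function(method = c("moat", "efast"), f, space, options = list(),
                    seed = 1) {
  method <- match.arg(method)
  design <- if (method == "moat") {
    morris_design(space,
                  r = options$r %||% 30,
                  levels = options$levels %||% 4,
                  seed = seed)
  } else {
    efast_design(space,
                 Ns = options$Ns %||% 65,
                 M = options$M %||% 4,
                 Nr = options$Nr %||% 4,
                 seed = seed)
  }
  y <- numeric(nrow(design$X))
  for (i in seq_len(nrow(design$X))) {
    p <- setNames(design$X[i, ], space$names)
    v <- tryCatch(f(p), error = function(e)
      stop(sprintf("metric failed at design point %d (%s): %s", i,
                   paste(sprintf("%s=%.4g", names(p), p), collapse = ", "),
                   conditionMessage(e)), call. = FALSE))
    if (!is.finite(v))
      stop(sprintf("metric returned non-finite value at design point %d", i))
    y[i] <- v
  }
  res <- if (method == "moat") morris_indices(design, y) else efast_indices(design, y)
  res$design <- design
  res$y <- y
  res$n_evaluations <- length(y)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
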