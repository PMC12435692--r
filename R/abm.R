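#' Parameters of the bundled 2D cell-proliferation ABM
#'
#' The bundled agent-based model is a 2D on-lattice birth-death-free
#' migration-proliferation model with explicit cell-cycle phases
#' (G1, S, G2, M). Cells advance through the cycle at per-phase exponential
#' rates. Contact inhibition acts at the restriction point: the G1 -> S
#' transition is arrested while more than `T_con` Moore neighbours are
#' occupied, so crowded cells accumulate in G1 as the culture approaches
#' confluence. The M -> G1 transition always completes; it additionally
#' produces a daughter G1 cell in a uniformly chosen empty Moore neighbour
#' unless no empty neighbour exists or the division is thinned globally with
#' probability `N/K_A` (logistic crowding; the analogue of the surrogate's
#' `(2 - N/K_C)` division-yield factor). Cells also migrate to empty Moore
#' neighbours at rate `s`.
#'
#' @param K_A carrying capacity (cells); a division is blocked with
#'   probability `N_total / K_A`.
#' @param T_con contact-inhibition threshold: the G1 -> S transition is
#'   arrested while the number of occupied Moore neighbours exceeds `T_con`.
#'   Integer in 0..8.
#' @param s migration rate (moves/cell/day).
#' @param rho_G1_S,rho_S_G2,rho_G2_M,rho_M_G1 phase-transition rates (1/day);
#'   `rho_M_G1` doubles as the division rate.
#'
#' @return An object of class `abm_params`.
#' @export
abm_params <- function(K_A = 3000, T_con = 3, s = 10,
                       rho_G1_S = 2, rho_S_G2 = 2, rho_G2_M = 2, rho_M_G1 = 2) {
  rates <- c(rho_G1_S = rho_G1_S, rho_S_G2 = rho_S_G2,
             rho_G2_M = rho_G2_M, rho_M_G1 = rho_M_G1)
  if (any(!is.finite(rates)) || any(rates < 0)) stop("transition rates must be finite and >= 0")
  if (!is.finite(s) || s < 0) stop("migration rate s must be >= 0")
  if (!is.finite(K_A) || K_A <= 0) stop("K_A must be > 0")
  if (T_con != round(T_con) || T_con < 0 || T_con > 8) stop("T_con must be an integer in [0, 8]")
  structure(list(K_A = K_A, T_con = as.integer(round(T_con)), s = s,
                 rho_G1_S = rho_G1_S, rho_S_G2 = rho_S_G2,
                 rho_G2_M = rho_G2_M, rho_M_G1 = rho_M_G1),
            class = "abm_params")
}

#' @export
print.abm_params <- function(x, ...) {
  cat("<abm_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

default_record_times <- function() seq(0, 3, by = 0.5)

#' Simulate one realization of the 2D lattice ABM
#'
#' Fixed-time-step stochastic simulation (synchronous over a random cell
#' order each step). Each cell attempts, in order, a phase transition with
#' probability `1 - exp(-rho * dt)` and a migration with probability
#' `1 - exp(-s * dt)`. The lattice has reflecting edges. Identical
#' `(params, seed)` give identical trajectories.
#'
#' @param params an [abm_params()] object.
#' @param lattice_size sites per side of the square lattice.
#' @param n_initial number of initially seeded cells, placed at uniformly
#'   random distinct sites with phases drawn from an asynchronous-culture
#'   mix (40/30/20/10% for G1/S/G2/M). Ignored when `init_cells` is given.
#' @param t_end end time (days).
#' @param record_times recording times (days), a subset of `[0, t_end]`.
#' @param seed integer RNG seed.
#' @param dt time step (days).
#' @param init_cells optional integer matrix (n x 3: column x, y, phase
#'   1=G1..4=M, 1-based coordinates) overriding the random initial seeding.
#'
#' @return An [ensemble_ts()] with one replicate and variables
#'   `N_G1S` (G1 + S counts) and `N_G2M` (G2 + M counts).
#' @export
simulate_abm <- function(params, lattice_size = 100, n_initial = 1000,
                         t_end = 3, record_times = default_record_times(),
                         seed = 1, dt = 0.01, init_cells = NULL) {
  stopifnot(inherits(params, "abm_params"))
  cap <- lattice_size^2
  if (params$K_A > cap) stop("K_A exceeds lattice capacity")
  if (any(record_times < 0) || any(record_times > t_end + 1e-9))
    stop("record_times must lie in [0, t_end]")
  if (any(diff(record_times) <= 0)) stop("record_times must be strictly increasing")
  set.seed(as.integer(seed))
  if (is.null(init_cells)) {
    if (n_initial > cap) stop("n_initial exceeds lattice capacity")
    sites <- sample.int(cap, n_initial)
    # asynchronous-culture phase mix, roughly proportional to typical
    # mammalian phase durations (G1 > S > G2 > M)
    init_cells <- cbind(((sites - 1L) %/% lattice_size) + 1L,
                        ((sites - 1L) %% lattice_size) + 1L,
                        sample.int(4L, n_initial, replace = TRUE,
                                   prob = c(0.4, 0.3, 0.2, 0.1)))
  }
  storage.mode(init_cells) <- "integer"
  rates <- c(params$rho_G1_S, params$rho_S_G2, params$rho_G2_M, params$rho_M_G1)
  cnt <- cpp_simulate_abm(as.integer(lattice_size), init_cells, rates,
                          params$s, params$K_A, params$T_con,
                          dt, as.numeric(record_times), t_end)
  counts <- array(0, dim = c(1L, length(record_times), 2L))
  counts[1, , 1] <- cnt[, 1]; counts[1, , 2] <- cnt[, 2]
  ensemble_ts(record_times, counts, c("N_G1S", "N_G2M"),
              meta = list(params = unclass(params), seed = seed,
                          lattice_size = lattice_size, dt = dt,
                          n_initial = nrow(init_cells)))
}

#' Run an ensemble of independent ABM replicates
#'
#' Replicate `i` uses seed `base_seed + i - 1`, so the ensemble is fully
#' reproducible and replicate trajectories are independent realizations.
#'
#' @param params an [abm_params()] object.
#' @param n_replicates number of replicates (>= 1).
#' @param base_seed integer; replicate seeds are derived from it.
#' @param ... further arguments passed to [simulate_abm()].
#' @return An [ensemble_ts()] with `n_replicates` replicates.
#' @export
run_ensemble <- function(params, n_replicates = 6, base_seed = 1, ...) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  reps <- lapply(seq_len(n_replicates), function(i)
    simulate_abm(params, seed = base_seed + i - 1L, ...))
  out <- bind_ensembles(reps)
  out$meta <- c(reps[[1]]$meta["params"], list(base_seed = base_seed,
                n_replicates = n_replicates))
  out
}

#' Sample ABM parameter vectors over a parameter space
#'
#' Both designs include every corner of the box (all `2^m` combinations of
#' bounds): a full-factorial grid contains them by construction, and the
#' Latin-hypercube design appends them explicitly, since boundary coverage is
#' needed to interpolate confidence hypersurfaces without extrapolation.
#'
#' @param space a [parameter_space()].
#' @param design `"grid"` (full factorial) or `"lhs"` (maximin-free random
#'   Latin hypercube plus corners).
#' @param levels for `"grid"`: number of levels per dimension (scalar or
#'   vector, >= 2).
#' @param n_points for `"lhs"`: number of interior points.
#' @param seed RNG seed (used by `"lhs"`).
#' @return A numeric matrix (points x parameters) with named columns.
#' @export
sample_parameter_space <- function(space, design = c("grid", "lhs"),
                                   levels = 2, n_points = NULL, seed = 1) {
  design <- match.arg(design)
  stopifnot(inherits(space, "parameter_space"))
  lo <- space$lower; up <- space$upper; m <- space$m
  if (design == "grid") {
    if (any(levels < 2)) stop("grid needs >= 2 levels per dimension")
    levels <- rep_len(levels, m)
    axes <- lapply(seq_len(m), function(j) seq(lo[j], up[j], length.out = levels[j]))
    names(axes) <- space$names
    X <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  } else {
    if (is.null(n_points) || n_points < 1) stop("lhs needs n_points >= 1")
    set.seed(as.integer(seed))
    U <- lhs::randomLHS(n_points, m)
    X <- sweep(sweep(U, 2, up - lo, "*"), 2, lo, "+")
    corners <- as.matrix(expand.grid(lapply(seq_len(m), function(j) c(lo[j], up[j]))))
    X <- rbind(X, corners)
    colnames(X) <- space$names
  }
  rownames(X) <- NULL
  X
}

#' Stochastic mock growth-curve ensembles
#'
#' Stand-in generator for an expensive external ABM: replicate trajectories
#' are a deterministic growth-law solution times multiplicative lognormal
#' noise (`meanlog = 0`, `sdlog = noise_sd`), clipped at zero.
#'
#' @param truth_model `"exponential"`, `"logistic"` or `"vonB"`.
#' @param truth_params named list of the growth-law parameters, including
#'   the initial size `N0` (see [solve_growth()]).
#' @param noise_sd lognormal sdlog (approximately the fractional noise level).
#' @param times recording times (days).
#' @param n_replicates number of replicates.
#' @param seed RNG seed.
#' @return An [ensemble_ts()] with the single variable `N`.
#' @export
mock_growth_ensemble <- function(truth_model = c("exponential", "logistic", "vonB"),
                                 truth_params, noise_sd = 0.1,
                                 times = seq(0, 3, by = 0.5),
                                 n_replicates = 10, seed = 1) {
  truth_model <- match.arg(truth_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  N0 <- truth_params$N0
  if (is.null(N0)) stop("truth_params must include N0")
  sol <- solve_growth(growth_params(truth_model, truth_params), N0, times)
  base <- sol$values[, 1]
  set.seed(as.integer(seed))
  noise <- matrix(exp(rnorm(n_replicates * length(times), 0, noise_sd)),
                  nrow = n_replicates)
  counts <- array(0, dim = c(n_replicates, length(times), 1L))
  counts[, , 1] <- pmax(sweep(noise, 2, base, "*"), 0)
  ensemble_ts(times, counts, "N",
              meta = list(truth_model = truth_model, truth_params = truth_params,
                          noise_sd = noise_sd, seed = seed))
}
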