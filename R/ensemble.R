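#' Replicate-resolved ensemble time series
#'
#' Container for ABM (or mock-ABM) ensemble output: counts of each recorded
#' variable at each recording time, for each replicate.
#'
#' @param times numeric vector of recording times (days), strictly increasing.
#' @param counts numeric array of dimension `n_replicates x n_times x n_variables`.
#' @param variables character vector naming the recorded variables.
#' @param meta list of provenance metadata (parameters, seeds, lattice size...).
#'
#' @return An object of class `ensemble_ts`.
#' @export
ensemble_ts <- function(times, counts, variables, meta = list()) {
  times <- as.numeric(times)
  if (is.matrix(counts)) counts <- array(counts, dim = c(dim(counts), 1L))
  stopifnot(length(dim(counts)) == 3L)
  if (any(diff(times) <= 0)) stop("recording times must be strictly increasing")
  if (dim(counts)[2] != length(times)) stop("counts/time dimension mismatch")
  if (dim(counts)[3] != length(variables)) stop("counts/variable dimension mismatch")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  dimnames(counts) <- list(NULL, NULL, variables)
  structure(list(times = times, variables = variables, counts = counts,
                 n_replicates = dim(counts)[1], meta = meta),
            class = "ensemble_ts")
}

#' @export
print.ensemble_ts <- function(x, ...) {
  cat(sprintf("<ensemble_ts> %d replicate(s), %d times [%g, %g] days, variables: %s\n",
              x$n_replicates, length(x$times), min(x$times), max(x$times),
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' Ensemble mean and standard deviation
#'
#' @param ts an [ensemble_ts()] object.
#' @return A `n_times x n_variables` matrix.
#' @export
ens_mean <- function(ts) {
  m <- apply(ts$counts, c(2, 3), mean)
  dimnames(m) <- list(NULL, ts$variables)
  m
}

#' @rdname ens_mean
#' @export
ens_sd <- function(ts) {
  s <- apply(ts$counts, c(2, 3), sd)
  dimnames(s) <- list(NULL, ts$variables)
  s
}

#' Mean total-count trajectory of an ensemble
#'
#' Sums all recorded variables (e.g. the two cell-cycle pools) and averages
#' over replicates; this is the scalarization the output metrics act on.
#'
#' @param ts an [ensemble_ts()] object.
#' @return A [trajectory()] object.
#' @export
mean_trajectory <- function(ts) {
  m <- ens_mean(ts)
  trajectory(ts$times, rowSums(m))
}

# stack replicate ensembles that share times/variables
bind_ensembles <- function(lst) {
  t0 <- lst[[1]]
  counts <- do.call(abind3, lapply(lst, function(e) e$counts))
  ensemble_ts(t0$times, counts, t0$variables, meta = t0$meta)
}

abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, dim = c(sum(vapply(arrs, function(a) dim(a)[1], 0)), d[2], d[3]))
  at <- 1L
  for (a in arrs) {
    n <- dim(a)[1]
    out[at:(at + n - 1L), , ] <- a
    at <- at + n
  }
  out
}
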