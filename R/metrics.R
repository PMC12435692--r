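#' Scalar trajectory container
#'
#' Total-count time course on which the GSA output metrics operate.
#'
#' @param times increasing numeric times (days).
#' @param values finite numeric values (cells).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(times, values) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) < 0)) stop("times must be increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "trajectory")
}

# collapse exactly duplicated interior time points (keep first occurrence)
dedup_traj <- function(traj) {
  keep <- !duplicated(traj$times)
  list(times = traj$times[keep], values = traj$values[keep])
}

#' Output metrics for global sensitivity analysis
#'
#' Three scalarizations of a total-count trajectory: the final value
#' ("final tumor size"), the trapezoidal area under the time course, and the
#' first time the trajectory reaches half its own maximum (linear
#' interpolation between bracketing points; `t0` if the trajectory starts at
#' or above half-maximum).
#'
#' @param traj a [trajectory()] (or list with `times`, `values`).
#' @return A scalar.
#' @export
final_value <- function(traj) {
  if (length(traj$values) == 0) stop("empty trajectory")
  traj$values[length(traj$values)]
}

#' @rdname final_value
#' @export
auc <- function(traj) {
  tr <- dedup_traj(traj)
  if (length(tr$times) < 2) stop("auc needs >= 2 distinct time points")
  dt <- diff(tr$times)
  sum(dt * (head(tr$values, -1) + tail(tr$values, -1)) / 2)
}

#' @rdname final_value
#' @export
time_to_half_max <- function(traj) {
  tr <- dedup_traj(traj)
  if (length(tr$times) < 2) stop("time_to_half_max needs >= 2 time points")
  half <- max(tr$values) / 2
  if (half <= 0) stop("undefined metric: all-zero trajectory")
  if (tr$values[1] >= half) return(tr$times[1])
  i <- which(tr$values >= half)[1]
  t0 <- tr$times[i - 1]; t1 <- tr$times[i]
  v0 <- tr$values[i - 1]; v1 <- tr$values[i]
  t0 + (t1 - t0) * (half - v0) / (v1 - v0)
}

#' Look up an output metric by name
#'
#' @param name `"final"`, `"auc"` or `"t_half"`.
#' @return The metric function.
#' @export
metric_fn <- function(name) {
  switch(name,
         final = final_value,
         auc = auc,
         t_half = time_to_half_max,
         stop("unknown metric: ", name))
}
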