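#' Profile likelihood of one surrogate parameter
#'
#' Fixes the named parameter at each value of a (log-spaced) grid and
#' re-optimizes the remaining parameters, warm-starting each grid point from
#' its inward neighbour (sweeping outward from the best fit in both
#' directions). Under the normalized weighted-RSS objective this traces the
#' profile likelihood up to a monotone transform.
#'
#' `fit` may be any list with elements `objective` (a function of the full
#' named parameter vector returning the normalized weighted RSS), `par`
#' (named best-fit vector), `rss`, `n_obs` and `bounds` (2 x k matrix with
#' named columns) -- i.e. an [fit_sm()] result or a hand-built equivalent for
#' custom models.
#'
#' @param fit an `sm_fit` (or fit-like list, see Details).
#' @param param_name name of the parameter to profile.
#' @param search_range length-2 range to profile over; default
#'   `best/100 .. best*100`, clipped to the search bounds.
#' @param n_grid number of grid points (log-spaced when the range is
#'   positive, else linear).
#' @return An object of class `profile_curve` with the grid, the
#'   re-optimized RSS profile, the best value/RSS, and failure flags
#'   (failed grid points are linearly interpolated over; more than 20%
#'   failures invalidates the profile with an error).
#' @export
profile_parameter <- function(fit, param_name, search_range = NULL, n_grid = 41) {
  par0 <- fit$par
  if (!param_name %in% names(par0)) stop("unknown parameter: ", param_name)
  best <- par0[[param_name]]
  bounds <- fit$bounds
  if (is.null(search_range)) {
    search_range <- c(best / 100, best * 100)
    if (!is.null(bounds)) {
      search_range[1] <- max(search_range[1], bounds[1, param_name])
      search_range[2] <- min(search_range[2], bounds[2, param_name])
    }
  }
  if (search_range[1] > best || search_range[2] < best)
    stop("search_range must contain the best-fit value")
  grid <- if (search_range[1] > 0) {
    exp(seq(log(search_range[1]), log(search_range[2]), length.out = n_grid))
  } else {
    seq(search_range[1], search_range[2], length.out = n_grid)
  }
  # include the best-fit value itself so the profile always contains its
  # minimum (a narrow basin could otherwise fall between grid points)
  if (min(abs(grid - best)) > 0) grid <- sort(unique(c(grid, best)))
  n_grid <- length(grid)

  free <- setdiff(names(par0), param_name)
  rss <- rep(NA_real_, n_grid)
  failed <- logical(n_grid)
  eval_at <- function(value, warm) {
    if (length(free) == 0) {
      v <- fit$objective(setNames(value, param_name))
      return(list(rss = v, par = warm))
    }
    obj_free <- function(pf) {
      full <- c(setNames(value, param_name), setNames(pf, free))[names(par0)]
      fit$objective(full)
    }
    lb <- bounds[1, free]; ub <- bounds[2, free]
    res <- tryCatch(
      multistart_optimize(obj_free, lb, ub, n_starts = 0, seed = 1,
                          start = warm),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) return(NULL)
    list(rss = res$value, par = res$par)
  }

  i0 <- which.min(abs(grid - best))
  for (dir in c(1, -1)) {
    idx <- if (dir == 1) i0:n_grid else rev(seq_len(i0))
    warm <- par0[free]
    for (i in idx) {
      r <- eval_at(grid[i], warm)
      if (is.null(r)) {
        failed[i] <- TRUE
      } else {
        if (is.na(rss[i]) || r$rss < rss[i]) rss[i] <- r$rss
        warm <- r$par
      }
    }
  }
  if (mean(failed) > 0.2) stop("profile invalid: > 20% of grid points failed")
  if (any(failed)) {
    ok <- which(!failed)
    rss[failed] <- approx(grid[ok], rss[ok], xout = grid[failed], rule = 2)$y
  }
  best_rss <- min(fit$rss, min(rss, na.rm = TRUE))
  structure(list(param_name = param_name, grid = grid, rss_profile = rss,
                 best_value = best, best_rss = best_rss, n_obs = fit$n_obs,
                 failed = failed),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("<profile_curve> %s over [%.4g, %.4g] (%d points), best %.4g @ rss %.4g\n",
              x$param_name, min(x$grid), max(x$grid), length(x$grid),
              x$best_value, x$best_rss))
  invisible(x)
}

#' @export
plot.profile_curve <- function(x, level = 0.95, ...) {
  plot(x$grid, x$rss_profile, type = "l", log = if (all(x$grid > 0)) "x" else "",
       xlab = x$param_name, ylab = "weighted RSS", ...)
  thr <- x$best_rss * (1 + qchisq(level, 1) / x$n_obs)
  abline(h = thr, lty = 2)
  points(x$best_value, x$best_rss, pch = 16)
  invisible(x)
}

#' 95% profile-likelihood confidence bounds
#'
#' Thresholds the RSS profile at `best_rss + delta` with
#' `delta = best_rss * qchisq(level, 1) / n_obs` (the likelihood-ratio
#' threshold for Gaussian errors under the 1/n-normalized weighted-RSS
#' objective; with unit-variance weights this is the classic
#' un-normalized `delta RSS = 3.841`). Bounds are the outermost threshold
#' crossings, located by linear interpolation between grid points. A side
#' with no crossing inside the search range gets an infinite sentinel; a
#' flat profile (range of the profile below `delta/10`) yields `(-Inf, Inf)`.
#'
#' @param profile a [profile_parameter()] result.
#' @param level confidence level.
#' @return An object of class `confidence_interval` with `lower`, `upper`,
#'   `level`.
#' @export
confidence_bounds <- function(profile, level = 0.95) {
  g <- profile$grid; rssp <- profile$rss_profile
  delta <- profile$best_rss * qchisq(level, 1) / profile$n_obs
  thr <- profile$best_rss + delta
  if (all(rssp > thr)) stop("invalid profile: entirely above threshold")
  ci <- if (diff(range(rssp)) < delta / 10) {
    c(-Inf, Inf) # flat profile: uninformative on both sides
  } else {
    n <- length(g)
    lower <- if (rssp[1] <= thr) -Inf else {
      i <- which(rssp <= thr)[1]
      cross_interp(g[i - 1], g[i], rssp[i - 1], rssp[i], thr)
    }
    upper <- if (rssp[n] <= thr) Inf else {
      i <- max(which(rssp <= thr))
      cross_interp(g[i + 1], g[i], rssp[i + 1], rssp[i], thr)
    }
    c(lower, upper)
  }
  structure(list(lower = ci[1], upper = ci[2], level = level,
                 param_name = profile$param_name),
            class = "confidence_interval")
}

cross_interp <- function(x_out, x_in, y_out, y_in, thr) {
  if (y_out == y_in) return(x_in)
  x_in + (x_out - x_in) * (thr - y_in) / (y_out - y_in)
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("<confidence_interval> %s: [%.6g, %.6g] at %.0f%%\n",
              if (is.null(x$param_name)) "" else x$param_name,
              x$lower, x$upper, 100 * x$level))
  invisible(x)
}

#' Identifiability index of a surrogate parameter
#'
#' Counts how many of the two 95% profile bounds are finite and fall inside
#' the biologically relevant range: 2 for a U-shaped profile (both bounds
#' informative), 1 for an L-shaped profile (one bound), 0 for a flat profile
#' (neither).
#'
#' @param ci a [confidence_bounds()] result.
#' @param relevant_range finite length-2 numeric range.
#' @return Integer 0, 1 or 2.
#' @export
identifiability_index <- function(ci, relevant_range) {
  if (any(!is.finite(relevant_range))) stop("relevant_range must be finite")
  inside <- function(b) is.finite(b) && b >= relevant_range[1] && b <= relevant_range[2]
  as.integer(inside(ci$lower) + inside(ci$upper))
}
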