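#' Akaike Information Criterion for a weighted least-squares fit
#'
#' Gaussian-error form `AIC = n_obs * ln(rss/n_obs) + 2k`, where `rss` is the
#' un-normalized weighted residual sum of squares. With `aicc = TRUE` the
#' small-sample correction `2k(k+1)/(n_obs - k - 1)` is added.
#'
#' @param rss_unnorm un-normalized weighted RSS (> 0; 0 yields `-Inf` with a
#'   warning).
#' @param n_obs number of fitted data points (> k).
#' @param k number of free parameters.
#' @param aicc apply the small-sample correction.
#' @return AIC value (vectorized over its arguments).
#' @export
aic <- function(rss_unnorm, n_obs, k, aicc = FALSE) {
  if (any(n_obs <= k)) stop("n_obs must exceed k")
  if (any(rss_unnorm < 0)) stop("rss must be >= 0")
  out <- ifelse(rss_unnorm == 0, -Inf, n_obs * log(rss_unnorm / n_obs) + 2 * k)
  if (any(rss_unnorm == 0)) warning("rss = 0: AIC is -Inf")
  if (aicc) out <- out + 2 * k * (k + 1) / (n_obs - k - 1)
  out
}

#' @export
AIC.sm_fit <- function(object, ..., k = 2) {
  aic(object$rss_unnorm, object$n_obs, object$k)
}

#' Compare candidate surrogate models fitted across ABM parameter vectors
#'
#' Computes per-point AIC for every candidate, the relative log-likelihood of
#' the reference versus each alternative (`(AIC_alt - AIC_ref) / 2`; positive
#' means the reference is more likely), the per-point winner (minimal AIC,
#' ties broken by fewest parameters then candidate order), and aggregate win
#' fractions.
#'
#' @param fits named list (one entry per candidate model) of lists of
#'   [fit_sm()] results, all of equal length (one fit per ABM point).
#' @param reference name of the reference candidate.
#' @param aicc use the small-sample corrected criterion.
#' @return An object of class `model_comparison` with `aic` (points x
#'   candidates matrix), `rel_loglik` (reference vs alternatives), `winner`,
#'   `win_fraction`.
#' @export
compare_models <- function(fits, reference = names(fits)[1], aicc = FALSE) {
  if (length(fits) < 2) stop("need >= 2 candidate models")
  models <- names(fits)
  if (!reference %in% models) stop("unknown reference model")
  n_pts <- unique(vapply(fits, length, 0L))
  if (length(n_pts) != 1) stop("all candidates must be fitted at every point")
  missing <- lapply(fits, function(fl) which(vapply(fl, is.null, TRUE)))
  if (any(lengths(missing) > 0))
    stop("missing fits at points: ",
         paste(unique(unlist(missing)), collapse = ", "))
  aic_mat <- vapply(fits, function(fl)
    vapply(fl, function(f) aic(f$rss_unnorm, f$n_obs, f$k, aicc = aicc), 0),
    numeric(n_pts))
  aic_mat <- matrix(aic_mat, nrow = n_pts, dimnames = list(NULL, models))
  k_vec <- vapply(fits, function(fl) as.integer(fl[[1]]$k), 0L)

  alts <- setdiff(models, reference)
  rel <- (aic_mat[, alts, drop = FALSE] - aic_mat[, reference]) / 2
  winner <- apply(aic_mat, 1, function(a) {
    cand <- which(a <= min(a) + 1e-12)
    cand[order(k_vec[cand], cand)][1]
  })
  winner <- models[winner]
  wf <- vapply(models, function(m) mean(winner == m), 0)
  structure(list(models = models, reference = reference, aic = aic_mat,
                 rel_loglik = rel, winner = winner, win_fraction = wf,
                 k = k_vec),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d points, reference: %s\n",
              nrow(x$aic), x$reference))
  cat("win fractions:\n")
  print(round(x$win_fraction, 3))
  invisible(x)
}

#' Aggregate identifiability indices across ABM parameter vectors
#'
#' @param indices matrix or data.frame (points x surrogate parameters) of
#'   0/1/2 identifiability indices.
#' @return Matrix (3 x parameters) of the frequencies of index 0, 1 and 2;
#'   columns sum to 1. This is the data behind the identifiability
#'   "donut" summaries.
#' @export
aggregate_identifiability <- function(indices) {
  indices <- as.matrix(indices)
  if (nrow(indices) == 0) stop("no identifiability indices supplied")
  if (any(is.na(indices))) stop("identifiability indices contain NA")
  out <- apply(indices, 2, function(col)
    c(mean(col == 0), mean(col == 1), mean(col == 2)))
  rownames(out) <- c("index0", "index1", "index2")
  out
}

#' Select a surrogate model balancing fit quality and identifiability
#'
#' Candidates are first filtered to those whose surrogate parameters all have
#' an index-2 frequency of at least `threshold`; among those the candidate
#' with the highest AIC win fraction is selected. If no candidate passes the
#' filter, the highest win fraction wins with a warning -- goodness-of-fit
#' alone is then driving the choice, which is exactly the failure mode the
#' identifiability filter exists to avoid.
#'
#' @param comparison a [compare_models()] result.
#' @param identifiability named list (per candidate) of
#'   [aggregate_identifiability()] tables.
#' @param threshold required index-2 frequency.
#' @return Name of the selected model (attributes record the passing set).
#' @export
select_sm <- function(comparison, identifiability, threshold = 0.8) {
  models <- comparison$models
  ok <- vapply(models, function(m) {
    tab <- identifiability[[m]]
    !is.null(tab) && all(tab["index2", ] >= threshold)
  }, TRUE)
  pool <- models[ok]
  if (length(pool) == 0) {
    warning("no candidate meets the identifiability threshold; ",
            "falling back to best AIC win fraction")
    pool <- models
  }
  wf <- comparison$win_fraction[pool]
  sel <- pool[which.max(wf)]
  attr(sel, "passing") <- models[ok]
  sel
}
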