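#' Sampled confidence bounds over ABM parameter space
#'
#' Bundles the sampled ABM parameter vectors with the (finite, clipped)
#' lower/upper 95% bounds of each surrogate parameter at each point. These
#' are the discrete points on the lower and upper confidence hypersurfaces.
#'
#' @param points numeric matrix (points x ABM parameters), named columns.
#' @param lower,upper numeric matrices (points x surrogate parameters),
#'   named columns, with `lower <= upper` everywhere.
#' @return Object of class `sampled_bounds`.
#' @export
sampled_bounds <- function(points, lower, upper) {
  points <- as.matrix(points); lower <- as.matrix(lower); upper <- as.matrix(upper)
  if (nrow(points) != nrow(lower) || nrow(points) != nrow(upper))
    stop("points/bounds row mismatch")
  if (!identical(colnames(lower), colnames(upper)))
    stop("lower/upper column names differ")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite; clip them first (see clip_bounds)")
  if (any(lower > upper)) stop("lower bound exceeds upper bound at some point")
  structure(list(points = points, lower = lower, upper = upper,
                 abm_names = colnames(points), sm_names = colnames(lower)),
            class = "sampled_bounds")
}

#' Build confidence-bound hypersurfaces over ABM parameter space
#'
#' Each surrogate parameter's lower and upper 95% bound is viewed as an
#' unknown scalar field over ABM parameter space and interpolated from the
#' sampled points. When the samples form a full rectangular grid the field
#' is multilinear (exact at nodes, continuous, linear within each cell);
#' otherwise an inverse-distance-weighted interpolant (power 4, exact at
#' nodes, continuous) is used on the bounding box of the samples.
#'
#' @param samples a [sampled_bounds()] object.
#' @param scheme `"grid"` (multilinear; requires grid-structured samples),
#'   `"idw"` (scattered), or `"auto"` (grid if the samples form one).
#' @return Object of class `hyperrectangle_field`; query it with [query()].
#' @export
build_field <- function(samples, scheme = c("auto", "grid", "idw")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(samples, "sampled_bounds"))
  pts <- samples$points
  gr <- try_grid_structure(pts)
  if (scheme == "auto") scheme <- if (is.null(gr)) "idw" else "grid"
  if (scheme == "grid") {
    if (is.null(gr)) stop("samples do not form a full rectangular grid")
    ord <- gr$order
    field <- list(scheme = "grid", axes = gr$axes,
                  lower = samples$lower[ord, , drop = FALSE],
                  upper = samples$upper[ord, , drop = FALSE],
                  abm_names = samples$abm_names, sm_names = samples$sm_names)
  } else {
    field <- list(scheme = "idw", points = pts,
                  lower = samples$lower, upper = samples$upper,
                  domain = apply(pts, 2, range),
                  abm_names = samples$abm_names, sm_names = samples$sm_names)
  }
  structure(field, class = "hyperrectangle_field")
}

# detect a full factorial grid; returns axes and the row order that sorts
# points into last-index-fastest... we store first-axis-fastest (expand.grid order)
try_grid_structure <- function(pts) {
  m <- ncol(pts)
  axes <- lapply(seq_len(m), function(j) sort(unique(pts[, j])))
  nl <- lengths(axes)
  if (prod(nl) != nrow(pts)) return(NULL)
  idx <- matrix(0L, nrow(pts), m)
  for (j in seq_len(m)) {
    k <- match_tol(pts[, j], axes[[j]])
    if (anyNA(k)) return(NULL)
    idx[, j] <- k
  }
  stride <- cumprod(c(1, nl[-m]))
  lin <- as.integer(1L + (idx - 1L) %*% stride)
  if (anyDuplicated(lin)) return(NULL)
  names(axes) <- colnames(pts)
  list(axes = axes, order = order(lin))
}

match_tol <- function(x, table, tol = 1e-8) {
  vapply(x, function(v) {
    d <- abs(table - v)
    i <- which.min(d)
    scale <- max(abs(table), 1)
    if (d[i] <= tol * scale) i else NA_integer_
  }, 0L)
}

#' @export
print.hyperrectangle_field <- function(x, ...) {
  n <- if (x$scheme == "grid") prod(lengths(x$axes)) else nrow(x$points)
  cat(sprintf("<hyperrectangle_field> %s scheme, %d sample points, %d ABM dims -> %d SM params\n",
              x$scheme, n, length(x$abm_names), length(x$sm_names)))
  invisible(x)
}

#' Query a hyperrectangle field at an ABM parameter vector
#'
#' Evaluates the lower and upper confidence hypersurfaces of every surrogate
#' parameter at `p_abm`; the Cartesian product of the resulting intervals is
#' the hyperrectangle of surrogate-parameter space consistent with the ABM
#' there. Queries outside the field's domain raise an error (no
#' extrapolation). If interpolation makes an interval cross, the endpoints
#' are swapped with a warning.
#'
#' @param field a [build_field()] result.
#' @param p_abm named (or ordered) numeric ABM parameter vector.
#' @return Object of class `hyperrectangle`: list with named `lower` and
#'   `upper` vectors over surrogate parameters.
#' @export
query <- function(field, p_abm) {
  stopifnot(inherits(field, "hyperrectangle_field"))
  p <- align_point(p_abm, field$abm_names)
  lo <- interp_field(field, p, "lower")
  hi <- interp_field(field, p, "upper")
  if (any(lo > hi)) {
    warning("interpolated bounds crossed; swapping")
    sw <- lo > hi
    tmp <- lo[sw]; lo[sw] <- hi[sw]; hi[sw] <- tmp
  }
  hyperrectangle(lo, hi)
}

align_point <- function(p, nms) {
  if (!is.null(names(p))) {
    if (!all(nms %in% names(p))) stop("p_abm is missing parameters")
    p <- p[nms]
  }
  if (length(p) != length(nms)) stop("p_abm has wrong length")
  as.numeric(p)
}

interp_field <- function(field, p, which) {
  vals <- field[[which]]
  if (field$scheme == "grid") {
    axes <- field$axes
    m <- length(axes)
    loc <- vector("list", m)
    for (j in seq_len(m)) {
      a <- axes[[j]]
      tol <- 1e-8 * max(abs(a), 1)
      if (p[j] < a[1] - tol || p[j] > a[length(a)] + tol)
        stop("query outside field domain")
      if (length(a) == 1) {
        loc[[j]] <- list(i = 1L, w = 0)
      } else {
        i <- findInterval(p[j], a, rightmost.closed = TRUE)
        i <- min(max(i, 1L), length(a) - 1L)
        loc[[j]] <- list(i = i, w = (p[j] - a[i]) / (a[i + 1] - a[i]))
      }
    }
    nl <- lengths(axes)
    stride <- cumprod(c(1, nl[-m]))
    out <- numeric(ncol(vals))
    corners <- expand.grid(lapply(loc, function(l) if (l$w == 0) 0L else 0:1))
    for (r in seq_len(nrow(corners))) {
      w <- 1; lin <- 1L
      for (j in seq_len(m)) {
        b <- corners[r, j]
        l <- loc[[j]]
        wj <- if (length(axes[[j]]) == 1) 1 else if (b == 0) 1 - l$w else l$w
        w <- w * wj
        lin <- lin + (l$i - 1L + b) * stride[j]
      }
      if (w > 0) out <- out + w * vals[lin, ]
    }
    setNames(out, field$sm_names)
  } else {
    dom <- field$domain
    if (any(p < dom[1, ] - 1e-8 * pmax(abs(dom[1, ]), 1)) ||
        any(p > dom[2, ] + 1e-8 * pmax(abs(dom[2, ]), 1)))
      stop("query outside field domain")
    scale <- pmax(dom[2, ] - dom[1, ], 1e-12)
    d2 <- colSums(((t(field$points) - p) / scale)^2)
    if (min(d2) < 1e-20) return(setNames(vals[which.min(d2), ], field$sm_names))
    w <- 1 / d2^2
    setNames(as.numeric(crossprod(w, vals)) / sum(w), field$sm_names)
  }
}

#' Hyperrectangle in surrogate-parameter space
#'
#' @param lower,upper named finite numeric vectors with `lower <= upper`.
#' @return Object of class `hyperrectangle`.
#' @export
hyperrectangle <- function(lower, upper) {
  if (any(!is.finite(lower)) || any(!is.finite(upper))) stop("bounds must be finite")
  if (any(lower > upper)) stop("lower > upper")
  structure(list(lower = lower, upper = upper), class = "hyperrectangle")
}

#' @export
print.hyperrectangle <- function(x, ...) {
  cat("<hyperrectangle>\n")
  print(rbind(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Sample uniformly from a hyperrectangle
#'
#' @param rect a [hyperrectangle()].
#' @param n number of i.i.d. uniform draws.
#' @param seed RNG seed.
#' @return Numeric matrix (n x parameters) with named columns.
#' @export
sample_hyperrectangle <- function(rect, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  k <- length(rect$lower)
  U <- matrix(runif(n * k), n, k)
  X <- sweep(sweep(U, 2, rect$upper - rect$lower, "*"), 2, rect$lower, "+")
  colnames(X) <- names(rect$lower)
  X
}

#' Clip a confidence interval to a finite relevant range
#'
#' Infinite or out-of-range bounds are replaced by the corresponding
#' endpoint of the relevant range, so every surrogate parameter contributes
#' a finite interval to the hyperrectangle field. Clipping is flagged
#' because it widens the sampled region to the full biological range on the
#' unidentified side, which degrades the surrogate-transfer accuracy (the
#' over-parameterized-surrogate failure mode).
#'
#' @param ci a [confidence_bounds()] result (or list with `lower`, `upper`).
#' @param relevant_range finite length-2 range.
#' @return List with finite `lower`, `upper` and logical `clipped`.
#' @export
clip_bounds <- function(ci, relevant_range) {
  if (any(!is.finite(relevant_range))) stop("relevant_range must be finite")
  r1 <- relevant_range[1]; r2 <- relevant_range[2]
  lo <- ci$lower; hi <- ci$upper
  clipped <- FALSE
  if (!is.finite(lo) || lo < r1 || lo > r2) { lo <- if (is.finite(lo) && lo > r2) r2 else r1; clipped <- TRUE }
  if (!is.finite(hi) || hi > r2 || hi < r1) { hi <- if (is.finite(hi) && hi < r1) r1 else r2; clipped <- TRUE }
  list(lower = lo, upper = hi, clipped = clipped)
}

#' Serialize / load a hyperrectangle field
#'
#' JSON round-trip with full numeric precision, so a reloaded field answers
#' queries identically.
#'
#' @param field a [build_field()] result.
#' @param path file path.
#' @return `read_field` returns the field; `write_field` returns `path`
#'   invisibly.
#' @export
write_field <- function(field, path) {
  obj <- unclass(field)
  obj$version <- 1L
  # store matrices as named column lists so the round-trip is unambiguous
  mat2list <- function(m) lapply(setNames(seq_len(ncol(m)), colnames(m)),
                                 function(j) m[, j])
  for (nm in intersect(c("lower", "upper", "points", "domain"), names(obj)))
    obj[[nm]] <- mat2list(obj[[nm]])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore_mat <- function(x) do.call(cbind, lapply(x, as.numeric))
  f <- list(scheme = obj$scheme, abm_names = obj$abm_names, sm_names = obj$sm_names)
  f$lower <- restore_mat(obj$lower)
  f$upper <- restore_mat(obj$upper)
  if (obj$scheme == "grid") {
    f$axes <- lapply(obj$axes, as.numeric)
    names(f$axes) <- obj$abm_names
  } else {
    f$points <- restore_mat(obj$points)
    f$domain <- restore_mat(obj$domain)
  }
  structure(f, class = "hyperrectangle_field")
}
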