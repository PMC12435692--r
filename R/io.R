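#' Write / read ensemble time series
#'
#' Long-format CSV with columns `time`, `variable`, `replicate`, `count`,
#' plus a JSON sidecar (`<path>.json`) recording parameters, seeds, lattice
#' size and a schema version; the pair round-trips losslessly.
#'
#' @param ts an [ensemble_ts()].
#' @param path CSV file path.
#' @return `read_ensemble` returns the [ensemble_ts()]; `write_ensemble`
#'   returns `path` invisibly.
#' @export
write_ensemble <- function(ts, path) {
  stopifnot(inherits(ts, "ensemble_ts"))
  long <- expand.grid(replicate = seq_len(ts$n_replicates),
                      time = ts$times, variable = ts$variables,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$count <- as.vector(ts$counts)
  long <- long[, c("time", "variable", "replicate", "count")]
  write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(c(ts$meta, list(schema_version = 1L,
                                       variables = ts$variables)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time", "variable", "replicate", "count")
  miss <- setdiff(needed, names(long))
  if (length(miss) > 0)
    stop("malformed ensemble CSV: missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(long$count) | long$count < 0)
  if (length(bad) > 0)
    stop("parse error at data line ", bad[1] + 1L, ": invalid count")
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  times <- sort(unique(long$time))
  vars <- if (!is.null(meta$variables)) meta$variables else unique(long$variable)
  reps <- sort(unique(long$replicate))
  counts <- array(NA_real_, dim = c(length(reps), length(times), length(vars)))
  ii <- cbind(match(long$replicate, reps), match(long$time, times),
              match(long$variable, vars))
  counts[ii] <- long$count
  if (any(is.na(counts))) stop("parse error: incomplete replicate/time/variable grid")
  meta$variables <- NULL; meta$schema_version <- NULL
  ensemble_ts(times, counts, vars, meta = meta)
}

#' Run the full surrogate-transfer sensitivity pipeline
#'
#' Executes the five framework stages against the bundled 2D lattice ABM:
#' (1) sample ABM parameter space and simulate ensembles, (2-3) fit the
#' candidate surrogate(s), profile their parameters and score
#' identifiability (plus AIC selection when several candidates are given),
#' (4) clip the confidence bounds and build the hyperrectangle field,
#' (5) run the requested GSA method through the surrogate (and optionally
#' directly on the ABM for comparison). When `out_dir` is given, stage
#' artifacts (ensemble CSVs, the serialized field, index CSVs and a
#' manifest recording seeds and evaluation counts) are written there; all
#' stages are deterministic functions of the config and seed, so a rerun
#' with the same config reproduces every artifact exactly.
#'
#' @param config a list with entries:
#'   `space` (named `lower`/`upper` vectors over ABM parameters),
#'   `design` (list: `type` "grid"/"lhs", `levels` or `n_points`),
#'   `abm` (list: `n_replicates`, plus [simulate_abm()] options and fixed
#'   parameter values),
#'   `sm_candidates` (character; default `"cellcycle"`),
#'   `profile` (list: `n_grid`, `relevant_ranges` named list),
#'   `gsa` (list: `method`, `metric`, `options`, `n_mc`, `direct` flag,
#'   `direct_replicates`),
#'   `seed`, and optional `out_dir`.
#' @return A list with the sampled `points`, per-candidate `fits`,
#'   `profiles`, `indices`, `identifiability` tables, the `selection` (if
#'   >= 2 candidates), the `field`, the surrogate-side `gsa` result, the
#'   optional `gsa_direct` result, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  space <- parameter_space(unlist(cfg$space$lower), unlist(cfg$space$upper))
  des <- cfg$design %||% list(type = "grid", levels = 2)
  pts <- if (identical(des$type, "lhs")) {
    sample_parameter_space(space, "lhs", n_points = des$n_points, seed = seed)
  } else {
    sample_parameter_space(space, "grid", levels = des$levels %||% 2)
  }

  abm_cfg <- cfg$abm %||% list()
  n_rep <- abm_cfg$n_replicates %||% 6
  sim_opts <- abm_cfg[setdiff(names(abm_cfg), c("n_replicates", "params"))]
  fixed <- abm_cfg$params %||% list()
  candidates <- cfg$sm_candidates %||% "cellcycle"
  prof_cfg <- cfg$profile %||% list()
  n_grid <- prof_cfg$n_grid %||% 41
  rel_default <- list(lambda_C = c(1e-6, 100), alpha_C = c(1e-6, 100),
                      K_C = c(1e-6, 1e6), lambda = c(1e-6, 100),
                      r = c(1e-6, 100), K = c(1e-6, 1e6),
                      alpha = c(1e-6, 1e6), beta = c(1e-6, 100),
                      nu = c(1, 20))
  rel_ranges <- modifyList(rel_default, prof_cfg$relevant_ranges %||% list())

  # stage 1: ensembles
  ensembles <- lapply(seq_len(nrow(pts)), function(i) {
    p <- as.list(pts[i, ])
    if (!is.null(p$T_con)) p$T_con <- round(p$T_con)
    params <- do.call(abm_params, modifyList(fixed, p))
    ens <- do.call(run_ensemble,
                   c(list(params = params, n_replicates = n_rep,
                          base_seed = stable_seed(seed, pts[i, ])), sim_opts))
    if (!is.null(out_dir))
      write_ensemble(ens, file.path(out_dir, sprintf("ensemble_%03d.csv", i)))
    ens
  })

  # stages 2-3: fit, profile, identifiability (per candidate)
  fits <- profiles <- indices <- ident <- list()
  for (mod in candidates) {
    fl <- lapply(ensembles, function(e) fit_sm(mod, e, seed = seed))
    pn <- names(fl[[1]]$par)
    prof <- lapply(fl, function(f) {
      setNames(lapply(pn, function(nm)
        profile_parameter(f, nm, n_grid = n_grid)), pn)
    })
    idx <- t(vapply(prof, function(pl)
      vapply(pn, function(nm)
        identifiability_index(confidence_bounds(pl[[nm]]), rel_ranges[[nm]]),
        0L), integer(length(pn))))
    colnames(idx) <- pn
    fits[[mod]] <- fl
    profiles[[mod]] <- prof
    indices[[mod]] <- idx
    ident[[mod]] <- aggregate_identifiability(idx)
  }

  selection <- NULL
  chosen <- candidates[1]
  if (length(candidates) >= 2) {
    cmp <- compare_models(fits, reference = candidates[1])
    chosen <- as.character(select_sm(cmp, ident))
    selection <- list(comparison = cmp, selected = chosen)
  } else {
    message("single surrogate candidate; skipping model selection")
  }

  # stage 4: clip bounds, build field
  fl <- fits[[chosen]]
  pn <- names(fl[[1]]$par)
  lower <- upper <- matrix(NA_real_, nrow(pts), length(pn),
                           dimnames = list(NULL, pn))
  n_clipped <- 0L
  for (i in seq_along(fl)) {
    for (nm in pn) {
      ci <- confidence_bounds(profiles[[chosen]][[i]][[nm]])
      cb <- clip_bounds(ci, rel_ranges[[nm]])
      if (cb$clipped) n_clipped <- n_clipped + 1L
      lower[i, nm] <- cb$lower; upper[i, nm] <- cb$upper
    }
  }
  field <- build_field(sampled_bounds(pts, lower, upper))
  if (!is.null(out_dir)) write_field(field, file.path(out_dir, "field.json"))

  # stage 5: GSA through the surrogate (and optionally direct)
  gsa_cfg <- cfg$gsa %||% list()
  method <- gsa_cfg$method %||% "moat"
  metric <- gsa_cfg$metric %||% "final"
  times <- sim_opts$record_times %||% default_record_times()
  init <- ens_mean(ensembles[[1]])[1, fl[[1]]$variables]
  f_sur <- surrogate_metric(field, list(model = chosen, init = init,
                                        times = times),
                            metric, n_mc = gsa_cfg$n_mc %||% 100, seed = seed)
  gsa_res <- run_gsa(method, f_sur, space, options = gsa_cfg$options %||% list(),
                     seed = seed)
  gsa_direct <- NULL
  if (isTRUE(gsa_cfg$direct)) {
    f_dir <- abm_metric(do.call(abm_params, fixed), metric,
                        n_replicates = gsa_cfg$direct_replicates %||% 5,
                        seed = seed, sim_options = sim_opts)
    gsa_direct <- run_gsa(method, f_dir, space,
                          options = gsa_cfg$options %||% list(), seed = seed)
  }

  manifest <- list(seed = seed, n_points = nrow(pts), n_replicates = n_rep,
                   candidates = candidates, selected = chosen,
                   n_clipped_bounds = n_clipped,
                   gsa_method = method, metric = metric,
                   surrogate_evaluations = evaluation_count(f_sur),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(cbind(gsa_res$table), file.path(out_dir, "gsa_surrogate.csv"),
              row.names = FALSE)
    if (!is.null(gsa_direct))
      write.csv(cbind(gsa_direct$table), file.path(out_dir, "gsa_direct.csv"),
                row.names = FALSE)
  }
  list(points = pts, ensembles = ensembles, fits = fits, profiles = profiles,
       indices = indices, identifiability = ident, selection = selection,
       field = field, gsa = gsa_res, gsa_direct = gsa_direct,
       manifest = manifest)
}
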