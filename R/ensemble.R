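# Run ensembles: parameter sweeps over model constants with step,
# Monte-Carlo, or Latin-hypercube designs, executed with full
# provenance (model hash, per-run assignments and seeds) so any run can
# be reproduced from the manifest alone.

#' Declare a swept parameter
#'
#' @param path Dotted path to an order-0 constant in the compiled model
#'   (population/connection prefix or model-scope global), e.g.
#'   `"Esyn.w"` or `"we"`.
#' @param design `"step"` (evenly spaced inclusive grid, crossed
#'   full-factorially with other step parameters), `"monte_carlo"`
#'   (joint uniform draws), or `"latin_hypercube"` (one draw per
#'   stratum, strata permuted independently per parameter).
#' @param range Numeric `c(low, high)` with `low <= high`.
#' @param count Number of levels (step) or samples (sampled designs).
#' @return A `"parameter_spec"` object.
#' @export
parameter_spec <- function(path, design = c("step", "monte_carlo", "latin_hypercube"),
                           range, count) {
  design <- match.arg(design)
  stopifnot(is.numeric(range), length(range) == 2L, range[[1L]] <= range[[2L]], count >= 1L)
  structure(list(path = path, design = design, range = as.numeric(range),
                 count = as.integer(count)),
            class = "parameter_spec")
}

# Check that a path resolves to an order-0 unconditioned equation.
.check_param_path <- function(cm, path) {
  segs <- identifier_segments(path)
  first <- segs[[1L]]
  tmpl <- NULL
  target <- path
  if (first %in% names(cm$populations)) {
    tmpl <- cm$populations[[first]]$template
    target <- paste(segs[-1L], collapse = ".")
  } else if (first %in% names(cm$connections)) {
    tmpl <- cm$connections[[first]]$template
    target <- paste(segs[-1L], collapse = ".")
  }
  eqs <- if (is.null(tmpl)) cm$globals else tmpl$equations
  for (eq in eqs)
    if (eq$target == target && is.null(eq$condition)) {
      if (eq$order > 0L)
        stop(sprintf("parameter path '%s' targets a differential equation", path), call. = FALSE)
      return(invisible(TRUE))
    }
  stop(sprintf("parameter path '%s' does not resolve to a constant in the model", path),
       call. = FALSE)
}

#' Plan a run ensemble
#'
#' Step parameters form an inclusive, evenly spaced grid and are crossed
#' full-factorially; sampled parameters (Monte Carlo or Latin hypercube,
#' which must share one sample count) are drawn jointly, and crossed
#' with the step grid.  Every run gets a distinct seed derived from
#' `base_seed` and the run index via [derive_seed()], so the plan alone
#' suffices to reproduce any run.
#'
#' @param model A `"compiled_model"`.
#' @param specs List of [parameter_spec()] objects (possibly empty: one
#'   baseline run).
#' @param base_seed Integer ensemble seed.
#' @return An `"ensemble_plan"`: list with `model_hash`, `base_seed`,
#'   `specs`, and `runs` (data frame: `run`, `seed`, one column per
#'   parameter path).
#' @export
plan_ensemble <- function(model, specs, base_seed) {
  stopifnot(inherits(model, "compiled_model"))
  if (inherits(specs, "parameter_spec")) specs <- list(specs)
  for (sp in specs) {
    stopifnot(inherits(sp, "parameter_spec"))
    .check_param_path(model, sp$path)
  }
  paths <- vapply(specs, function(s) s$path, "")
  if (anyDuplicated(paths)) stop("duplicate parameter paths in ensemble specs", call. = FALSE)

  step_specs <- Filter(function(s) s$design == "step", specs)
  samp_specs <- Filter(function(s) s$design != "step", specs)

  grid <- if (length(step_specs)) {
    levels <- lapply(step_specs, function(s) {
      if (s$count == 1L) s$range[[1L]]
      else seq(s$range[[1L]], s$range[[2L]], length.out = s$count)
    })
    names(levels) <- vapply(step_specs, function(s) s$path, "")
    expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(row.names = 1L)
  }

  samples <- NULL
  if (length(samp_specs)) {
    counts <- vapply(samp_specs, function(s) s$count, 0L)
    if (length(unique(counts)) != 1L)
      stop("sampled parameters must share one sample count", call. = FALSE)
    designs <- unique(vapply(samp_specs, function(s) s$design, ""))
    if (length(designs) != 1L)
      stop("sampled parameters must share one design (monte_carlo or latin_hypercube)",
           call. = FALSE)
    nsamp <- counts[[1L]]
    k <- length(samp_specs)
    u <- .with_seed(derive_seed(base_seed, 0L), function() {
      if (designs == "latin_hypercube") lhs::randomLHS(nsamp, k)
      else matrix(stats::runif(nsamp * k), nrow = nsamp, ncol = k)
    })
    samples <- as.data.frame(u)
    names(samples) <- vapply(samp_specs, function(s) s$path, "")
    for (j in seq_len(k)) {
      r <- samp_specs[[j]]$range
      samples[[j]] <- r[[1L]] + samples[[j]] * (r[[2L]] - r[[1L]])
    }
    attr(samples, "strata") <- apply(u, 2L, function(col) floor(col * nsamp))
  }

  runs <- if (is.null(samples)) grid
          else if (ncol(grid) == 0L) samples
          else merge(grid, samples, by = NULL)  # cross join
  if (nrow(runs) == 0L) runs <- data.frame(row.names = 1L)
  runs <- cbind(run = seq_len(nrow(runs)),
                seed = vapply(seq_len(nrow(runs)), function(i) derive_seed(base_seed, i), 0L),
                runs)
  rownames(runs) <- NULL

  structure(list(model_hash = model$content_hash, base_seed = as.integer(base_seed),
                 specs = specs, runs = runs,
                 strata = if (!is.null(samples)) attr(samples, "strata") else NULL),
            class = "ensemble_plan")
}

.with_seed <- function(seed, f) {
  glob <- globalenv()
  old <- if (exists(".Random.seed", envir = glob, inherits = FALSE))
    get(".Random.seed", envir = glob) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = glob)
          else assign(".Random.seed", old, envir = glob))
  f()
}

#' @export
print.ensemble_plan <- function(x, ...) {
  cat(sprintf("<ensemble plan: %d run(s), %d parameter(s), base seed %d>\n",
              nrow(x$runs), length(x$specs), x$base_seed))
  cat("  model:", substr(x$model_hash, 1, 12), "\n")
  invisible(x)
}

#' Execute a run ensemble
#'
#' Applies each run's parameter assignment with [override_parameter()],
#' simulates with the run's derived seed (the wiring stream is shared
#' across runs, seeded from the ensemble base seed, so all runs see the
#' same network structure), and writes
#' `run_<index>/series.csv|raster.csv|events.csv` plus a
#' `manifest.json` recording the model hash and every assignment and
#' seed.  A failing run is recorded with its error and the ensemble
#' continues.
#'
#' @param plan An `"ensemble_plan"` for `model`.
#' @param model The `"compiled_model"` the plan was made for.
#' @param config Base `"simulation_config"` (per-run seeds override its
#'   `seed`).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written as JSON).
#' @export
execute_ensemble <- function(plan, model, config, out_dir) {
  stopifnot(inherits(plan, "ensemble_plan"), inherits(model, "compiled_model"),
            inherits(config, "simulation_config"))
  if (!identical(plan$model_hash, model$content_hash))
    stop("plan was made for a different model (content hash mismatch)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(plan$specs, function(s) s$path, "")
  wiring_seed <- derive_seed(plan$base_seed, 999983L)

  run_entries <- vector("list", nrow(plan$runs))
  for (i in seq_len(nrow(plan$runs))) {
    row <- plan$runs[i, , drop = FALSE]
    assignment <- as.list(row[paths])
    rdir <- file.path(out_dir, sprintf("run_%d", row$run))
    dir.create(rdir, showWarnings = FALSE)
    status <- "ok"; err <- NULL; counts <- NULL
    res <- tryCatch({
      cmi <- model
      for (p in paths) cmi <- override_parameter(cmi, p, row[[p]])
      cfg <- config
      cfg$seed <- as.integer(row$seed)
      cfg$wiring_seed <- wiring_seed
      r <- run_simulation(cmi, cfg)
      write_series_csv(r, file.path(rdir, "series.csv"))
      write_raster_csv(r, file.path(rdir, "raster.csv"))
      write_events_csv(r, file.path(rdir, "events.csv"))
      counts <- as.list(r$final_counts)
      r
    }, error = function(e) {
      status <<- "error"; err <<- conditionMessage(e); NULL
    })
    run_entries[[i]] <- list(
      run = row$run, seed = row$seed, wiring_seed = wiring_seed,
      assignment = assignment, status = status,
      error = err, final_counts = counts,
      paths = list(series = file.path(sprintf("run_%d", row$run), "series.csv"),
                   raster = file.path(sprintf("run_%d", row$run), "raster.csv"),
                   events = file.path(sprintf("run_%d", row$run), "events.csv")))
  }

  manifest <- list(
    format = "partsim-ensemble-1",
    model_name = model$model_name,
    model_hash = model$content_hash,
    base_seed = plan$base_seed,
    wiring_seed = wiring_seed,
    config = list(dt = config$dt, duration = config$duration,
                  integrator = config$integrator,
                  spike_threshold = config$spike_threshold,
                  spike_variable = config$spike_variable),
    parameters = lapply(plan$specs, function(s)
      list(path = s$path, design = s$design, range = s$range, count = s$count)),
    runs = run_entries,
    out_dir = normalizePath(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "ensemble_manifest"
  invisible(manifest)
}

#' Read an ensemble manifest back from disk
#'
#' @param path Path to a `manifest.json` or to the ensemble directory.
#' @return An `"ensemble_manifest"` list.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::read_json(path)
  m$out_dir <- dirname(normalizePath(path))
  class(m) <- "ensemble_manifest"
  m
}

#' Load an ensemble configuration file
#'
#' JSON with fields `base_seed`, `simulation` (arguments to
#' [simulation_config()]), and `parameters` (each with `path`,
#' `design`, `range`, `count`).
#'
#' @param path Path to the JSON configuration.
#' @return List with `specs`, `base_seed`, and `config`.
#' @export
load_ensemble_config <- function(path) {
  cfg <- jsonlite::read_json(path)
  specs <- lapply(cfg$parameters, function(p)
    parameter_spec(p$path, p$design, unlist(p$range), p$count))
  sim <- cfg$simulation %||% list()
  config <- do.call(simulation_config, sim)
  list(specs = specs, base_seed = as.integer(cfg$base_seed %||% 1L), config = config)
}
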