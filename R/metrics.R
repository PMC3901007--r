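# Activity metrics for spiking runs: per-neuron rates, participation,
# rate dispersion (Gini), and a four-way dynamical-regime
# classification used to summarize parameter sweeps.

#' Summary statistics of a spike raster
#'
#' @param raster Data frame with columns `neuron_id` and `spike_time`
#'   (as produced by [run_simulation()]).
#' @param window Analysis window length in milliseconds (> 0); rates
#'   are reported in Hz.
#' @param n_neurons Number of neurons in the population (silent neurons
#'   count toward participation and dispersion).
#' @return An `"activity_stats"` object: `mean_rate` (Hz),
#'   `per_neuron_rates`, `participation` (fraction with >= 1 spike),
#'   and `dispersion` (Gini coefficient of per-neuron rates; 0 when no
#'   neuron spikes).
#' @export
activity_stats <- function(raster, window, n_neurons) {
  stopifnot(window > 0, n_neurons >= 1)
  counts <- rep(0, n_neurons)
  if (nrow(raster)) {
    tab <- table(raster$neuron_id)
    ids <- as.numeric(names(tab))
    if (min(ids) >= 0 && max(ids) < n_neurons) {
      counts[ids + 1] <- as.numeric(tab)  # 0-based instance ids
    } else {
      u <- sort(unique(ids))
      if (length(u) > n_neurons)
        stop("raster contains more distinct neuron ids than n_neurons", call. = FALSE)
      counts[match(ids, u)] <- as.numeric(tab)
    }
  }
  rates <- counts / (window / 1000)
  structure(list(mean_rate = mean(rates),
                 per_neuron_rates = rates,
                 participation = mean(counts > 0),
                 dispersion = .gini(rates)),
            class = "activity_stats")
}

.gini <- function(x) {
  n <- length(x)
  mu <- mean(x)
  if (n == 0L || mu == 0) return(0)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mu)
}

#' @export
print.activity_stats <- function(x, ...) {
  cat(sprintf("mean rate %.2f Hz, participation %.2f, dispersion (Gini) %.2f\n",
              x$mean_rate, x$participation, x$dispersion))
  invisible(x)
}

#' Classify network activity into a dynamical regime
#'
#' Four mutually exclusive regimes, in the order tested: `silent`
#' (mean rate below `rate_silent`), `hyperactive` (mean rate at or
#' above `rate_hyper` with broad participation), `skewed` (activity
#' confined to a sub-`participation_low` fraction of neurons), else
#' `asynchronous`.
#'
#' @param stats An `"activity_stats"` object.
#' @param thresholds List with `rate_silent` (Hz, default 0.5),
#'   `rate_hyper` (Hz, default 50), `participation_low` (default 0.5).
#' @return One of `"silent"`, `"asynchronous"`, `"skewed"`,
#'   `"hyperactive"`.
#' @export
classify_regime <- function(stats, thresholds = regime_thresholds()) {
  th <- utils::modifyList(regime_thresholds(), thresholds)
  if (th$rate_silent >= th$rate_hyper)
    stop("inconsistent thresholds: rate_silent must be below rate_hyper", call. = FALSE)
  if (stats$mean_rate < th$rate_silent) return("silent")
  if (stats$mean_rate >= th$rate_hyper && stats$participation >= th$participation_low)
    return("hyperactive")
  if (stats$participation < th$participation_low) return("skewed")
  "asynchronous"
}

#' @rdname classify_regime
#' @export
regime_thresholds <- function() {
  list(rate_silent = 0.5, rate_hyper = 50, participation_low = 0.5)
}

#' Summarize an executed ensemble run by run
#'
#' Reads each run's spike raster, computes [activity_stats()] over the
#' simulated window, and attaches a regime label.  Missing or failed
#' runs are kept as flagged rows, never dropped.
#'
#' @param manifest An `"ensemble_manifest"` (or a path readable by
#'   [read_manifest()]).
#' @param thresholds Regime thresholds, see [classify_regime()].
#' @param population Population prefix to analyze; default: the
#'   population with the largest final count in the first completed
#'   run.
#' @param window Analysis window in ms; default: the configured
#'   duration.
#' @return Data frame with one row per run: `run`, the parameter
#'   assignments, `status`, `mean_rate`, `participation`, `dispersion`,
#'   `regime`.  The number of distinct regimes is attached as attribute
#'   `"n_regimes"`.
#' @export
sweep_report <- function(manifest, thresholds = regime_thresholds(),
                         population = NULL, window = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  window <- window %||% (manifest$config$duration)
  runs <- manifest$runs
  if (is.null(population)) {
    for (r in runs)
      if (identical(r$status, "ok") && length(r$final_counts)) {
        fc <- unlist(r$final_counts)
        population <- names(fc)[which.max(fc)]
        break
      }
    if (is.null(population)) stop("no completed run to infer the population from", call. = FALSE)
  }
  rows <- lapply(runs, function(r) {
    base <- c(list(run = r$run), lapply(r$assignment, as.numeric))
    if (!identical(r$status, "ok")) {
      return(c(base, list(status = r$status, mean_rate = NA_real_,
                          participation = NA_real_, dispersion = NA_real_,
                          regime = NA_character_)))
    }
    raster <- utils::read.csv(file.path(manifest$out_dir, r$paths$raster))
    raster <- raster[raster$population == population, , drop = FALSE]
    n <- as.numeric(r$final_counts[[population]])
    st <- activity_stats(raster, window, n)
    c(base, list(status = "ok", mean_rate = st$mean_rate,
                 participation = st$participation, dispersion = st$dispersion,
                 regime = classify_regime(st, thresholds)))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "n_regimes") <- length(unique(stats::na.omit(out$regime)))
  attr(out, "population") <- population
  out
}
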