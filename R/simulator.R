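#' Simulation run settings
#'
#' @param n_steps Total number of integration steps (1 step = `dt` ms).
#' @param dt Step size in ms. The printed noise scales place the mean
#'   Poisson drive at the spiking boundary under 1 ms steps, so 1 is the
#'   intended value; other values are accepted for numerical experiments.
#' @param seed Integer seed for the run, or `NULL` to use the current RNG
#'   state.
#' @param burn_in Initial steps excluded from downstream state
#'   classification while the network settles. Defaults to 1000, reduced
#'   to half the run for short runs so the invariant `burn_in < n_steps`
#'   always holds.
#' @param record_voltages If `TRUE`, record the membrane potential of the
#'   first neuron of each population at every step.
#' @param store_spikes If `TRUE` (default), keep the individual spike
#'   events (step, population, neuron). Per-step population counts are
#'   always kept; long or large-N runs can set this to `FALSE` to bound
#'   memory.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_steps, dt = 1, seed = NULL,
                              burn_in = NULL, record_voltages = FALSE,
                              store_spikes = TRUE) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("n_steps must be >= 1")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(burn_in)) burn_in <- min(1000L, n_steps %/% 2L)
  burn_in <- as.integer(burn_in)
  if (is.na(burn_in) || burn_in < 0L) stop("burn_in must be >= 0")
  if (burn_in >= n_steps) stop("burn_in must be smaller than n_steps")
  structure(
    list(n_steps = n_steps, dt = dt, seed = seed, burn_in = burn_in,
         record_voltages = isTRUE(record_voltages),
         store_spikes = isTRUE(store_spikes)),
    class = "simulation_config"
  )
}

#' Run the three-population network forward in time
#'
#' Integrates every neuron with forward Euler. Each step: (1) per-population
#' spike counts from the previous step are size-normalised and weighted by
#' the signed wiring to give the synaptic current, applied uniformly to
#' every neuron of the target population; (2) leak and one fresh
#' per-neuron Poisson noise draw are added; (3) neurons crossing threshold
#' spike and reset to rest. Identical seed and configuration give a
#' bit-identical raster.
#'
#' @param config A [simulation_config()].
#' @param specs Named list of [population_spec()] objects for `WA`, `SA`
#'   and `WP`.
#' @param conn A [connectivity_matrix()].
#' @param constants A [membrane_constants()].
#' @return An object of class `"spike_raster"`: a list with `counts` (an
#'   `n_steps` x 3 integer matrix of per-step spike counts, columns
#'   `n_WA`, `n_SA`, `n_WP`), `spikes` (data frame `step`, `population`,
#'   `neuron_index`, or `NULL` when not stored), `voltages` (data frame or
#'   `NULL`), plus `dt`, `burn_in`, `sizes`, `seed` and the inputs used.
#' @examples
#' pre <- get_preset("n5-no-lc")
#' r <- run_simulation(simulation_config(5000, seed = 1),
#'                     pre$specs, pre$conn, pre$constants)
#' r
#' @export
run_simulation <- function(config, specs, conn,
                           constants = membrane_constants()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(conn, "connectivity_matrix"),
            inherits(constants, "membrane_constants"))
  if (!all(POPULATIONS %in% names(specs)))
    stop("specs must be a named list with elements WA, SA and WP")
  specs <- specs[POPULATIONS]
  for (sp in specs) stopifnot(inherits(sp, "population_spec"))

  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  signed <- unclass(conn) * .wiring_signs

  res <- .lif_simulate_cpp(
    n_steps = config$n_steps,
    sizes = vapply(specs, `[[`, integer(1), "size"),
    capacitance = vapply(specs, `[[`, numeric(1), "capacitance"),
    tau = vapply(specs, `[[`, numeric(1), "tau"),
    noise_scale = vapply(specs, `[[`, numeric(1), "noise_scale"),
    signed_s = signed,
    rmp = constants$rmp, threshold = constants$threshold, dt = config$dt,
    store_spikes = config$store_spikes,
    record_voltages = config$record_voltages
  )

  counts <- res$counts
  colnames(counts) <- paste0("n_", POPULATIONS)

  spikes <- NULL
  if (!is.null(res$events)) {
    spikes <- data.frame(
      step = res$events$step,
      population = POPULATIONS[res$events$pop],
      neuron_index = res$events$neuron,
      stringsAsFactors = FALSE
    )
  }
  voltages <- NULL
  if (!is.null(res$voltages)) {
    voltages <- data.frame(
      step = rep(seq_len(config$n_steps), 3L),
      population = rep(POPULATIONS, each = config$n_steps),
      neuron_index = 1L,
      voltage_mV = as.vector(res$voltages)
    )
  }

  structure(
    list(counts = counts, spikes = spikes, voltages = voltages,
         dt = config$dt, burn_in = config$burn_in,
         sizes = vapply(specs, `[[`, integer(1), "size"),
         seed = config$seed, specs = specs, conn = conn,
         constants = constants, n_steps = config$n_steps),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  tot <- colSums(x$counts)
  cat(sprintf("<spike_raster> %d steps of %g ms, N = (%s)\n",
              x$n_steps, x$dt, paste(x$sizes, collapse = ", ")))
  cat(sprintf("  total spikes: WA %d, SA %d, WP %d; burn-in %d steps\n",
              tot[1], tot[2], tot[3], x$burn_in))
  if (is.null(x$spikes)) cat("  per-neuron events not stored\n")
  invisible(x)
}

.window_steps <- function(raster, window) {
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[2] <= window[1])
    stop("window must be c(t0, t1) in ms with t1 > t0")
  from <- floor(window[1] / raster$dt) + 1L
  to <- ceiling(window[2] / raster$dt)
  if (from < 1L || to > raster$n_steps)
    stop("window extends beyond the raster")
  seq.int(from, to)
}

#' Mean firing rate per population over a time window
#'
#' @param raster A [run_simulation()] result.
#' @param window `c(t0, t1)`: half-open interval in ms.
#' @return Named numeric vector of rates in spikes per second per neuron.
#' @examples
#' # 227 spikes in 1000 ms over 5 neurons -> 45.4 spikes/s/neuron
#' @export
population_rates <- function(raster, window) {
  steps <- .window_steps(raster, window)
  secs <- (window[2] - window[1]) / 1000
  tot <- colSums(raster$counts[steps, , drop = FALSE])
  setNames(as.numeric(tot) / secs / raster$sizes, POPULATIONS)
}

# ---- delimited-text export/import ----------------------------------------

.meta_header <- function(raster) {
  c(sprintf("# dt_ms=%s", format(raster$dt)),
    sprintf("# n_steps=%d", raster$n_steps),
    sprintf("# burn_in=%d", raster$burn_in),
    sprintf("# sizes=%d,%d,%d", raster$sizes[1], raster$sizes[2],
            raster$sizes[3]))
}

#' Write per-step population spike counts to CSV
#'
#' Columns `step, n_WA, n_SA, n_WP`, preceded by `#` metadata lines
#' (dt, run length, burn-in, population sizes) so the file round-trips.
#'
#' @param raster A spike raster.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(raster), con)
  df <- data.frame(step = seq_len(raster$n_steps), raster$counts)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population spike-count CSV back into a raster
#'
#' The result carries counts only (`spikes = NULL`); it supports every
#' count-based analysis (state classification, bouts, rates).
#'
#' @param path File written by [write_counts_csv()].
#' @return A `"spike_raster"` object.
#' @export
read_counts_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- list(dt_ms = 1, n_steps = NA, burn_in = 0,
               sizes = c(NA_integer_, NA_integer_, NA_integer_))
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    if (kv[1] == "sizes") {
      meta$sizes <- as.integer(strsplit(kv[2], ",")[[1]])
    } else meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- read.csv(path, comment.char = "#")
  counts <- as.matrix(df[, c("n_WA", "n_SA", "n_WP")])
  if (any(is.na(meta$sizes)))
    meta$sizes <- apply(counts, 2, max)  # lower bound when absent
  structure(
    list(counts = counts, spikes = NULL, voltages = NULL,
         dt = meta$dt_ms, burn_in = as.integer(meta$burn_in),
         sizes = setNames(as.integer(meta$sizes), POPULATIONS),
         seed = NULL, specs = NULL, conn = NULL, constants = NULL,
         n_steps = nrow(counts)),
    class = "spike_raster"
  )
}

#' Write individual spike events to CSV
#'
#' One row per spike: `step, population, neuron_index`.
#'
#' @inheritParams write_counts_csv
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(raster, path) {
  if (is.null(raster$spikes))
    stop("this raster was run with store_spikes = FALSE")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(raster), con)
  write.csv(raster$spikes, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write recorded voltage traces to CSV
#'
#' Columns `step, population, neuron_index, voltage_mV`.
#'
#' @inheritParams write_counts_csv
#' @return `path`, invisibly.
#' @export
write_voltages_csv <- function(raster, path) {
  if (is.null(raster$voltages))
    stop("this raster was run with record_voltages = FALSE")
  df <- raster$voltages
  df$voltage_mV <- sprintf("%.10g", df$voltage_mV)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(raster), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
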