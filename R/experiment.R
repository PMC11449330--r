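.resolve_preset <- function(preset) {
  if (is.character(preset)) get_preset(preset) else {
    stopifnot(inherits(preset, "sleep_preset"))
    preset
  }
}

# simulate + classify + summarise; the shared core of run_experiment and
# sweep. Classification failures on degenerate runs (e.g. no strict
# spike-count majority in any window) are reported, not fatal.
.compute_summary <- function(preset, steps, seed, window_ms = 30,
                             store_spikes = FALSE, record_voltages = FALSE,
                             tail_fraction = 1.0) {
  preset <- .resolve_preset(preset)
  if (is.null(steps)) steps <- preset$recommended_steps
  config <- simulation_config(steps, seed = seed,
                              store_spikes = store_spikes,
                              record_voltages = record_voltages)
  raster <- run_simulation(config, preset$specs, preset$conn,
                           preset$constants)
  states <- tryCatch(classify_states(raster, window_ms),
                     error = function(e) e)
  out <- list(preset = preset$name, steps = config$n_steps,
              burn_in = config$burn_in, seed = seed,
              window_ms = window_ms, raster = raster)
  if (inherits(states, "error")) {
    out$note <- paste("state classification unavailable:",
                      conditionMessage(states))
    out$bouts <- NULL
    return(out)
  }
  out$states <- states
  out$bouts <- extract_bouts(states)
  out$stats <- bout_statistics(out$bouts)
  interior <- out$bouts[!out$bouts$censored, , drop = FALSE]
  wake_d <- interior$duration_ms[interior$state == "WAKE"]
  sleep_d <- interior$duration_ms[interior$state == "SLEEP"]
  if (length(wake_d) >= 2L && length(sleep_d) >= 2L)
    out$shapes <- tryCatch(shape_report(wake_d, sleep_d, tail_fraction),
                           error = function(e) NULL)
  if (length(wake_d) >= 1L && length(sleep_d) >= 1L)
    out$lc <- tryCatch(lc_rate_comparison(raster, states),
                       warning = function(w) {
                         res <- suppressWarnings(
                           lc_rate_comparison(raster, states))
                         res$note <- conditionMessage(w)
                         res
                       },
                       error = function(e) NULL)
  out
}

.summary_json_list <- function(res) {
  stats <- NULL
  if (!is.null(res$stats)) {
    stats <- lapply(seq_len(nrow(res$stats)), function(i) {
      r <- res$stats[i, ]
      list(state = r$state, n = r$n, mean_ms = r$mean_ms,
           sd_ms = r$sd_ms, max_ms = r$max_ms)
    })
    names(stats) <- res$stats$state
  }
  fits <- NULL
  if (!is.null(res$shapes)) {
    fits <- lapply(res$shapes[c("WAKE", "SLEEP")], function(f) {
      list(exp_rate = f$exp_rate, semilog_r2 = f$semilog_r2,
           loglog_slope = f$loglog_slope, loglog_r2 = f$loglog_r2,
           shape = f$shape)
    })
  }
  list(preset = res$preset, steps = res$steps, burn_in = res$burn_in,
       seed = res$seed, window_ms = res$window_ms,
       n_interior_bouts = if (is.null(res$bouts)) 0L
                          else sum(!res$bouts$censored),
       bout_statistics = stats,
       lc_rate_comparison = res$lc,
       distribution_fits = fits,
       note = res$note)
}

#' Run a full simulation-to-analysis experiment
#'
#' Simulates a preset, classifies behavioural states, extracts bouts and
#' writes the full analysis to `output_dir`: `counts.csv` (and
#' `spikes.csv`/`voltages.csv` when recorded), `bouts.csv`,
#' `survivor_wake.csv`/`survivor_sleep.csv`, `summary.json` and
#' `run_log.txt` with the seed and every resolved parameter. Re-running
#' with the same seed reproduces the outputs byte-identically.
#'
#' @param preset Preset name (see [preset_names()]) or a `"sleep_preset"`.
#' @param steps Simulation length in steps; default the preset's
#'   recommendation.
#' @param seed Integer RNG seed.
#' @param output_dir Directory for output files, created if needed;
#'   `NULL` skips all file output.
#' @param window_ms State-classification window (ms).
#' @param store_spikes,record_voltages Forwarded to [simulation_config()];
#'   spike events default to off here to bound file sizes on long runs.
#' @return The summary (bout statistics, LC rate comparison, distribution
#'   fits), invisibly, as a list of class `"experiment_summary"`.
#' @export
run_experiment <- function(preset, steps = NULL, seed = 1,
                           output_dir = NULL, window_ms = 30,
                           store_spikes = FALSE, record_voltages = FALSE) {
  res <- .compute_summary(preset, steps, seed, window_ms,
                          store_spikes, record_voltages)
  summary <- .summary_json_list(res)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    marker <- file.path(output_dir, "INCOMPLETE")
    file.create(marker)
    write_counts_csv(res$raster, file.path(output_dir, "counts.csv"))
    if (!is.null(res$raster$spikes))
      write_spikes_csv(res$raster, file.path(output_dir, "spikes.csv"))
    if (!is.null(res$raster$voltages))
      write_voltages_csv(res$raster, file.path(output_dir, "voltages.csv"))
    if (!is.null(res$bouts))
      write_bouts_csv(res$bouts, file.path(output_dir, "bouts.csv"))
    if (!is.null(res$shapes)) {
      write_survivor_csv(res$shapes$WAKE$curve,
                         file.path(output_dir, "survivor_wake.csv"))
      write_survivor_csv(res$shapes$SLEEP$curve,
                         file.path(output_dir, "survivor_sleep.csv"))
    }
    writeLines(
      jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null"),
      file.path(output_dir, "summary.json"))
    pre <- .resolve_preset(preset)
    kv <- .preset_kv(pre)
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("steps: %d", res$steps),
                 sprintf("burn_in: %d", res$burn_in),
                 sprintf("window_ms: %g", window_ms),
                 paste0(names(kv), ": ", unname(kv))),
               file.path(output_dir, "run_log.txt"))
    file.remove(marker)
  }
  invisible(structure(summary, class = "experiment_summary"))
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary> preset %s, %d steps, seed %s\n",
              x$preset, x$steps, format(x$seed)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  for (st in names(x$bout_statistics)) {
    s <- x$bout_statistics[[st]]
    cat(sprintf("  %-5s n = %4d  mean = %8.2f ms  sd = %8.2f  max = %g\n",
                st, s$n, s$mean_ms, s$sd_ms, s$max_ms))
  }
  if (!is.null(x$lc_rate_comparison))
    cat(sprintf("  LC rate wake/sleep: %.3g / %.3g (ratio %.3g)\n",
                x$lc_rate_comparison$wake_rate,
                x$lc_rate_comparison$sleep_rate,
                x$lc_rate_comparison$ratio))
  for (st in names(x$distribution_fits)) {
    f <- x$distribution_fits[[st]]
    cat(sprintf("  %-5s semilog R2 %.4f | loglog R2 %.4f -> %s\n",
                st, f$semilog_r2, f$loglog_r2, f$shape))
  }
  invisible(x)
}

.sweep_row <- function(value, seed, res) {
  g <- function(st, col) {
    if (is.null(res$stats)) return(NA_real_)
    r <- res$stats[res$stats$state == st, col]
    if (length(r) == 0L) NA_real_ else r
  }
  f <- function(st, col) {
    if (is.null(res$shapes)) return(NA_real_)
    res$shapes[[st]][[col]]
  }
  data.frame(
    value = value, seed = seed,
    sleep_n = g("SLEEP", "n"), sleep_mean_ms = g("SLEEP", "mean_ms"),
    sleep_sd_ms = g("SLEEP", "sd_ms"),
    wake_n = g("WAKE", "n"), wake_mean_ms = g("WAKE", "mean_ms"),
    wake_sd_ms = g("WAKE", "sd_ms"),
    wake_semilog_r2 = f("WAKE", "semilog_r2"),
    wake_loglog_r2 = f("WAKE", "loglog_r2"),
    sleep_semilog_r2 = f("SLEEP", "semilog_r2"),
    sleep_loglog_r2 = f("SLEEP", "loglog_r2")
  )
}

#' Sweep one numeric parameter over a set of values
#'
#' Runs one experiment per (value, seed) combination on top of a base
#' preset, replacing the parameter at `parameter_path` (see
#' [preset_with()]; `conn.mutual_inhibition` scales both reciprocal WA-SA
#' strengths together).
#'
#' @param preset Base preset name or object.
#' @param parameter_path Dotted path of the numeric field to vary.
#' @param values Numeric vector of replacement values.
#' @param steps Steps per run; default the preset's recommendation.
#' @param seeds Integer vector of seeds (one run per seed per value).
#' @param window_ms State-classification window (ms).
#' @return List of class `"sweep_result"`: `runs` (one row per value and
#'   seed: bout counts, means, SDs and distribution R-squareds) and
#'   `summary` (per value: across-seed mean and SD of the per-state mean
#'   bout lengths).
#' @export
sweep <- function(preset, parameter_path, values, steps = NULL, seeds = 1,
                  window_ms = 30) {
  preset <- .resolve_preset(preset)
  if (length(values) < 1L) stop("values must be non-empty")
  rows <- list()
  for (v in values) {
    pre_v <- preset_with(preset, parameter_path, v)
    for (s in seeds) {
      res <- .compute_summary(pre_v, steps, s, window_ms)
      rows[[length(rows) + 1L]] <- .sweep_row(v, s, res)
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$value), function(d) {
    data.frame(value = d$value[1], n_seeds = nrow(d),
               sleep_mean_ms = mean(d$sleep_mean_ms),
               sleep_mean_sd = sd_or_zero(d$sleep_mean_ms),
               wake_mean_ms = mean(d$wake_mean_ms),
               wake_mean_sd = sd_or_zero(d$wake_mean_ms))
  }))
  summ <- summ[order(summ$value), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(parameter_path = parameter_path, runs = runs,
                 summary = summ),
            class = "sweep_result")
}

sd_or_zero <- function(x) if (length(x) < 2L) 0 else sd(x)

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over %d value(s)\n",
              x$parameter_path, nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
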