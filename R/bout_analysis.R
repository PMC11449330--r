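#' Classify each step as WAKE or SLEEP
#'
#' The behavioural state at step t is decided by a trailing sliding window:
#' whichever of the wake-active and sleep-active populations fired more
#' spikes over `(t - window, t]` is the active one. Ties keep the previous
#' label; the first label is set by the first strict majority and earlier
#' in-window steps inherit it. Wake-promoting spikes never enter the
#' classification. The raster's burn-in steps are excluded.
#'
#' @param raster A [run_simulation()] result (counts are sufficient).
#' @param window_ms Sliding-window length in ms (default 30).
#' @return An object of class `"state_sequence"`: character labels
#'   (`"WAKE"`/`"SLEEP"`), one per analysed step, with the raster step
#'   index of the first label in `start_step` and `window_ms`, `dt`.
#' @export
classify_states <- function(raster, window_ms = 30) {
  stopifnot(inherits(raster, "spike_raster"))
  w <- as.integer(round(window_ms / raster$dt))
  if (w < 1L) stop("window_ms must cover at least one step")
  region <- seq.int(raster$burn_in + 1L, raster$n_steps)
  if (length(region) <= w)
    stop("raster (after burn-in) is shorter than the classification window")

  wa <- raster$counts[region, "n_WA"]
  sa <- raster$counts[region, "n_SA"]
  cw <- cumsum(wa); cs <- cumsum(sa)
  L <- length(region)
  idx <- seq.int(w, L)
  wwa <- cw[idx] - c(0, cw)[idx - w + 1L]
  wsa <- cs[idx] - c(0, cs)[idx - w + 1L]
  raw <- sign(wwa - wsa)

  nz <- which(raw != 0)
  if (length(nz) == 0L)
    stop("no strict spike-count majority in any window; states undefined")
  # ties inherit the previous label; leading ties inherit the first majority
  filled <- raw
  filled[seq_len(nz[1] - 1L)] <- raw[nz[1]]
  keep <- filled != 0
  filled <- cummax_label(filled, keep)

  structure(
    list(labels = ifelse(filled > 0, "WAKE", "SLEEP"),
         start_step = raster$burn_in + w,
         window_ms = window_ms, dt = raster$dt),
    class = "state_sequence"
  )
}

# forward-fill zeros with the last non-zero value (vectorised)
cummax_label <- function(x, keep) {
  pos <- which(keep)
  x[pos][cumsum(keep)]
}

#' @export
print.state_sequence <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("WAKE", "SLEEP")))
  cat(sprintf("<state_sequence> %d labelled steps (%g ms window): %d WAKE, %d SLEEP\n",
              length(x$labels), x$window_ms, tab["WAKE"], tab["SLEEP"]))
  invisible(x)
}

#' Extract bouts from a state sequence
#'
#' A bout is a maximal run of one behavioural state. The first and last
#' runs are truncated by the analysis window, so their true durations are
#' unknown: they are returned flagged `censored = TRUE` and excluded from
#' [bout_statistics()].
#'
#' @param states A [classify_states()] result, or a plain character vector
#'   of `"WAKE"`/`"SLEEP"` labels (then `dt` = 1 ms and start 0 assumed).
#' @return A data frame with columns `state`, `start_ms`, `duration_ms`,
#'   `censored`; consecutive rows alternate states and durations sum to
#'   the labelled interval.
#' @examples
#' extract_bouts(c("WAKE", "WAKE", "SLEEP", "SLEEP", "SLEEP", "WAKE",
#'                 "WAKE", "WAKE", "SLEEP"))
#' @export
extract_bouts <- function(states) {
  if (is.character(states))
    states <- structure(list(labels = states, start_step = 1L,
                             window_ms = NA, dt = 1),
                        class = "state_sequence")
  stopifnot(inherits(states, "state_sequence"))
  lab <- states$labels
  if (length(lab) == 0L) stop("empty state sequence")
  r <- rle(lab)
  n <- length(r$lengths)
  start_steps <- states$start_step + c(0L, cumsum(r$lengths))[seq_len(n)]
  censored <- rep(FALSE, n)
  censored[c(1L, n)] <- TRUE  # n == 1 -> the single run is censored
  data.frame(
    state = r$values,
    start_ms = (start_steps - 1L) * states$dt,
    duration_ms = r$lengths * states$dt,
    censored = censored,
    stringsAsFactors = FALSE
  )
}

#' Summary statistics of interior bout durations
#'
#' @param bouts Data frame from [extract_bouts()].
#' @return Data frame with one row per state that has at least one interior
#'   (uncensored) bout: `state`, `n`, `mean_ms`, `sd_ms` (population
#'   standard deviation), `max_ms`. States without interior bouts are
#'   absent, not zero.
#' @export
bout_statistics <- function(bouts) {
  interior <- bouts[!bouts$censored, , drop = FALSE]
  out <- lapply(c("WAKE", "SLEEP"), function(st) {
    d <- interior$duration_ms[interior$state == st]
    if (length(d) == 0L) return(NULL)
    data.frame(state = st, n = length(d), mean_ms = mean(d),
               sd_ms = sqrt(mean((d - mean(d))^2)), max_ms = max(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

.state_steps <- function(raster, states, label) {
  i <- which(states$labels == label)
  states$start_step + i - 1L
}

#' Wake versus sleep firing rate of the wake-promoting population
#'
#' Computes the WP (locus coeruleus) spike rate separately over all
#' wake-labelled and all sleep-labelled steps, in spikes per second per
#' neuron, and their ratio. In the developed network the WP population
#' fires substantially faster during wake.
#'
#' @param raster The raster the states were classified from.
#' @param states A [classify_states()] result.
#' @return List with `wake_rate`, `sleep_rate` (spikes/s/neuron) and
#'   `ratio` = wake/sleep. A sleep rate of zero gives an infinite ratio
#'   with a warning.
#' @export
lc_rate_comparison <- function(raster, states) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(states, "state_sequence"))
  rate <- function(label) {
    steps <- .state_steps(raster, states, label)
    if (length(steps) == 0L)
      stop("no ", label, "-labelled steps in this sequence")
    sum(raster$counts[steps, "n_WP"]) /
      (length(steps) * raster$dt / 1000) / raster$sizes[["WP"]]
  }
  wr <- rate("WAKE"); sr <- rate("SLEEP")
  if (sr == 0) {
    warning("no WP spikes during sleep-labelled time; ratio is infinite")
    ratio <- Inf
  } else ratio <- wr / sr
  list(wake_rate = wr, sleep_rate = sr, ratio = ratio)
}

#' Representative per-bout wake-promoting firing rates
#'
#' For each interior bout of a state lasting at least `bout_window_ms`,
#' counts WP spikes over the first `bout_window_ms` of the bout and
#' converts to spikes per second per neuron; the representative rate is
#' the median across such bouts.
#'
#' @param raster The raster the states were classified from.
#' @param states A [classify_states()] result.
#' @param bout_window_ms Sample length taken from each qualifying bout.
#' @return List with `wake_rate` and `sleep_rate` (spikes/s/neuron);
#'   `NA` for a state with no qualifying bout.
#' @export
representative_lc_rates <- function(raster, states, bout_window_ms = 1000) {
  bouts <- extract_bouts(states)
  rep_rate <- function(label) {
    b <- bouts[!bouts$censored & bouts$state == label &
                 bouts$duration_ms >= bout_window_ms, , drop = FALSE]
    if (nrow(b) == 0L) return(NA_real_)
    w <- as.integer(round(bout_window_ms / raster$dt))
    counts <- vapply(seq_len(nrow(b)), function(i) {
      s0 <- as.integer(b$start_ms[i] / raster$dt) + 1L
      sum(raster$counts[s0:(s0 + w - 1L), "n_WP"])
    }, numeric(1))
    median(counts) / (bout_window_ms / 1000) / raster$sizes[["WP"]]
  }
  list(wake_rate = rep_rate("WAKE"), sleep_rate = rep_rate("SLEEP"))
}

#' Write a bout table to CSV
#'
#' Columns `state, start_ms, duration_ms, censored`.
#'
#' @param bouts Data frame from [extract_bouts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bouts_csv <- function(bouts, path) {
  write.csv(bouts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
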