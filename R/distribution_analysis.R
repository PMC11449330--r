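#' Empirical survivor curve of bout durations
#'
#' At every distinct observed duration t, survival = P(T >= t) =
#' (number of durations >= t) / n. The curve is non-increasing and equals
#' 1 at the smallest observed duration. Exponential duration distributions
#' are linear on semi-log axes; power laws are linear on log-log axes.
#'
#' @param durations Positive durations (ms), length >= 2.
#' @return Data frame of class `"survivor_curve"` with columns `duration`
#'   (sorted, distinct) and `survival`.
#' @examples
#' survivor_curve(c(1, 2, 2, 5))
#' @export
survivor_curve <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) < 2L) stop("need at least 2 durations")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be finite and > 0")
  t <- sort(unique(durations))
  n <- length(durations)
  surv <- vapply(t, function(ti) sum(durations >= ti) / n, numeric(1))
  structure(data.frame(duration = t, survival = surv),
            class = c("survivor_curve", "data.frame"))
}

#' Plot a survivor curve on semi-log or log-log axes
#'
#' @param x A [survivor_curve()].
#' @param scale `"semilog"` (log survival vs duration; an exponential is a
#'   straight line) or `"loglog"` (log survival vs log duration; a power
#'   law is a straight line).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.survivor_curve <- function(x, scale = c("semilog", "loglog"), ...) {
  scale <- match.arg(scale)
  log_axes <- if (scale == "semilog") "y" else "xy"
  graphics::plot(x$duration, x$survival, log = log_axes,
                 xlab = "bout duration (ms)", ylab = "P(T >= t)", ...)
  invisible(x)
}

.ols_r2 <- function(xv, yv) {
  fit <- lm(yv ~ xv)
  sse <- sum(fit$residuals^2)
  sst <- sum((yv - mean(yv))^2)
  list(slope = unname(coef(fit)[2]),
       r2 = if (sst == 0) NA_real_ else 1 - sse / sst)
}

#' Maximum-likelihood exponential fit with a semi-log linearity diagnostic
#'
#' The rate is the ML estimate for an exponential sample, `1 / mean`. The
#' diagnostic regresses log empirical survival on duration over the
#' survivor curve's support: an exponential sample gives a nearly perfect
#' linear fit (R-squared near 1), a heavy-tailed sample a visibly poorer
#' one.
#'
#' @param durations Positive durations (ms); intended for samples of at
#'   least 10, accepted down to 2.
#' @return List with `rate` (1/ms) and `semilog_r2` (`NA` for degenerate,
#'   all-equal input).
#' @examples
#' fit_exponential(c(2, 4))$rate  # 1/3
#' @export
fit_exponential <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) < 2L) stop("need at least 2 durations")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be finite and > 0")
  rate <- 1 / mean(durations)
  curve <- NULL
  r2 <- NA_real_
  if (length(unique(durations)) >= 2L) {
    curve <- survivor_curve(durations)
    r2 <- .ols_r2(curve$duration, log(curve$survival))$r2
  }
  list(rate = rate, semilog_r2 = r2)
}

#' Log-log linearity diagnostic of a survivor curve
#'
#' Ordinary least squares of log survival on log duration over the upper
#' `tail_fraction` of the curve's points. A heavy (power-law-like) tail is
#' close to linear with negative slope; an exponential curves downward.
#'
#' @param curve A [survivor_curve()].
#' @param tail_fraction Fraction (0, 1] of the largest-duration points to
#'   fit; default 1 uses the whole curve.
#' @return List with `slope` and `loglog_r2`.
#' @examples
#' s <- structure(data.frame(duration = 1:100, survival = (1:100)^-2),
#'                class = c("survivor_curve", "data.frame"))
#' loglog_linearity(s)  # slope -2, r2 = 1
#' @export
loglog_linearity <- function(curve, tail_fraction = 1.0) {
  stopifnot(inherits(curve, "survivor_curve"))
  if (!is.finite(tail_fraction) || tail_fraction <= 0 || tail_fraction > 1)
    stop("tail_fraction must be in (0, 1]")
  np <- nrow(curve)
  k <- ceiling(tail_fraction * np)
  sel <- curve[seq.int(np - k + 1L, np), , drop = FALSE]
  if (nrow(sel) < 3L)
    stop("fewer than 3 points in the selected tail")
  fit <- .ols_r2(log(sel$duration), log(sel$survival))
  list(slope = fit$slope, loglog_r2 = fit$r2)
}

.fd_histogram <- function(durations) {
  h <- graphics::hist(durations, breaks = "FD", plot = FALSE)
  data.frame(bin_left = h$breaks[-length(h$breaks)],
             bin_right = h$breaks[-1], count = h$counts)
}

.state_fit <- function(durations, tail_fraction) {
  fe <- fit_exponential(durations)
  curve <- survivor_curve(durations)
  ll <- if (nrow(curve) >= 3L)
    loglog_linearity(curve, tail_fraction)
  else list(slope = NA_real_, loglog_r2 = NA_real_)
  shape <- if (is.na(fe$semilog_r2) || is.na(ll$loglog_r2)) {
    NA_character_
  } else if (ll$loglog_r2 > fe$semilog_r2) {
    "power-law-like"   # heavy tails may also be exponential mixtures
  } else "exponential-like"
  list(exp_rate = fe$rate, semilog_r2 = fe$semilog_r2,
       loglog_slope = ll$slope, loglog_r2 = ll$loglog_r2, shape = shape,
       curve = curve, histogram = .fd_histogram(durations))
}

#' Distribution-shape report for wake and sleep bout durations
#'
#' For each state: Freedman-Diaconis histogram counts, the ML exponential
#' rate with its semi-log linearity R-squared, the log-log slope and
#' R-squared of the survivor curve, and a shape label. The label is
#' `"power-law-like"` (never a power-law claim: mixtures of exponentials
#' can be log-log linear too) when the log-log fit is the more linear,
#' otherwise `"exponential-like"`.
#'
#' @param wake_durations,sleep_durations Interior bout durations (ms).
#' @param tail_fraction Passed to [loglog_linearity()].
#' @return List of class `"shape_report"` with elements `WAKE` and
#'   `SLEEP`, each carrying `exp_rate`, `semilog_r2`, `loglog_slope`,
#'   `loglog_r2`, `shape`, the survivor `curve` and the `histogram` table.
#' @export
shape_report <- function(wake_durations, sleep_durations,
                         tail_fraction = 1.0) {
  if (length(wake_durations) == 0L || length(sleep_durations) == 0L)
    stop("both states need at least one duration")
  structure(
    list(WAKE = .state_fit(wake_durations, tail_fraction),
         SLEEP = .state_fit(sleep_durations, tail_fraction)),
    class = "shape_report"
  )
}

#' @export
print.shape_report <- function(x, ...) {
  cat("<shape_report>\n")
  for (st in c("WAKE", "SLEEP")) {
    f <- x[[st]]
    cat(sprintf(
      "  %-5s rate = %.5g /ms | semilog R2 = %.4f | loglog R2 = %.4f (slope %.3g) -> %s\n",
      st, f$exp_rate, f$semilog_r2, f$loglog_r2, f$loglog_slope, f$shape))
  }
  invisible(x)
}

#' Write a survivor curve to CSV
#'
#' @param curve A [survivor_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survivor_csv <- function(curve, path) {
  df <- data.frame(duration_ms = curve$duration,
                   survival = sprintf("%.10g", curve$survival))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
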