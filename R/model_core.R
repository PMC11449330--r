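#' @useDynLib somnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois sd median lm aggregate setNames coef
#' @importFrom utils read.csv write.csv head tail
NULL

POPULATIONS <- c("WA", "SA", "WP")

# Fixed wiring signs of the three-population switch: wake-active (WA) and
# sleep-active (SA) mutually inhibit and self-excite; the wake-promoting
# locus coeruleus (WP) excites WA and is excited by WA, inhibited by SA,
# self-excites, and sends nothing to SA. Rows = source, cols = target.
.wiring_signs <- matrix(
  c( 1, -1,  1,
    -1,  1, -1,
     1,  0,  1),
  nrow = 3, byrow = TRUE,
  dimnames = list(POPULATIONS, POPULATIONS)
)

.norm_pop <- function(name) {
  name <- toupper(as.character(name))
  name[name == "LC"] <- "WP"
  if (!all(name %in% POPULATIONS)) {
    stop("unknown population name(s): ",
         paste(setdiff(name, POPULATIONS), collapse = ", "),
         " (expected WA, SA or WP/LC)", call. = FALSE)
  }
  name
}

#' Describe one neuron population
#'
#' Bundles the size, membrane constants and Poisson-noise multiplier of a
#' population of identical leaky integrate-and-fire neurons.
#'
#' @param name Population identifier: `"WA"` (wake-active), `"SA"`
#'   (sleep-active) or `"WP"` (wake-promoting locus coeruleus; `"LC"` is
#'   accepted as a synonym).
#' @param size Number of neurons (>= 1).
#' @param capacitance Membrane capacitance factor C (dimensionless as used
#'   here); scales the leak current.
#' @param tau Membrane time constant (ms) governing decay back to rest.
#' @param noise_scale Multiplier p applied to each neuron's per-step
#'   Poisson(1) noise draw (mV/ms per event); `0` disables noise.
#' @return An object of class `"population_spec"`.
#' @examples
#' population_spec("WA", size = 5, noise_scale = 1.05)
#' @export
population_spec <- function(name, size, capacitance = 1, tau = 15,
                            noise_scale = 0) {
  name <- .norm_pop(name)
  stopifnot(length(name) == 1L, length(size) == 1L)
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("size must be a positive integer")
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (!is.finite(capacitance) || capacitance <= 0)
    stop("capacitance must be > 0")
  if (!is.finite(noise_scale) || noise_scale < 0)
    stop("noise_scale must be >= 0")
  structure(
    list(name = name, size = size, capacitance = capacitance,
         tau = tau, noise_scale = noise_scale),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s: N = %d, C = %g, tau = %g ms, p = %g\n",
              x$name, x$size, x$capacitance, x$tau, x$noise_scale))
  invisible(x)
}

#' Signed synaptic wiring of the three-population network
#'
#' Stores the non-negative synaptic strengths s_XY for every ordered pair of
#' populations. The excitatory/inhibitory sign of each connection is fixed
#' structurally (it is applied when currents are summed, not stored):
#' self-connections and the reciprocal WA-WP coupling are excitatory, the
#' WA-SA reciprocal coupling and SA->WP are inhibitory, and WP->SA is
#' absent, so its strength must be zero.
#'
#' @param wa_wa,sa_sa,wp_wp Self-excitation strengths.
#' @param wa_sa,sa_wa Mutual-inhibition strengths between the wake- and
#'   sleep-active populations.
#' @param wa_wp,wp_wa Reciprocal excitation between the wake-active and
#'   wake-promoting populations.
#' @param sa_wp Inhibition of the wake-promoting population by the
#'   sleep-active population.
#' @return A 3x3 numeric matrix of class `"connectivity_matrix"` with
#'   rows = source population and columns = target population.
#' @examples
#' connectivity_matrix(wa_wa = 6, sa_sa = 6, wa_sa = 24, sa_wa = 24)
#' @export
connectivity_matrix <- function(wa_wa = 0, wa_sa = 0, wa_wp = 0,
                                sa_wa = 0, sa_sa = 0, sa_wp = 0,
                                wp_wa = 0, wp_wp = 0) {
  m <- matrix(0, 3, 3, dimnames = list(POPULATIONS, POPULATIONS))
  m["WA", "WA"] <- wa_wa; m["WA", "SA"] <- wa_sa; m["WA", "WP"] <- wa_wp
  m["SA", "WA"] <- sa_wa; m["SA", "SA"] <- sa_sa; m["SA", "WP"] <- sa_wp
  m["WP", "WA"] <- wp_wa; m["WP", "WP"] <- wp_wp
  validate_connectivity(m)
}

validate_connectivity <- function(m) {
  stopifnot(is.matrix(m), dim(m) == c(3L, 3L))
  dimnames(m) <- list(POPULATIONS, POPULATIONS)
  if (any(!is.finite(m)) || any(m < 0))
    stop("synaptic strengths must be finite and >= 0 (signs are structural)")
  if (m["WP", "SA"] != 0)
    stop("the WP->SA connection is absent; its strength must be 0")
  class(m) <- c("connectivity_matrix", "matrix", "array")
  m
}

#' Look up one synaptic strength
#'
#' @param conn A [connectivity_matrix()].
#' @param src,tgt Source and target population names (`"LC"` is accepted
#'   for `"WP"`).
#' @return The stored non-negative strength.
#' @export
conn_strength <- function(conn, src, tgt) {
  unname(conn[.norm_pop(src), .norm_pop(tgt)])
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> strengths (source -> target), signs structural:\n")
  print(unclass(x))
  invisible(x)
}

#' Resting and threshold membrane potentials
#'
#' @param rmp Resting membrane potential V0 (mV).
#' @param threshold Spike threshold (mV); must exceed `rmp`.
#' @return An object of class `"membrane_constants"`.
#' @export
membrane_constants <- function(rmp = -70, threshold = -55) {
  if (!is.finite(rmp) || !is.finite(threshold) || threshold <= rmp)
    stop("threshold must be finite and greater than rmp")
  structure(list(rmp = rmp, threshold = threshold),
            class = "membrane_constants")
}

#' Leak current toward the resting potential
#'
#' I_leak = -(C/tau) (v - V0): zero at rest, opposing any displacement.
#'
#' @param voltage Membrane potential (mV); may be a vector.
#' @param spec A [population_spec()] supplying C and tau.
#' @param constants A [membrane_constants()] supplying V0.
#' @return Current in mV/ms, same length as `voltage`.
#' @examples
#' sp <- population_spec("WA", 5)
#' leak_current(-40, sp, membrane_constants())  # -2 mV/ms
#' @export
leak_current <- function(voltage, spec, constants = membrane_constants()) {
  if (any(!is.finite(voltage)))
    stop("non-finite membrane voltage: invalid neuron state")
  -(spec$capacitance / spec$tau) * (voltage - constants$rmp)
}

#' Synaptic current into one population
#'
#' Sums the size-normalised previous-step spike counts of each source
#' population, weighted by the stored strengths and the structural signs:
#' into WA, `+self +WP -SA`; into SA, `+self -WA` (no WP term); into WP,
#' `+self +WA -SA`.
#'
#' @param target Target population name.
#' @param activity Named integer vector `c(WA=, SA=, WP=)` of current
#'   per-population spike counts.
#' @param conn A [connectivity_matrix()].
#' @param specs Named list of [population_spec()] for WA, SA, WP (supplies
#'   the population sizes N used for normalisation).
#' @return Current in mV/ms.
#' @examples
#' specs <- lapply(c("WA", "SA", "WP"), population_spec, size = 5)
#' names(specs) <- c("WA", "SA", "WP")
#' conn <- connectivity_matrix(wa_wa = 6, sa_sa = 6, wa_sa = 24, sa_wa = 24,
#'                             wp_wa = 4, wa_wp = 3, sa_wp = 3, wp_wp = 2)
#' synaptic_current("WA", c(WA = 2, SA = 3, WP = 1), conn, specs)
#' @export
synaptic_current <- function(target, activity, conn, specs) {
  target <- .norm_pop(target)
  act <- activity[POPULATIONS]
  sizes <- vapply(specs[POPULATIONS], `[[`, integer(1), "size")
  if (any(is.na(act)) || any(act < 0) || any(act > sizes))
    stop("activity counts must satisfy 0 <= count <= population size")
  sum(.wiring_signs[, target] * conn[, target] * act / sizes)
}

#' Per-neuron Poisson noise current
#'
#' One independent Poisson(mean 1) event-count draw per neuron per step,
#' scaled by the population's `noise_scale`. Models excitatory spikes
#' arriving from outside the network.
#'
#' @param spec A [population_spec()].
#' @param n Number of independent draws.
#' @return Numeric vector of currents (mV/ms).
#' @export
poisson_drive <- function(spec, n = 1) {
  spec$noise_scale * rpois(n, 1)
}

#' One forward-Euler update of a single neuron
#'
#' Candidate voltage = v + dt * current; crossing the threshold registers a
#' spike and resets the voltage to rest in the same step. There is no
#' refractory period and no lower clamp (hyperpolarisation is allowed).
#'
#' @param state List with elements `voltage` (mV) and `spiked` (logical).
#' @param total_current Net current (mV/ms): leak + synaptic + noise.
#' @param dt Step size (ms).
#' @param constants A [membrane_constants()].
#' @return Updated state list.
#' @examples
#' step_neuron(list(voltage = -56, spiked = FALSE), 1, 1)
#' @export
step_neuron <- function(state, total_current, dt = 1,
                        constants = membrane_constants()) {
  if (!is.finite(total_current))
    stop("non-finite input current: invalid neuron state")
  if (dt <= 0) stop("dt must be > 0")
  cand <- state$voltage + dt * total_current
  if (cand >= constants$threshold) {
    list(voltage = constants$rmp, spiked = TRUE)
  } else {
    list(voltage = cand, spiked = FALSE)
  }
}
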