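# Independent reference implementations used as oracles. They share only
# the model definition with the package, not its code paths: the
# simulator is a plain R loop, the classifier recounts every window, the
# bout scanner re-scans every run, the survivor curve recounts every
# duration.

POPS <- c("WA", "SA", "WP")

wiring_signs_ref <- matrix(
  c( 1, -1,  1,
    -1,  1, -1,
     1,  0,  1),
  nrow = 3, byrow = TRUE, dimnames = list(POPS, POPS))

# slow per-neuron forward-Euler loop with the same RNG consumption order
# (population-major, neuron-minor, all draws before any update)
ref_simulate <- function(n_steps, specs, conn, constants, dt = 1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- unclass(conn) * wiring_signs_ref
  sizes <- vapply(specs[POPS], `[[`, integer(1), "size")
  v <- lapply(sizes, function(n) rep(constants$rmp, n))
  sigma <- c(WA = 0, SA = 0, WP = 0)
  counts <- matrix(0L, n_steps, 3,
                   dimnames = list(NULL, paste0("n_", POPS)))
  volt1 <- matrix(NA_real_, n_steps, 3, dimnames = list(NULL, POPS))
  for (t in seq_len(n_steps)) {
    noise <- lapply(POPS, function(p)
      specs[[p]]$noise_scale * rpois(sizes[[p]], 1))
    names(noise) <- POPS
    for (p in POPS) {
      spec <- specs[[p]]
      base <- sum(s[, p] * sigma / sizes)
      nsp <- 0L
      for (i in seq_len(sizes[[p]])) {
        cur <- -(spec$capacitance / spec$tau) *
          (v[[p]][i] - constants$rmp) + base + noise[[p]][i]
        cand <- v[[p]][i] + dt * cur
        if (cand >= constants$threshold) {
          v[[p]][i] <- constants$rmp
          nsp <- nsp + 1L
        } else v[[p]][i] <- cand
      }
      counts[t, paste0("n_", p)] <- nsp
      volt1[t, p] <- v[[p]][1]
    }
    sigma <- c(counts[t, 1], counts[t, 2], counts[t, 3])
    names(sigma) <- POPS
  }
  list(counts = counts, volt1 = volt1)
}

# recount every window explicitly; same tie rule (keep previous label,
# leading steps take the first strict majority)
ref_classify <- function(counts, burn_in, w) {
  region <- seq.int(burn_in + 1L, nrow(counts))
  wa <- counts[region, 1]
  sa <- counts[region, 2]
  L <- length(region)
  raw <- integer(L - w + 1L)
  for (t in seq.int(w, L))
    raw[t - w + 1L] <- sign(sum(wa[(t - w + 1L):t]) -
                            sum(sa[(t - w + 1L):t]))
  lab <- raw
  for (i in seq_along(lab))
    if (lab[i] == 0L && i > 1L) lab[i] <- lab[i - 1L]
  nz <- which(lab != 0L)
  if (length(nz) == 0L) return(NULL)
  if (nz[1] > 1L) lab[seq_len(nz[1] - 1L)] <- lab[nz[1]]
  ifelse(lab > 0L, "WAKE", "SLEEP")
}

# re-scan every run of equal labels
ref_bouts <- function(labels) {
  n <- length(labels)
  starts <- c(1L, which(labels[-1L] != labels[-n]) + 1L)
  ends <- c(starts[-1L] - 1L, n)
  data.frame(state = labels[starts], len = ends - starts + 1L,
             stringsAsFactors = FALSE)
}

ref_survivor <- function(durations) {
  t <- sort(unique(durations))
  data.frame(duration = t,
             survival = vapply(t, function(ti)
               mean(durations >= ti), numeric(1)))
}

make_specs <- function(n, p_wa = 1.05, p_sa = 1.05, p_wp = 1.0) {
  list(WA = population_spec("WA", n, noise_scale = p_wa),
       SA = population_spec("SA", n, noise_scale = p_sa),
       WP = population_spec("WP", n, noise_scale = p_wp))
}

# hand-made raster with prescribed per-step counts (for classifier and
# rate tests); counts is an n x 3 matrix
fake_raster <- function(counts, sizes = c(WA = 5L, SA = 5L, WP = 5L),
                        dt = 1, burn_in = 0L) {
  colnames(counts) <- paste0("n_", POPS)
  structure(
    list(counts = counts, spikes = NULL, voltages = NULL, dt = dt,
         burn_in = as.integer(burn_in), sizes = sizes, seed = NULL,
         specs = NULL, conn = NULL, constants = NULL,
         n_steps = nrow(counts)),
    class = "spike_raster")
}
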