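test_that("leak current opposes displacement from rest and vanishes there", {
  sp <- population_spec("WA", 5, capacitance = 1, tau = 15)
  mc <- membrane_constants(-70, -55)
  expect_equal(leak_current(-70, sp, mc), 0)
  expect_equal(leak_current(-40, sp, mc), -2)
  expect_equal(leak_current(-85, sp, mc), 1)
  expect_error(leak_current(NaN, sp, mc), "non-finite")
})

test_that("population and connectivity constructors enforce invariants", {
  expect_error(population_spec("WA", 0), "positive")
  expect_error(population_spec("WA", 5, tau = 0), "tau")
  expect_error(population_spec("WA", 5, noise_scale = -1), "noise_scale")
  expect_error(population_spec("XX", 5), "unknown population")
  expect_error(membrane_constants(-55, -70), "greater than rmp")
  expect_error(connectivity_matrix(wa_wa = -1), ">= 0")
  # the WP->SA connection is structurally absent
  m <- unclass(connectivity_matrix())
  m["WP", "SA"] <- 2
  expect_error(somnet:::validate_connectivity(m), "WP->SA")
  # LC is accepted as a synonym for WP
  conn <- connectivity_matrix(wp_wa = 4)
  expect_equal(conn_strength(conn, "LC", "WA"), 4)
})

test_that("synaptic current follows the signed wiring", {
  specs <- make_specs(5)
  conn <- connectivity_matrix(wa_wa = 6, sa_sa = 6, wa_sa = 24, sa_wa = 24,
                              wp_wa = 4, wa_wp = 3, sa_wp = 3, wp_wp = 2)
  # +self +WP -SA into WA: 6*2/5 + 4*1/5 - 24*3/5
  expect_equal(synaptic_current("WA", c(WA = 2, SA = 3, WP = 1), conn, specs),
               -11.2)
  # the SA equation carries no WP term
  for (wp in 0:5)
    expect_equal(
      synaptic_current("SA", c(WA = 0, SA = 0, WP = wp), conn, specs), 0)
  # no spikes, no current
  for (tgt in c("WA", "SA", "WP"))
    expect_equal(
      synaptic_current(tgt, c(WA = 0, SA = 0, WP = 0), conn, specs), 0)
  expect_error(
    synaptic_current("WA", c(WA = 6, SA = 0, WP = 0), conn, specs),
    "population size")
})

test_that("synaptic current matches per-edge brute force on small networks", {
  set.seed(11)
  for (rep in 1:5) {
    sizes <- sample(1:3, 3, replace = TRUE)
    specs <- list(WA = population_spec("WA", sizes[1]),
                  SA = population_spec("SA", sizes[2]),
                  WP = population_spec("WP", sizes[3]))
    vals <- round(runif(8, 0, 30), 2)
    conn <- connectivity_matrix(wa_wa = vals[1], wa_sa = vals[2],
                                wa_wp = vals[3], sa_wa = vals[4],
                                sa_sa = vals[5], sa_wp = vals[6],
                                wp_wa = vals[7], wp_wp = vals[8])
    grid <- expand.grid(WA = 0:sizes[1], SA = 0:sizes[2], WP = 0:sizes[3])
    for (k in seq_len(nrow(grid))) {
      act <- unlist(grid[k, ])
      for (tgt in c("WA", "SA", "WP")) {
        # per-edge oracle: every spiking source neuron contributes one
        # unit of sign * s / N_src to each target neuron
        expected <- 0
        for (src in c("WA", "SA", "WP")) {
          w <- wiring_signs_ref[src, tgt] * unclass(conn)[src, tgt] /
            specs[[src]]$size
          expected <- expected + sum(rep(w, act[[src]]))
        }
        expect_equal(synaptic_current(tgt, act, conn, specs), expected)
      }
    }
  }
})

test_that("raising SA activity never raises input to WA or WP; WP never reaches SA", {
  specs <- make_specs(5)
  conn <- connectivity_matrix(wa_wa = 6, sa_sa = 6, wa_sa = 24, sa_wa = 24,
                              wp_wa = 4, wa_wp = 3, sa_wp = 3, wp_wp = 2)
  for (wa in 0:5) for (wp in 0:5) for (sa in 0:4) {
    lo <- c(WA = wa, SA = sa, WP = wp)
    hi <- c(WA = wa, SA = sa + 1, WP = wp)
    expect_lte(synaptic_current("WA", hi, conn, specs),
               synaptic_current("WA", lo, conn, specs))
    expect_lte(synaptic_current("WP", hi, conn, specs),
               synaptic_current("WP", lo, conn, specs))
    hi_wp <- c(WA = wa, SA = sa, WP = min(wp + 1, 5))
    expect_equal(synaptic_current("SA", hi_wp, conn, specs),
                 synaptic_current("SA", c(WA = wa, SA = sa, WP = 0),
                                  conn, specs))
  }
})

test_that("poisson drive scales a mean-1 count and respects zero scale", {
  off <- population_spec("WA", 5, noise_scale = 0)
  expect_equal(poisson_drive(off, 100), rep(0, 100))
  sp <- population_spec("WA", 5, noise_scale = 1.05)
  set.seed(1)
  draws <- poisson_drive(sp, 1e5)
  expect_true(all(abs(draws / 1.05 - round(draws / 1.05)) < 1e-9))
  expect_equal(mean(draws), 1.05, tolerance = 0.02)
})

test_that("neuron stepping spikes at threshold and resets to rest", {
  mc <- membrane_constants(-70, -55)
  rest <- step_neuron(list(voltage = -70, spiked = FALSE), 0, 1, mc)
  expect_equal(rest$voltage, -70)
  expect_false(rest$spiked)
  sp <- step_neuron(list(voltage = -56, spiked = FALSE), 1, 1, mc)
  expect_true(sp$spiked)
  expect_equal(sp$voltage, -70)
  # leak-only Euler update just below threshold
  spec <- population_spec("WA", 1, capacitance = 1, tau = 15)
  cur <- leak_current(-55.5, spec, mc)
  st <- step_neuron(list(voltage = -55.5, spiked = FALSE), cur, 1, mc)
  expect_false(st$spiked)
  expect_equal(st$voltage, -55.5 - 14.5 / 15)
  expect_error(step_neuron(list(voltage = -70, spiked = FALSE), Inf, 1, mc),
               "non-finite")
})

test_that("leak-only voltage decays geometrically toward rest", {
  spec <- population_spec("WA", 1, capacitance = 1, tau = 15)
  mc <- membrane_constants(-70, -55)
  v0 <- -60
  st <- list(voltage = v0, spiked = FALSE)
  for (k in 1:40) {
    st <- step_neuron(st, leak_current(st$voltage, spec, mc), 1, mc)
    expect_equal(st$voltage, -70 + (v0 + 70) * (1 - 1 / 15)^k)
    expect_false(st$spiked)
  }
})
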