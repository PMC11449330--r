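test_that("sliding-window classification follows the spike-count majority", {
  # WA spikes only in the first half, SA only in the second
  counts <- matrix(0L, 100, 3)
  counts[1:50, 1] <- 5L
  counts[51:100, 2] <- 3L
  s <- classify_states(fake_raster(counts), window_ms = 30)
  expect_identical(s$labels, ref_classify(counts, 0L, 30L))
  rl <- rle(s$labels)
  expect_identical(rl$values, c("WAKE", "SLEEP"))
  # the switch happens within one window length of the activity change
  expect_lte(abs((s$start_step + rl$lengths[1]) - 50), 30)
})

test_that("window ties retain the previous label", {
  counts <- matrix(0L, 70, 3)
  counts[1:40, 1] <- 2L   # WAKE majority
  counts[41:70, 1] <- 1L  # equal counts from step 41 on
  counts[41:70, 2] <- 1L
  s <- classify_states(fake_raster(counts), window_ms = 30)
  expect_true(all(s$labels == "WAKE"))
  # leading ties inherit the first strict majority
  counts2 <- matrix(0L, 80, 3)
  counts2[1:40, 1] <- 1L
  counts2[1:40, 2] <- 1L
  counts2[41:80, 2] <- 3L
  s2 <- classify_states(fake_raster(counts2), window_ms = 30)
  expect_true(all(s2$labels == "SLEEP"))
})

test_that("WP spikes never influence classification", {
  set.seed(8)
  counts <- matrix(0L, 200, 3)
  counts[, 1] <- rpois(200, 2)
  counts[, 2] <- rpois(200, 2)
  base <- classify_states(fake_raster(counts))$labels
  counts[, 3] <- rpois(200, 50)
  expect_identical(classify_states(fake_raster(counts))$labels, base)
})

test_that("classification and bout extraction match brute force on random rasters", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(60:500, 1)
    burn <- sample(0:10, 1)
    counts <- matrix(0L, n, 3)
    counts[, 1] <- rpois(n, 1.2)
    counts[, 2] <- rpois(n, 1.2)
    r <- fake_raster(counts, burn_in = burn)
    ref_lab <- ref_classify(counts, burn, 30L)
    if (is.null(ref_lab)) {
      expect_error(classify_states(r), "majority")
      next
    }
    s <- classify_states(r)
    expect_identical(s$labels, ref_lab)
    bouts <- extract_bouts(s)
    rb <- ref_bouts(ref_lab)
    expect_identical(bouts$state, rb$state)
    expect_identical(as.integer(bouts$duration_ms), rb$len)
    # alternation and exact tiling of the labelled interval
    expect_true(all(diff(match(bouts$state, c("WAKE", "SLEEP"))) != 0))
    expect_identical(sum(bouts$duration_ms), as.numeric(length(ref_lab)))
    expect_true(bouts$censored[1] && bouts$censored[nrow(bouts)])
    expect_true(all(!bouts$censored[-c(1, nrow(bouts))]))
  }
})

test_that("bout extraction censors edge runs and keeps interior runs", {
  b <- extract_bouts(c("WAKE", "WAKE", "SLEEP", "SLEEP", "SLEEP",
                       "WAKE", "WAKE", "WAKE", "SLEEP"))
  expect_identical(b$state, c("WAKE", "SLEEP", "WAKE", "SLEEP"))
  expect_identical(b$duration_ms, c(2, 3, 3, 1))
  expect_identical(b$censored, c(TRUE, FALSE, FALSE, TRUE))
  # a constant sequence has no interior bout
  cb <- extract_bouts(rep("WAKE", 50))
  expect_identical(nrow(cb), 1L)
  expect_true(all(cb$censored))
  expect_null(bout_statistics(cb))
  # alternating 50-step blocks over 10^4 steps: 200 runs, 198 interior
  lab <- rep(rep(c("WAKE", "SLEEP"), each = 50), 100)
  ab <- extract_bouts(lab)
  expect_identical(sum(!ab$censored), 198L)
  expect_true(all(ab$duration_ms == 50))
})

test_that("bout statistics report count, mean, population sd, max per state", {
  b <- data.frame(state = c("WAKE", "WAKE", "WAKE", "SLEEP", "WAKE"),
                  start_ms = c(0, 2, 102, 402, 444),
                  duration_ms = c(2, 100, 300, 42, 7),
                  censored = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  st <- bout_statistics(b)
  wake <- st[st$state == "WAKE", ]
  expect_equal(wake$n, 2L)
  expect_equal(wake$mean_ms, 200)
  expect_equal(wake$sd_ms, 100)  # population sd of {100, 300}
  expect_equal(wake$max_ms, 300)
  sleep <- st[st$state == "SLEEP", ]
  expect_equal(sleep$mean_ms, 42)
  expect_equal(sleep$sd_ms, 0)
  # a state with no interior bouts is absent, not zero
  st2 <- bout_statistics(b[b$state == "WAKE", ])
  expect_false("SLEEP" %in% st2$state)
})

test_that("wake/sleep WP rate comparison reproduces hand-computed rates", {
  counts <- matrix(0L, 2100, 3)
  counts[1:1050, 1] <- 3L              # wake first ~half
  counts[1051:2100, 2] <- 3L           # sleep second ~half
  set.seed(9)
  # 227 WP spikes during wake-labelled time, 85 during sleep-labelled time
  s <- classify_states(fake_raster(counts), window_ms = 30)
  wake_steps <- s$start_step + which(s$labels == "WAKE") - 1L
  sleep_steps <- s$start_step + which(s$labels == "SLEEP") - 1L
  counts[sample(wake_steps, 227), 3] <- 1L
  counts[sample(sleep_steps, 85), 3] <- 1L
  r <- fake_raster(counts)
  res <- lc_rate_comparison(r, s)
  expect_equal(res$wake_rate, 227 / (length(wake_steps) / 1000) / 5)
  expect_equal(res$sleep_rate, 85 / (length(sleep_steps) / 1000) / 5)
  expect_equal(res$ratio, res$wake_rate / res$sleep_rate)
  # identical WP activity in both states gives ratio 1
  counts2 <- matrix(0L, 2100, 3)
  counts2[1:1050, 1] <- 3L
  counts2[1051:2100, 2] <- 3L
  counts2[, 3] <- 2L
  expect_equal(lc_rate_comparison(fake_raster(counts2), s)$ratio, 1)
  # zero sleep-state WP spikes: infinite ratio with a warning
  counts3 <- counts2
  counts3[sleep_steps, 3] <- 0L
  expect_warning(res3 <- lc_rate_comparison(fake_raster(counts3), s),
                 "infinite")
  expect_identical(res3$ratio, Inf)
})

test_that("representative per-bout WP rates use interior bouts of full length", {
  # four activity blocks so one wake and one sleep bout are interior
  counts <- matrix(0L, 4800, 3)
  counts[1:1200, 1] <- 3L
  counts[1201:2400, 2] <- 3L
  counts[2401:3600, 1] <- 3L
  counts[3601:4800, 2] <- 3L
  counts[, 3] <- rep(c(1L, 0L), length.out = 4800)  # 500 spikes/s in WP
  s <- classify_states(fake_raster(counts), window_ms = 30)
  rr <- representative_lc_rates(fake_raster(counts), s,
                                bout_window_ms = 1000)
  expect_equal(rr$wake_rate, 500 / 5)
  expect_equal(rr$sleep_rate, 500 / 5)
  # no qualifying bout -> NA
  rr2 <- representative_lc_rates(fake_raster(counts), s,
                                 bout_window_ms = 5000)
  expect_true(is.na(rr2$wake_rate) && is.na(rr2$sleep_rate))
})
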