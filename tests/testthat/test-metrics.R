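test_that("persistent-state detection recovers prescribed intervals", {
  # silent raster
  empty <- data.frame(time_ms = numeric(0), neuron = integer(0))
  expect_identical(nrow(detect_persistent_states(empty, 1:10, 0, 30000)), 0L)
  expect_error(detect_persistent_states(empty, integer(0), 0, 1000), "empty")

  # one engram at 20 /s over [10 s, 20 s): one interval, edges within the
  # window length
  fx <- generate_fixture_raster(list(cbind(10000, 20000)), span_ms = 30000,
                                n_per_engram = 50, baseline_hz = 0.2,
                                elevated_hz = 20, seed = 2)
  iv <- detect_persistent_states(fx$raster, fx$engrams[[1]], 0, 30000)
  expect_identical(nrow(iv), 1L)
  expect_lt(abs(iv[1, 1] - 10000), 1000)
  expect_lt(abs(iv[1, 2] - 20000), 1000)

  # two elevated blocks separated by a 0.5 s gap merge into one state
  fx2 <- generate_fixture_raster(list(rbind(c(5000, 9000), c(9500, 13500))),
                                 span_ms = 20000, n_per_engram = 50,
                                 baseline_hz = 0, elevated_hz = 20, seed = 3)
  iv2 <- detect_persistent_states(fx2$raster, fx2$engrams[[1]], 0, 20000)
  expect_identical(nrow(iv2), 1L)

  # a 2 s gap stays split
  fx3 <- generate_fixture_raster(list(rbind(c(2000, 6000), c(8500, 12500))),
                                 span_ms = 16000, n_per_engram = 50,
                                 baseline_hz = 0, elevated_hz = 20, seed = 4)
  iv3 <- detect_persistent_states(fx3$raster, fx3$engrams[[1]], 0, 16000)
  expect_identical(nrow(iv3), 2L)
})

test_that("detection is invariant to raster time translation", {
  fx <- generate_fixture_raster(list(cbind(4000, 9000)), span_ms = 15000,
                                n_per_engram = 40, baseline_hz = 0.5,
                                elevated_hz = 25, seed = 5)
  iv <- detect_persistent_states(fx$raster, fx$engrams[[1]], 0, 15000)
  shifted <- fx$raster
  shifted$time_ms <- shifted$time_ms + 7000
  iv_s <- detect_persistent_states(shifted, fx$engrams[[1]], 7000, 22000)
  expect_equal(iv_s, iv + 7000)
})

test_that("persistence score rectifies and normalises per engram", {
  expect_identical(persistence_score(rep(10, 5), 10), 1)
  expect_identical(persistence_score(0, 10), 0)
  expect_identical(persistence_score(20, 10), 0)     # twice the ideal: rectified
  expect_equal(persistence_score(c(10, 5), 10), mean(c(1, 0.5)))
  expect_error(persistence_score(5, 0), "positive")
})

test_that("overlapping proportion is intersection-over-union of time sets", {
  a <- cbind(0, 10000)
  expect_identical(overlapping_proportion(list(a, a)), 1)
  expect_identical(overlapping_proportion(list(cbind(0, 5000),
                                               cbind(5000, 10000))), 0)
  expect_equal(overlapping_proportion(list(cbind(0, 10000),
                                           cbind(5000, 10000))), 0.5)
  # empty union
  none <- matrix(numeric(0), ncol = 2)
  expect_identical(overlapping_proportion(list(none, none)), 0)
  # cue exclusion removes shared time from both counts
  expect_equal(overlapping_proportion(list(cbind(0, 10000), cbind(0, 10000)),
                                      exclude = cbind(0, 5000)), 1)
  expect_error(overlapping_proportion(list(a)), "two engrams")
  # bounded by construction over random configurations
  set.seed(8)
  for (i in 1:200) {
    mk <- function() {
      s <- sort(runif(4, 0, 100))
      rbind(s[1:2] * 1000, s[3:4] * 1000)
    }
    ov <- overlapping_proportion(list(mk(), mk(), mk()))
    expect_true(ov >= 0 && ov <= 1)
  }
})

test_that("population rate and high-firing proportion follow their definitions", {
  r <- data.frame(time_ms = rep(seq(0, 9999.9, length.out = 4000), 1),
                  neuron = rep(1:200, 20))
  expect_equal(population_rate(r, 1:200, 0, 10000), 2)
  expect_error(population_rate(r, 1:200, 5, 5), "window")
  silent <- data.frame(time_ms = numeric(0), neuron = integer(0))
  expect_identical(population_rate(silent, 1:10, 0, 1000), 0)
  expect_identical(high_firing_proportion(silent, 1:10, 0, 1000), 0)
  # every neuron at 6 /s
  r6 <- data.frame(time_ms = rep(seq(0, 9990, length.out = 60), 10),
                   neuron = rep(1:10, each = 60))
  expect_identical(high_firing_proportion(r6, 1:10, 0, 10000), 1)
})

test_that("synchrony index normalisation gives 1 for identical trains", {
  tt <- c(10, 250, 900, 1500)
  expect_equal(synchrony_index(tt, tt, 0, 2000), 1)
  expect_equal(synchrony_index(c(10, 500), c(250, 900), 0, 1000), 0)
  expect_true(is.na(synchrony_index(numeric(0), tt, 0, 2000)))
  # independent Poisson trains: K ~ sqrt(p_i p_j) with p = rate * bin
  set.seed(12)
  span <- 2e5
  k <- mean(replicate(20, {
    a <- sort(runif(rpois(1, 0.01 * span), 0, span))
    b <- sort(runif(rpois(1, 0.01 * span), 0, span))
    synchrony_index(a, b, 0, span)
  }))
  expect_equal(k, 0.01, tolerance = 0.15)
  # unrooted variant divides by the product
  expect_equal(synchrony_index(tt, tt, 0, 2000, sqrt_norm = FALSE), 1 / 4)
})

test_that("CV of inter-spike intervals separates regular, Poisson and bursty firing", {
  expect_identical(cv_isi(seq(0, 1000, by = 10)), 0)
  expect_true(is.na(cv_isi(c(1, 2))))
  set.seed(13)
  pois <- cumsum(rexp(20000, 0.01))
  expect_equal(cv_isi(pois), 1, tolerance = 0.03)
  # burst-doublet train: pairs 2 ms apart, pairs 1 s apart; closed form from
  # the two-point ISI mixture
  n <- 5000
  starts <- (0:(n - 1)) * 1000
  doublets <- sort(c(starts, starts + 2))
  isis <- c(rep(2, n), rep(998, n - 1))
  expect_equal(cv_isi(doublets), sd(isis) / mean(isis), tolerance = 1e-10)
  # burst-triplet train: ISI mixture (2, 2, 996) ms is over-dispersed
  triplets <- sort(as.vector(outer(c(0, 2, 4), starts, "+")))
  expect_gt(cv_isi(triplets), 1)
})

test_that("normalised firing rate divides each condition row by its mean", {
  expect_equal(normalized_firing_rate(c(2, 4)), c(2, 4) / 3)
  m <- rbind(a = c(1, 1, 1), b = c(2, 4, 6))
  out <- normalized_firing_rate(m)
  expect_equal(unname(rowMeans(out)), c(1, 1))
  expect_equal(unname(out["a", ]), c(1, 1, 1))
  expect_error(normalized_firing_rate(c(0, 0)), "zero mean")
})

test_that("oscillation power spotlights the driving band", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  set.seed(14)
  x <- sin(2 * pi * 40 * t) + rnorm(length(t), sd = 0.1)
  bp <- oscillation_power(x, fs = fs)
  expect_gt(bp$slow_gamma, bp$theta)
  expect_gt(bp$slow_gamma, bp$fast_gamma)
  peak <- bp$spectrum$freq_hz[which.max(bp$spectrum$power)]
  expect_equal(peak, 40, tolerance = 0.2)
  expect_false(bp$short_window)

  # white noise: normalised power is flat at ~1 per bin
  bw <- oscillation_power(rnorm(10000), fs = fs)
  n_theta <- sum(bw$spectrum$freq_hz >= 4 & bw$spectrum$freq_hz <= 12)
  expect_equal(bw$theta / n_theta, 1, tolerance = 0.25)

  # constant trace: zero power after detrending
  bc <- suppressWarnings(oscillation_power(rep(3, 2000), fs = fs))
  expect_true(all(bc$spectrum$power == 0))
  expect_warning(oscillation_power(rnorm(500), fs = fs), "shorter")
})

test_that("E/I current ratio handles zero-inhibition stretches", {
  tr <- data.frame(time_ms = 1:4,
                   exc_current = c(2, 2, 4, 1),
                   inh_current = c(-2, 0, -2, -0.5))
  r <- ei_ratio(tr)
  expect_equal(r$ratio$ei_ratio, c(1, NA, 2, 2))
  expect_equal(r$mean, mean(c(1, 2, 2)))
  expect_equal(r$undefined_fraction, 0.25)
  allzero <- data.frame(time_ms = 1:3, exc_current = 1:3,
                        inh_current = numeric(3))
  expect_true(is.na(ei_ratio(allzero)$mean))
})

test_that("fixture round trip: prescribed states yield the expected scores", {
  # one engram elevated for exactly the ideal duration: score ~ 1
  fx <- generate_fixture_raster(
    list(cbind(5000, 15000), cbind(20000, 30000)),
    span_ms = 35000, n_per_engram = 50, baseline_hz = 0.2,
    elevated_hz = 20, seed = 6)
  tp <- vapply(1:2, function(k) {
    iv <- detect_persistent_states(fx$raster, fx$engrams[[k]], 0, 35000)
    sum(iv[, 2] - iv[, 1]) / 1000
  }, numeric(1))
  expect_equal(persistence_score(tp, 10), 1, tolerance = 0.1)

  # identical intervals in two engrams: overlap ~ 1
  fx2 <- generate_fixture_raster(
    list(cbind(5000, 15000), cbind(5000, 15000)),
    span_ms = 20000, n_per_engram = 50, baseline_hz = 0.2,
    elevated_hz = 20, seed = 7)
  ivs <- lapply(1:2, function(k)
    detect_persistent_states(fx2$raster, fx2$engrams[[k]], 0, 20000))
  expect_gt(overlapping_proportion(ivs), 0.9)

  # near-silent fixture: nothing detected
  fx3 <- generate_fixture_raster(list(cbind(1000, 2000)), span_ms = 10000,
                                 n_per_engram = 30, baseline_hz = 0.1,
                                 elevated_hz = 0, seed = 8)
  expect_identical(
    nrow(detect_persistent_states(fx3$raster, fx3$engrams[[1]], 0, 10000)), 0L)
})
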