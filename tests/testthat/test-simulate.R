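test_that("membrane dynamics hold the leak fixed point and stay bounded", {
  # no external input, no edges: V remains at the leak potential
  cfg <- small_ei_config(C = 0, f_background = 0)
  g <- build_network(cfg)
  sim <- simulate_network(g, 500, seed = 1)
  expect_identical(nrow(sim$raster), 0L)
  expect_true(all(abs(sim$traces$mean_V_E - cfg$neuron$V_L) < 1e-9))

  # with input, the recorded mean E potential respects the reversal bounds
  g2 <- build_network(small_ei_config(seed = 2))
  sim2 <- simulate_network(g2, 2000, seed = 3)
  expect_true(all(sim2$traces$mean_V_E >= g2$config$neuron$E_I))
  expect_true(all(sim2$traces$mean_V_E <= g2$config$neuron$V_th))
})

test_that("identical seeds reproduce a run bit-for-bit; seeds differ otherwise", {
  g <- build_network(small_ei_config(seed = 4))
  a <- simulate_network(g, 1500, seed = 11, record_traces = FALSE)
  b <- simulate_network(g, 1500, seed = 11, record_traces = FALSE)
  expect_identical(a$raster, b$raster)
  c <- simulate_network(g, 1500, seed = 12, record_traces = FALSE)
  expect_false(identical(a$raster, c$raster))
})

test_that("halving the integration step changes spike counts by a few percent", {
  g <- build_network(small_ei_config(seed = 5))
  n1 <- nrow(simulate_network(g, 3000, seed = 6, dt = 0.05,
                              record_traces = FALSE)$raster)
  n2 <- nrow(simulate_network(g, 3000, seed = 6, dt = 0.025,
                              record_traces = FALSE)$raster)
  expect_gt(n1, 50)   # the comparison is only meaningful with activity
  expect_lt(abs(n1 - n2) / n1, 0.05)
})

test_that("background state is low-rate for excitatory neurons", {
  g <- build_network(scaled_config(seed = 3))
  sim <- simulate_network(g, 6000, seed = 2, record_traces = FALSE)
  e_rate <- population_rate(sim$raster, which(g$type == "E"), 1000, 6000)
  expect_lt(e_rate, 5)
})

test_that("aggregated external events match the Poisson expectation", {
  ev <- sample_external_events(400 * 2.5, 10000, seed = 1)
  expect_lt(abs(length(ev) - 10000), 4 * sqrt(10000))
  expect_identical(sample_external_events(0, 1000), numeric(0))
  expect_error(sample_external_events(-1, 1000), "rate")
})

test_that("drive schedules place cue windows on the right neurons and blocks", {
  g <- build_network(small_ei_config(n_engrams = 2, seed = 6))
  sch <- cue_schedule(2, warmup_s = 1, cue_s = 1, gap_s = 2,
                      f_cue = 12.5, f_background = 2.5)
  drv <- make_drive(g, sch$duration_ms,
                    windows = lapply(1:2, function(k)
                      list(start_ms = sch$onset_ms[k],
                           end_ms = sch$offset_ms[k],
                           neurons = engram_neurons(g, k), add_hz = 12.5)))
  base <- 400 * 2.5
  i1 <- engram_neurons(g, 1)[1]
  blocks <- which(drv$block_end > sch$onset_ms[1] &
                    drv$block_end <= sch$offset_ms[1])
  expect_true(all(drv$rate[i1, blocks] == base + 400 * 12.5))
  other <- setdiff(seq_len(nrow(drv$rate)), engram_neurons(g, 1))
  expect_true(all(drv$rate[other, blocks] == base))
  # excitability variant: inhibitory rows keep the standard background
  drv2 <- make_drive(g, 1000, f_E = 3.5, f_I = 2.5)
  expect_true(all(drv2$rate[g$type == "I", ] == base))
  expect_true(all(drv2$rate[g$type == "E", ] == 400 * 3.5))
})

test_that("rescue stimulation suppresses targeted interneurons during on-phases", {
  g <- build_network(small_ei_config(seed = 7))
  rs <- rescue_spec(frequency_hz = 40, duty = 0.5, start_ms = 200, prob = 1)
  expect_equal(1000 / rs$frequency_hz * rs$duty, 12.5)  # 12.5 ms on per 25 ms
  base <- simulate_network(g, 2500, seed = 8, record_traces = FALSE)
  resc <- simulate_network(g, 2500, rescue = rs, seed = 8,
                           record_traces = FALSE)
  inh <- which(g$type == "I")
  set.seed(8 + 7L)   # the chosen half is drawn from seed + 7
  chosen <- sort(sample(inh, round(0.5 * length(inh))))
  n_base <- sum(base$raster$neuron %in% chosen & base$raster$time_ms > 200)
  n_resc <- sum(resc$raster$neuron %in% chosen & resc$raster$time_ms > 200)
  expect_gt(n_base, 20)
  expect_lt(n_resc, 0.7 * n_base)
  # rescue absent leaves the trajectory untouched
  again <- simulate_network(g, 2500, seed = 8, record_traces = FALSE)
  expect_identical(base$raster, again$raster)
})

test_that("weight snapshots track plasticity only inside the window", {
  cfg <- small_ei_config(n_engrams = 2, seed = 9,
                         plasticity = plasticity_params(A = 0, B = 0,
                                                        beta = 0, delta1 = 0))
  g <- build_network(cfg)
  sim <- simulate_network(g, 1000, plasticity_window = c(200, 800),
                          snapshot_ms = 200, seed = 10,
                          record_traces = FALSE)
  # all-zero amplitudes: weights constant, snapshots flat
  expect_true(all(abs(diff(sim$snapshots$engram_1)) < 1e-12))
  expect_equal(sim$weights$weight, g$edges$weight[order(g$edges$pre,
                                                        g$edges$post)])
})

test_that("transmitter-induced growth counts presynaptic spikes exactly", {
  # delta1-only plasticity: every E->E weight grows by delta1 times the
  # presynaptic spike count inside the window
  cfg <- small_ei_config(n_engrams = 0, seed = 11,
                         plasticity = plasticity_params(A = 0, B = 0,
                                                        beta = 0,
                                                        delta1 = 1e-4))
  g <- build_network(cfg)
  sim <- simulate_network(g, 2000, plasticity_window = c(0, 2000),
                          seed = 12, record_traces = FALSE)
  counts <- table(factor(sim$raster$neuron, levels = seq_along(g$type)))
  e_ord <- sim$weights
  w0 <- g$edges$weight[order(g$edges$pre, g$edges$post)]
  plast <- e_ord$plastic
  expected <- w0[plast] + 1e-4 * as.numeric(counts[e_ord$pre[plast]])
  expect_equal(e_ord$weight[plast], expected, tolerance = 1e-12)
})
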