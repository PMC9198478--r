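test_that("conductance update: exact decay, saturating and additive jumps", {
  spec <- sif_neuron()
  # pure decay over one synaptic time constant
  g <- update_conductances(c(100, 0), dt_ms = 1, arrivals = integer(), spec)
  expect_equal(g[1], 100 * exp(-1), tolerance = 1e-12)
  # a spike returns a saturating group to exactly its ceiling, not beyond
  g <- update_conductances(c(36.79, 0), 1, c(`1` = 1), spec)
  expect_identical(g[1], 100)
  g <- update_conductances(c(99.9, 0), 0.01, c(`1` = 1, `2` = 1), spec)
  expect_identical(g[1], 100)
  # additive groups accumulate without bound
  lif <- make_lif(spec)
  g <- update_conductances(100, dt_ms = 1e-9, arrivals = c(`1` = 1, `3` = 1),
                           lif)
  expect_equal(g, 100 * exp(-1e-9) + 200, tolerance = 1e-9)
  # errors
  expect_error(update_conductances(c(1, 1), 1, c(`9` = 1), spec),
               class = "satif_error_mapping")
  expect_error(update_conductances(c(-1, 0), 1, integer(), spec),
               class = "satif_error_state")
})

test_that("voltage step solves the affine membrane equation exactly", {
  m <- membrane_params()
  # resting fixed point
  expect_identical(step_voltage(-65, 0, 1, m), -65)
  # closed-form relaxation over one membrane time constant
  expect_equal(step_voltage(-60, 0, dt_ms = 20, m), -65 + 5 * exp(-1),
               tolerance = 1e-12)
  # constant-drive fixed point (v_rest + RgE_s)/(1 + Rg); E_s = 0
  v_star <- -65 / (1 + 20 * 100 * 1e-6)
  expect_equal(step_voltage(-65, 100, dt_ms = 1e6, m), v_star,
               tolerance = 1e-9)
  expect_equal(v_star, -64.87, tolerance = 1e-4)
  # cross-check the fixed point against a dense forward-Euler integration
  v <- -65
  for (k in seq_len(500000)) {
    v <- v + 0.001 / 20 * (-(v + 65) + 20 * 100 * 1e-6 * (0 - v))
  }
  expect_equal(step_voltage(-65, 100, dt_ms = 1e6, m), v, tolerance = 1e-6)
})

test_that("no input leaves the membrane exactly at rest with no spikes", {
  for (spec in list(sif_neuron(), make_lif(sif_neuron()))) {
    sim <- run_simulation(spec, spike_trains(list(), horizon_ms = 100))
    expect_identical(unique(sim$voltage_mV), -65)
    expect_length(sim$spike_times_ms, 0)
    expect_identical(max(sim$conductance_pS), 0)
    expect_identical(length(sim$voltage_mV), 1000L)
  }
})

test_that("clustered input saturates at 100 pS, scattered reaches 200 pS", {
  spec <- sif_neuron()
  same_group <- run_simulation(
    spec, generate_single_spike_trains("1100", 10, 50))
  split_group <- run_simulation(
    spec, generate_single_spike_trains("1010", 10, 50))
  expect_identical(max(rowSums(same_group$conductance_pS)), 100)
  expect_identical(max(rowSums(split_group$conductance_pS)), 200)
  # and the scattered pattern therefore depolarises further
  expect_gt(max(split_group$voltage_mV), max(same_group$voltage_mV))
})

test_that("default-step integration matches a dense forward-Euler reference", {
  spec <- sif_neuron()
  fixtures <- list(
    generate_single_spike_trains("1010", 10, 50),
    generate_single_spike_trains("1100", 10, 50),
    spike_trains(list(`1` = c(5, 6, 6.4), `4` = c(5.2, 20)), horizon_ms = 50)
  )
  for (trains in fixtures) {
    peak <- max(run_simulation(spec, trains, dt_ms = 0.1,
                               spiking = FALSE)$voltage_mV)
    peak_ref <- fe_reference(spec, trains, dt_ms = 0.001)
    expect_lt(abs(peak - peak_ref), 1e-3)  # 1 microvolt
  }
})

test_that("saturating groups never exceed their ceiling under random drive", {
  spec <- sif_neuron()
  for (seed in 1:25) {
    pattern <- withr::with_seed(seed, rbinom(4, 1, 0.7))
    if (sum(pattern) == 0) pattern[1] <- 1L
    trains <- generate_poisson_trains(pattern, 200, 200, seed = seed, sync = 0)
    sim <- run_simulation(spec, trains)
    expect_true(all(sim$conductance_pS >= 0))
    expect_true(all(sim$conductance_pS <= spec$drive_scale * 100))
  }
})

test_that("adding an input spike never decreases the somatic spike count", {
  spec <- sif_neuron(drive_scale = 100)
  spec$membrane$v_threshold_mV <- -64.13
  for (seed in 1:20) {
    trains <- generate_poisson_trains("1010", 50, 300, seed = seed, sync = 1)
    n0 <- length(run_simulation(spec, trains)$spike_times_ms)
    extra <- withr::with_seed(seed, runif(1, 0, 300))
    df <- rbind(as.data.frame(trains),
                data.frame(source_id = "2", time_ms = extra))
    n1 <- length(run_simulation(spec, spike_trains(df, 300))$spike_times_ms)
    expect_gte(n1, n0)
  }
})

test_that("spike times line up with threshold crossings and reset", {
  spec <- sif_neuron(drive_scale = 100)
  spec$membrane$v_threshold_mV <- -64.13
  sim <- run_simulation(spec, generate_single_spike_trains("1010", 10, 50))
  expect_gte(length(sim$spike_times_ms), 1)
  idx <- as.integer(round(sim$spike_times_ms / sim$dt_ms))
  expect_identical(unique(sim$voltage_mV[idx]), spec$membrane$v_reset_mV)
  expect_true(all(sim$voltage_mV <= spec$membrane$v_threshold_mV))
  expect_true(all(sim$voltage_mV >= spec$membrane$v_reset_mV))
})

test_that("resolution and horizon guards reject unusable settings", {
  spec <- sif_neuron()
  trains <- generate_single_spike_trains("1010", 10, 50)
  expect_error(run_simulation(spec, trains, dt_ms = 0.5),
               class = "satif_error_resolution")
  expect_error(spike_trains(list(`1` = 1), horizon_ms = 0))
})

test_that("tidy/glance expose traces and summaries consistently", {
  spec <- sif_neuron()
  sim <- run_simulation(spec, generate_single_spike_trains("1010", 10, 50))
  td <- tidy(sim)
  expect_named(td, c("time_ms", "voltage_mV", "g1_pS", "g2_pS"))
  expect_identical(nrow(td), 500L)
  g <- glance(sim)
  expect_identical(g$peak_total_g_pS, 200)
  expect_identical(g$n_spikes, 0L)
  expect_s3_class(autoplot(sim), "ggplot")
})
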