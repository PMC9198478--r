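test_that("Poisson episode generator is seeded, patterned and rate-true", {
  # inactive everywhere -> empty
  empty <- generate_poisson_trains("0000", 50, 500, seed = 3)
  expect_identical(nrow(empty), 0L)
  expect_identical(train_horizon(empty), 500)
  # determinism
  a <- generate_poisson_trains("1111", 50, 500, seed = 11)
  b <- generate_poisson_trains("1111", 50, 500, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(
    as.data.frame(a),
    as.data.frame(generate_poisson_trains("1111", 50, 500, seed = 12))))
  # only active sources fire
  tr <- generate_poisson_trains("1010", 50, 500, seed = 5)
  expect_setequal(unique(tr$source_id), c("1", "3"))
  # a source's train does not depend on which other sources are active
  tr2 <- generate_poisson_trains("1100", 50, 500, seed = 5)
  expect_identical(tr$time_ms[tr$source_id == "1"],
                   tr2$time_ms[tr2$source_id == "1"])
  # marginal rate: 40 episodes x 4 sources at 50 Hz, 500 ms -> mean near 25
  counts <- vapply(1:40, function(s)
    nrow(generate_poisson_trains("1111", 50, 500, seed = s, sync = 0)) / 4,
    numeric(1))
  se <- sqrt(25 / 40)
  expect_lt(abs(mean(counts) - 25), 3 * se)
  # synchronous construction preserves the marginal rate
  counts1 <- vapply(1:40, function(s)
    nrow(generate_poisson_trains("1111", 50, 500, seed = s, sync = 1)) / 4,
    numeric(1))
  expect_lt(abs(mean(counts1) - 25), 3 * se)
})

test_that("single-spike episodes activate exactly the patterned sources", {
  tr <- generate_single_spike_trains("1010", t0_ms = 10, horizon_ms = 500)
  expect_identical(tr$source_id, c("1", "3"))
  expect_identical(tr$time_ms, c(10, 10))
  expect_identical(nrow(generate_single_spike_trains("0000", 10, 500)), 0L)
  # the two clustered patterns are cluster-permutations of each other
  t1 <- generate_single_spike_trains("1100", 10, 500)
  t2 <- generate_single_spike_trains("0011", 10, 500)
  expect_identical(t1$time_ms, t2$time_ms)
  expect_identical(as.integer(t2$source_id) - 2L, as.integer(t1$source_id))
  expect_error(generate_single_spike_trains("1010", t0_ms = 600,
                                            horizon_ms = 500),
               class = "satif_error_invalid_trains")
})

test_that("calibration finds the class gap for a SIF and scales the drive", {
  cfg <- protocol_config(make_cfbp(2), mode = "spike")
  cal <- calibrate(sif_neuron(), cfg)
  expect_true(cal$calibratable)
  expect_identical(cal$drive_scale, 100)
  expect_gt(cal$v_threshold_mV, -65 + 0.5)
  expect_gt(cal$margin_mV, 0)
  # threshold sits strictly between the class peaks
  pk0 <- max(cal$peaks$peak_voltage_mV[cal$peaks$output == 0])
  pk1 <- min(cal$peaks$peak_voltage_mV[cal$peaks$output == 1])
  expect_true(pk0 < cal$v_threshold_mV && cal$v_threshold_mV < pk1)
})

test_that("a LIF cannot be calibrated: its episode peaks are identical", {
  cfg <- protocol_config(make_cfbp(2), mode = "spike")
  cal <- calibrate(make_lif(sif_neuron()), cfg)
  expect_false(cal$calibratable)
  expect_identical(length(unique(cal$peaks$peak_voltage_mV)), 1L)
})

test_that("degenerate single-class tables are not calibratable", {
  tbl <- boolean_table(c("1100", "0011"), c(0, 0))
  cal <- calibrate(sif_neuron(), protocol_config(tbl, mode = "spike"))
  expect_false(cal$calibratable)
  expect_match(cal$reason, "single output class")
})

test_that("the calibrated SIF reproduces the truth table in spike mode", {
  spec <- sif_neuron()
  cfg <- protocol_config(make_cfbp(2), mode = "spike")
  res <- run_protocol(spec, cfg, calibrate(spec, cfg))
  expect_identical(res$episodes$output, c(0L, 0L, 1L, 1L))
  expect_identical(res$episodes$pattern, cfbp_patterns())
  expect_true(glance(res)$matches_table)
  # an all-zero pattern is silent
  tbl0 <- boolean_table(c("0000", "1100", "0011", "0101", "1010"),
                        c(0, 0, 0, 1, 1))
  cfg0 <- protocol_config(tbl0, mode = "spike")
  res0 <- run_protocol(spec, cfg0, calibrate(spec, cfg0))
  expect_identical(res0$episodes$output[res0$episodes$pattern == "0000"], 0L)
})

test_that("no single threshold lets the LIF match the table", {
  lif <- make_lif(sif_neuron(drive_scale = 100))
  cfg <- protocol_config(make_cfbp(2), mode = "spike")
  # outputs are constant across episodes for any threshold choice
  for (th in c(-64.9, -64.5, -64.13, -63.5)) {
    spec <- lif
    spec$membrane$v_threshold_mV <- th
    outs <- vapply(cfbp_patterns(), function(p) {
      sim <- run_simulation(spec, generate_single_spike_trains(p, 10, 500))
      as.integer(length(sim$spike_times_ms) >= 1)
    }, integer(1))
    expect_identical(length(unique(outs)), 1L)
  }
})

test_that("implements_table separates SIF from LIF and counts groups", {
  cfg <- protocol_config(make_cfbp(2), mode = "spike")
  expect_true(implements_table(sif_neuron(), cfg)$implements)
  lif_res <- implements_table(make_lif(sif_neuron()), cfg)
  expect_false(lif_res$implements)
  expect_match(lif_res$reason, "not calibratable")
  # one saturating point is not enough: two are
  one_group <- implements_table(sif_neuron(n_groups = 1), cfg)
  expect_false(one_group$implements)
  expect_true(implements_table(sif_neuron(n_groups = 2), cfg)$implements)
})

test_that("the verdict survives doubling the initial drive", {
  cfg <- protocol_config(make_cfbp(2), mode = "spike")
  res <- implements_table(sif_neuron(drive_scale = 2), cfg)
  expect_true(res$implements)
  expect_identical(res$episodes$output, c(0L, 0L, 1L, 1L))
})

test_that("spike-mode protocol runs are bit-identical across repeats", {
  spec <- sif_neuron()
  cfg <- protocol_config(make_cfbp(2), mode = "spike")
  cal <- calibrate(spec, cfg)
  r1 <- run_protocol(spec, cfg, cal)
  r2 <- run_protocol(spec, cfg, cal)
  expect_identical(r1$episodes, r2$episodes)
})

test_that("rate-mode episodes show the ordinal saturation contrast", {
  # within every seed, each scattered episode out-fires every clustered one
  # for the SIF, while the LIF is pattern-blind; episode-level categorical
  # readout is not asserted (peak summation varies with event density)
  spec <- sif_neuron(drive_scale = 100)
  spec$membrane$v_threshold_mV <- -64.13
  lif <- make_lif(spec)
  for (seed in 1:8) {
    counts <- vapply(cfbp_patterns(), function(p) {
      tr <- generate_poisson_trains(p, 50, 500, seed = seed, sync = 1)
      length(run_simulation(spec, tr)$spike_times_ms)
    }, integer(1))
    expect_gt(min(counts[3:4]), max(counts[1:2]))
    lif_counts <- vapply(cfbp_patterns(), function(p) {
      tr <- generate_poisson_trains(p, 50, 500, seed = seed, sync = 1)
      length(run_simulation(lif, tr)$spike_times_ms)
    }, integer(1))
    expect_identical(length(unique(lif_counts)), 1L)
  }
})

test_that("rate-mode verdicts are seed-stable and honestly reported", {
  spec <- sif_neuron()
  cfg <- protocol_config(make_cfbp(2), mode = "rate", seed = 7)
  r1 <- implements_table(spec, cfg, n_seeds = 5)
  r2 <- implements_table(spec, cfg, n_seeds = 5)
  expect_identical(r1$implements, r2$implements)
  expect_identical(r1$agreement, r2$agreement)
  expect_true(r1$agreement >= 0 && r1$agreement <= 1)
})
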