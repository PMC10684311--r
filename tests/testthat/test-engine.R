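# short-duration configurations keep the engine tests fast; the full
# 5,000 ms protocols are exercised in test-acceptance.R

test_that("a quiescent network stays silent and its weights untouched", {
  cfg <- sim_config(gks1 = 1.5, dc1 = 0, gks2 = 1.5, dc2 = 0,
                    noise_rate = 0, duration = 300, seed = 4)
  r <- run_simulation(cfg)
  expect_equal(nrow(r$spikes), 0)
  expect_identical(r$w_final$w12, r$wiring$w12$w)
  expect_identical(r$w_final$w21, r$wiring$w21$w)
})

test_that("with plasticity disabled the weight matrices are bit-identical", {
  cfg <- sim_config(gks1 = 0.6, dc1 = 3.0, gks2 = 0.6, dc2 = 2.0,
                    noise_rate = 5, duration = 300, seed = 4, stdp = FALSE)
  r <- run_simulation(cfg)
  expect_gt(nrow(r$spikes), 0)
  expect_identical(r$w_final$w12, r$wiring$w12$w)
  expect_identical(r$w_final$w21, r$wiring$w21$w)
})

test_that("identical config and master seed give bit-identical runs", {
  cfg <- sim_config(gks1 = 0.6, dc1 = 3.0, gks2 = 0.6, dc2 = 2.0,
                    noise_rate = 5, duration = 250, seed = 11)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$w_final, b$w_final)
  # and a different seed gives a different realization
  cfg2 <- cfg
  cfg2$seed <- 12L
  c2 <- run_simulation(cfg2)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("plastic weights respect the hard bounds during simulation", {
  cfg <- sim_config(gks1 = 0.2, dc1 = 3.0, gks2 = 0.2, dc2 = 3.0,
                    noise_rate = 0, duration = 400, seed = 2)
  r <- run_simulation(cfg)
  expect_true(all(r$w_final$w12 >= 0 & r$w_final$w12 <= 0.01))
  expect_true(all(r$w_final$w21 >= 0 & r$w_final$w21 <= 0.01))
})

test_that("a synchronized module produces PING volleys recruiting most E cells", {
  cfg <- sim_config(gks1 = 0.6, dc1 = 2.0, gks2 = 0.6, dc2 = 2.0,
                    noise_rate = 0, duration = 1000, seed = 6)
  r <- run_simulation(cfg)
  bursts <- module_bursts(r, 2)
  expect_gte(length(bursts), 5)
  sp <- module_e_spikes(r, 2)
  # discard the initial settling volley, then require >= 80% of the 400
  # E cells within +/-5 ms of each volley peak
  late <- bursts[bursts > 200]
  frac <- vapply(late, function(b) {
    length(unique(r$spikes$cell[r$spikes$module == 2 & r$spikes$kind == "E" &
                                  abs(r$spikes$time - b) <= 5])) / 400
  }, numeric(1))
  expect_true(all(frac >= 0.8))
  # volley rhythm is in the gamma band
  expect_gt(bursting_frequency(bursts), 20)
  expect_lt(bursting_frequency(bursts), 80)
})

test_that("weight snapshots are taken at the requested times and stay bounded", {
  cfg <- sim_config(gks1 = 0.6, dc1 = 3.0, gks2 = 0.6, dc2 = 2.0,
                    noise_rate = 0, duration = 300, seed = 8,
                    snapshot_times = c(100, 200, 300))
  r <- run_simulation(cfg)
  expect_equal(ncol(r$w_snapshots), 3)
  expect_true(all(r$w_snapshots >= 0 & r$w_snapshots <= 0.01))
  # snapshots interpolate between initial and final states monotonically
  # in time for a potentiating direction (not necessarily per-synapse)
  n12 <- nrow(r$wiring$w12)
  expect_equal(r$w_snapshots[seq_len(n12), 3], r$w_final$w12,
               tolerance = 1e-12)
})

test_that("trial seeds differ and the summary reports a finite standard error", {
  cfg <- sim_config(gks1 = 0.6, dc1 = 3.0, gks2 = 0.6, dc2 = 2.0,
                    noise_rate = 0, duration = 250, seed = 3)
  rt <- run_trials(cfg, n_trials = 2)
  expect_length(rt$trials, 2)
  expect_false(identical(rt$trials[[1]]$spikes, rt$trials[[2]]$spikes))
  expect_true(all(is.finite(rt$summary$se_dw)))
  expect_equal(rt$summary$into_module, 1:2)
  # single trial: the average is the trial itself
  rt1 <- run_trials(cfg, n_trials = 1)
  expect_equal(rt1$summary$mean_dw[2], module_delta_w(rt1$trials[[1]], 2))
})

test_that("simulation outputs round-trip through the directory exporter", {
  cfg <- sim_config(gks1 = 0.6, dc1 = 3.0, gks2 = 0.6, dc2 = 2.0,
                    noise_rate = 0, duration = 200, seed = 5)
  r <- run_simulation(cfg)
  dir <- file.path(tempdir(), "simout")
  write_simulation(r, dir)
  sp <- read.table(file.path(dir, "spikes.tsv"), header = TRUE)
  expect_equal(nrow(sp), nrow(r$spikes))
  wi <- as.matrix(Matrix::readMM(file.path(dir, "w12_initial.mtx")))
  expect_equal(sum(wi), sum(r$wiring$w12$w), tolerance = 1e-10)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$seed, 5)
  expect_equal(meta$noise_rate_hz, 0)
})

test_that("gating variables stay in [0,1] throughout a long single-cell run", {
  sim <- simulate_neuron(neuron_params(gKs = 1.5), 1.5, 5000,
                         record_traces = TRUE)
  expect_true(all(sim$z >= 0 & sim$z <= 1))
  expect_true(all(is.finite(sim$V)))
})
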