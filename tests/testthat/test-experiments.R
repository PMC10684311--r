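# transcription of the figure-caption parameters, kept separate from the
# registry implementation as a guard against silent edits
caption_params <- list(
  E = c(0.3, 0.5), F = c(0.6, 3.0), G = c(1.2, 2.0), H = c(1.2, 3.5),
  fig5_E = c(0.2, 2.0), fig5_F = c(0.6, 2.0), fig5_G = c(1.1, 2.0),
  fig6_E = c(0.9, 1.5), fig6_F = c(0.3, 3.5), fig6_G = c(0.9, 3.5),
  fig7_C = c(0.6, 1.5), fig7_D = c(0.0, 3.5), fig7_E = c(1.2, 3.0),
  fig8_C = c(0.9, 1.0), fig8_D = c(0.3, 3.0), fig8_E = c(1.5, 2.5))

test_that("the example registry matches the transcribed protocol parameters", {
  tab <- example_registry()
  expect_setequal(tab$name, names(caption_params))
  for (nm in names(caption_params)) {
    row <- tab[tab$name == nm, ]
    expect_equal(c(row$gks1, row$dc1), unname(caption_params[[nm]]),
                 info = nm)
  }
  # the homogeneous protocols hold module 2 at gKs 0.6, DC 2.0
  homog <- tab$module2 == "homog_0.6_2.0"
  expect_true(all(tab$wiring[homog] == "random"))
  expect_true(all(tab$in_degree[homog] == 40))
  # the topographic hotspot protocols use in-degree 5
  expect_true(all(tab$in_degree[tab$wiring == "topographic"] == 5))
})

test_that("example configs assemble the right maps and wiring", {
  cfg <- example_config("F", noise_rate = 5, duration = 100)
  expect_true(all(cfg$gks1$E == 0.6) && all(cfg$dc1$E == 3.0))
  expect_true(all(cfg$gks2$E == 0.6) && all(cfg$dc2$E == 2.0))
  expect_equal(cfg$noise_rate, 5)
  expect_equal(cfg$wiring, "random")

  cfg7 <- example_config("fig7_D", duration = 100)
  expect_lt(min(cfg7$gks2$E), 0.2 + 0.01 * 1.3)
  expect_true(all(cfg7$dc2$E == 3.0))
  expect_true(all(cfg7$gks1$E == 0.0))

  cfg9 <- example_config("fig9_C", duration = 100)
  expect_equal(cfg9$wiring, "topographic")
  expect_equal(cfg9$in_degree, 5)
  expect_equal(min(cfg9$gks1$E), min(cfg9$gks2$E))

  cfgB <- example_config("fig10_B", duration = 100)
  low1 <- sum(cfgB$gks1$E < 0.85)
  low2 <- sum(cfgB$gks2$E < 0.85)
  expect_gt(low1, 1.5 * low2)  # two hotspots vs one
  expect_error(example_config("fig11_Z"), "unknown example")
})

test_that("run_example returns trials, bursts and weight-change bundles", {
  res <- run_example("F", n_trials = 1, duration = 400, seed = 2,
                     out_dir = file.path(tempdir(), "exF"))
  expect_s3_class(res$config, "sim_config")
  expect_length(res$trials, 1)
  expect_gt(length(res$bursts$module1), 2)
  expect_s3_class(res$weight_change$into2, "weight_change")
  grid <- weight_change_grid(res$weight_change$into2)
  expect_equal(dim(grid), c(20, 20))
  expect_true(file.exists(file.path(tempdir(), "exF", "spikes.tsv")))
  expect_true(file.exists(file.path(tempdir(), "exF", "dw_into_module2.csv")))
})

test_that("sweeps return a tidy grid with per-point statistics", {
  spec <- sweep_spec(gks_values = 0.6, dc_values = c(2.0, 3.0),
                     noise_rates = 0, n_trials = 1, duration = 400, seed = 9)
  out <- run_sweep(spec)
  expect_equal(nrow(out), 2)
  expect_setequal(out$dc1, c(2.0, 3.0))
  expect_true(all(is.finite(out$dw_into2)))
  expect_true(all(is.finite(out$mpc)))
  expect_true(all(out$mpc >= 0 & out$mpc <= 1))
  expect_true(all(is.finite(out$freq_diff)))
  expect_true(all(out$n_trials == 1))
})

test_that("sweep output does not depend on grid evaluation order", {
  fwd <- sweep_spec(gks_values = c(0.3, 0.9), dc_values = 2.0,
                    noise_rates = 0, n_trials = 1, duration = 250, seed = 13)
  rev_ <- sweep_spec(gks_values = c(0.9, 0.3), dc_values = 2.0,
                     noise_rates = 0, n_trials = 1, duration = 250, seed = 13)
  a <- run_sweep(fwd)
  b <- run_sweep(rev_)
  a <- a[order(a$gks1), ]
  b <- b[order(b$gks1), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("volley fixtures honour participation, jitter and lag", {
  set.seed(33)
  truth <- c(100, 200, 300)
  fx <- volley_fixture(truth, n_cells = 100, participation = 1, jitter_sd = 0)
  expect_equal(nrow(fx$spikes), 2 * 3 * 100)  # both modules, full turnout
  expect_equal(sort(unique(fx$spikes$time)), truth)

  fx2 <- volley_fixture(truth, n_cells = 1000, participation = 0.3,
                        jitter_sd = 0)
  per_volley <- table(fx2$spikes$time[fx2$spikes$module == 1])
  expect_true(all(abs(per_volley - 300) < 4 * sqrt(1000 * 0.3 * 0.7)))

  fx3 <- volley_fixture(truth, n_cells = 50, participation = 1,
                        jitter_sd = 0, lag = 5)
  expect_equal(fx3$truth$volleys2, truth + 5)
  expect_equal(sort(unique(fx3$spikes$time[fx3$spikes$module == 2])),
               truth + 5)
})
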