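# literal transcription of the mean-phase-coherence formula, written
# directly from its definition as an independent check
mpc_literal <- function(top, bottom) {
  one_way <- function(a, b) {
    ph <- c()
    for (k in seq_len(length(a) - 1)) {
      inb <- b[b >= a[k] & b < a[k + 1]]
      if (length(inb))
        ph <- c(ph, 2 * pi * (inb[1] - a[k]) / (a[k + 1] - a[k]))
    }
    sqrt(sum(cos(ph))^2 + sum(sin(ph))^2) / length(ph)
  }
  (one_way(top, bottom) + one_way(bottom, top)) / 2
}

test_that("population traces are Gaussian kernel sums with the right mass", {
  tr0 <- population_trace(numeric(0), t_max = 50)
  expect_true(all(tr0$activity == 0))

  tr1 <- population_trace(100, t_max = 200)
  expect_equal(tr1$time[which.max(tr1$activity)], 100)
  expect_equal(max(tr1$activity), 1)
  # integral = N * sigma * sqrt(2*pi) up to grid error
  expect_equal(sum(tr1$activity) * 0.1, sqrt(2 * pi), tolerance = 1e-3)

  # linearity: N coincident spikes scale the single-spike peak by N
  trN <- population_trace(rep(100, 37), t_max = 200)
  expect_equal(max(trN$activity), 37 * max(tr1$activity))
})

test_that("burst detection finds constructed volleys and ignores flat traces", {
  spikes <- rep(c(100, 200, 300), each = 400)
  tr <- population_trace(spikes, t_max = 400)
  expect_equal(detect_bursts(tr), c(100, 200, 300))
  expect_length(detect_bursts(population_trace(numeric(0), t_max = 100)), 0)
  # sub-threshold volleys (< 10% of cells) are not reported
  weak <- population_trace(rep(150, 10), t_max = 300)
  expect_length(detect_bursts(weak), 0)
})

test_that("burst detection recovers >= 95% of jittered fixture volleys within 2 ms", {
  set.seed(21)
  hits <- 0
  total <- 0
  for (rep in 1:20) {
    truth <- seq(100, 900, by = 80)
    fx <- volley_fixture(truth, n_cells = 400, participation = 0.5,
                         jitter_sd = 2)
    sp <- fx$spikes$time[fx$spikes$module == 1]
    got <- detect_bursts(population_trace(sp, t_max = 1000))
    total <- total + length(truth)
    hits <- hits + sum(vapply(truth, function(tv)
      any(abs(got - tv) <= 2), logical(1)))
  }
  expect_gte(hits / total, 0.95)
})

test_that("MPC is 1 for constant-lag periodic trains and ~0 for uniform phases", {
  a <- seq(0, 2000, by = 25)
  expect_equal(mean_phase_coherence(a, a + 7), 1.0, tolerance = 1e-12)
  # invariance to a global time shift of both trains
  expect_equal(mean_phase_coherence(a + 123.4, a + 7 + 123.4), 1.0,
               tolerance = 1e-12)

  set.seed(5)
  n <- 10000
  ref <- seq(0, by = 100, length.out = n + 1)
  other <- ref[-(n + 1)] + runif(n, 0, 100)  # phases uniform by construction
  expect_lt(mean_phase_coherence(ref, other, symmetrize = FALSE), 0.02)
})

test_that("MPC agrees with an independent literal transcription on small examples", {
  b1 <- c(0, 100, 210, 330)
  b2 <- c(40, 160, 240, 350)
  expect_equal(mean_phase_coherence(b1, b2), mpc_literal(b1, b2),
               tolerance = 1e-12)
  b3 <- c(10, 95, 180, 400)
  expect_equal(mean_phase_coherence(b1, b3), mpc_literal(b1, b3),
               tolerance = 1e-12)
  expect_true(mean_phase_coherence(b1, b2) >= 0 &&
                mean_phase_coherence(b1, b2) <= 1)
  expect_true(is.na(mean_phase_coherence(numeric(0), b2)))
})

test_that("linlog display is odd, monotone, continuous at the breakpoints", {
  expect_equal(linlog_display(0), 0)
  expect_equal(linlog_display(2), 2)
  expect_equal(linlog_display(-2), -2)
  expect_equal(linlog_display(20), 3)    # one decade above the breakpoint
  expect_equal(linlog_display(200), 4)
  expect_equal(linlog_display(-100), -(2 + log10(50)))
  x <- seq(-100, 100, by = 0.5)
  y <- linlog_display(x)
  expect_true(all(diff(y) > 0))
  expect_equal(y, -rev(y))
})

test_that("bursting frequency comes from the mean inter-burst interval", {
  expect_equal(bursting_frequency(seq(0, 5000, by = 25)), 40)
  expect_equal(bursting_frequency(c(0, 1000)), 1)
  expect_true(is.na(bursting_frequency(500)))
  set.seed(3)
  jittered <- seq(0, 4000, by = 40) + rnorm(101, 0, 1)
  expect_equal(bursting_frequency(sort(jittered)), 25, tolerance = 0.02)
})

test_that("volley fixtures carry their ground truth through the analysis stack", {
  set.seed(10)
  truth <- seq(50, 950, by = 60)
  fx <- volley_fixture(truth, n_cells = 200, participation = 1,
                       jitter_sd = 0, lag = 5)
  sp1 <- fx$spikes$time[fx$spikes$module == 1]
  expect_equal(sort(unique(sp1)), truth)
  b1 <- detect_bursts(population_trace(sp1, t_max = 1000), n_cells = 200)
  b2 <- detect_bursts(population_trace(
    fx$spikes$time[fx$spikes$module == 2], t_max = 1000), n_cells = 200)
  expect_equal(mean_phase_coherence(b1, b2), 1, tolerance = 1e-9)
  expect_equal(burst_lead(b1, b2), 5, tolerance = 0.2)

  fx2 <- volley_fixture(truth, n_cells = 300, participation = 0.3,
                        jitter_sd = 2)
  got <- detect_bursts(population_trace(
    fx2$spikes$time[fx2$spikes$module == 1], t_max = 1000), n_cells = 300)
  expect_true(all(vapply(truth, function(tv)
    any(abs(got - tv) <= 2), logical(1))))
})
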