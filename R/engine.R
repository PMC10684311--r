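# Named seed substreams derived from the master seed: wiring, initial
# conditions and noise can each be reproduced independently.
seed_stream <- function(master, name) {
  offset <- switch(name, wiring = 1L, init = 2L, noise = 3L,
                   stop("unknown seed stream: ", name))
  as.integer((as.numeric(master) * 11 + offset * 7919) %% 2147483647)
}

#' Configuration of a two-module network simulation
#'
#' Collects everything that defines one simulation: the per-module gKs
#' (ACh) and DC maps, inter-module wiring mode and in-degree, Poisson
#' noise rate, plasticity switch, duration and the master seed. gKs and DC
#' arguments accept either a scalar (homogeneous map) or a
#' [spatial_map] (hotspot geometry).
#'
#' @param gks1,dc1 gKs map (mS/cm^2) and DC drive map (uA/cm^2) of
#'   module 1.
#' @param gks2,dc2 the same for module 2.
#' @param wiring inter-module wiring mode, `"random"` or `"topographic"`.
#' @param in_degree inter-module synapses per E cell and direction.
#' @param noise_rate Poisson pulse rate per cell (Hz).
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param stdp enable plasticity on the inter-module E-to-E synapses.
#' @param seed master seed; expands into independent substreams for
#'   wiring, initial conditions and noise.
#' @param w0 initial inter-module weight (mS/cm^2).
#' @param noise a [noise_params()] object for amplitude/width/targeting;
#'   its `rate` field is overridden by `noise_rate`.
#' @param stdp_par an [stdp_params()] object.
#' @param syn a [synapse_params()] object.
#' @param neuron a [neuron_params()] object supplying the non-gKs
#'   biophysics shared by all cells.
#' @param ii_self allow I->I self-edges.
#' @param snapshot_times times (ms) at which to snapshot the plastic
#'   weights during the run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(gks1, dc1, gks2, dc2,
                       wiring = c("random", "topographic"), in_degree = 40,
                       noise_rate = 0, duration = 5000, dt = 0.05,
                       stdp = TRUE, seed = 1, w0 = 0.005,
                       noise = noise_params(), stdp_par = stdp_params(),
                       syn = synapse_params(), neuron = neuron_params(),
                       ii_self = FALSE, snapshot_times = numeric(0)) {
  wiring <- match.arg(wiring)
  stopifnot(duration > 0, dt > 0, noise_rate >= 0)
  structure(list(
    gks1 = as_spatial_map(gks1), dc1 = as_spatial_map(dc1),
    gks2 = as_spatial_map(gks2), dc2 = as_spatial_map(dc2),
    wiring = wiring, in_degree = in_degree, noise_rate = noise_rate,
    duration = duration, dt = dt, stdp = stdp, seed = as.integer(seed),
    w0 = w0, noise = noise, stdp_par = stdp_par, syn = syn,
    neuron = neuron, ii_self = ii_self, snapshot_times = snapshot_times),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Two-module E-I simulation config: %g ms at dt = %g ms, seed %d\n",
    x$duration, x$dt, x$seed))
  cat(sprintf("  wiring: %s (in-degree %d), noise %g Hz, STDP %s\n",
              x$wiring, x$in_degree, x$noise_rate,
              if (x$stdp) "on" else "off"))
  cat(sprintf("  module 1: gKs [%g, %g], DC [%g, %g]\n",
              min(x$gks1$E), max(x$gks1$E), min(x$dc1$E), max(x$dc1$E)))
  cat(sprintf("  module 2: gKs [%g, %g], DC [%g, %g]\n",
              min(x$gks2$E), max(x$gks2$E), min(x$dc2$E), max(x$dc2$E)))
  invisible(x)
}

# edge frames (local 1-based) -> global 0-based CSR by source over n cells
edges_to_csr <- function(src0, dst0, w, n_cells) {
  o <- order(src0)
  src0 <- src0[o]; dst0 <- dst0[o]; w <- w[o]
  counts <- tabulate(src0 + 1L, nbins = n_cells)
  list(ptr = c(0L, cumsum(counts)), tgt = as.integer(dst0), w = w, ord = o)
}

# index CSR: for each cell, positions into the plastic-synapse arrays
index_csr <- function(cell0, n_cells, n_syn) {
  o <- order(cell0)
  counts <- tabulate(cell0 + 1L, nbins = n_cells)
  list(ptr = c(0L, cumsum(counts)), idx = as.integer((seq_len(n_syn) - 1L)[o]))
}

#' Run one two-module network simulation
#'
#' Builds the wiring (seeded), draws initial conditions and noise trains
#' (seeded), and integrates both modules with the compiled fixed-step
#' engine. Identical configs with identical seeds give bit-identical spike
#' records and final weights.
#'
#' Internal cell order is module 1 (E 1-400, I 401-500) then module 2; the
#' returned spike records carry the raster display indices (module 2 E
#' cells 1-400, module 2 I cells 401-500, module 1 E cells 501-900,
#' module 1 I cells 901-1000).
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_result`: list with `spikes` (data frame
#'   `cell` = display id, `time` ms, `module`, `kind`), `wiring`
#'   (the [build_intermodule()] object holding initial weights), `w_final`
#'   (list `w12`, `w21` of final weights aligned with the wiring edge
#'   rows), optional `w_snapshots`, and the `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))

  set.seed(seed_stream(config$seed, "wiring"))
  top <- list(build_module(ii_self = config$ii_self),
              build_module(ii_self = config$ii_self))
  inter <- build_intermodule(config$wiring, config$in_degree, w0 = config$w0)

  n_cells <- 2L * N_MOD
  gks <- c(config$gks1$E, config$gks1$I, config$gks2$E, config$gks2$I)
  dc <- c(config$dc1$E, config$dc1$I, config$dc2$E, config$dc2$I)
  is_exc <- rep(rep(c(TRUE, FALSE), 2), times = c(N_E, N_I, N_E, N_I))

  static_src <- static_dst <- integer(0)
  static_w <- numeric(0)
  for (m in 1:2) {
    off <- (m - 1L) * N_MOD
    for (nm in c("ee", "ei", "ie", "ii")) {
      ed <- top[[m]][[nm]]
      static_src <- c(static_src, off + ed$src - 1L)
      static_dst <- c(static_dst, off + ed$dst - 1L)
      static_w <- c(static_w, ed$w)
    }
  }
  scsr <- edges_to_csr(static_src, static_dst, static_w, n_cells)

  # plastic inter-module synapses: module1 -> module2 then module2 -> module1
  p_src <- c(inter$w12$src - 1L, N_MOD + inter$w21$src - 1L)
  p_tgt <- c(N_MOD + inter$w12$dst - 1L, inter$w21$dst - 1L)
  p_w0 <- c(inter$w12$w, inter$w21$w)
  n12 <- nrow(inter$w12)
  n_syn <- length(p_src)
  by_src <- index_csr(p_src, n_cells, n_syn)
  by_tgt <- index_csr(p_tgt, n_cells, n_syn)

  set.seed(seed_stream(config$seed, "init"))
  # initial potentials near rest with modest dispersion: the network is
  # bistable between the synchronized-volley state and a sparse
  # inhibition-dominated state, and wide initial dispersion strands it in
  # the latter; this range starts trials in the volley regime the model
  # is built to study (see the methods vignette)
  v0 <- runif(n_cells, -68, -62)

  set.seed(seed_stream(config$seed, "noise"))
  ev <- draw_noise_events(config$noise_rate, n_cells, config$duration)
  if (config$noise$e_only)
    ev[!is_exc] <- list(numeric(0))
  noise_ptr <- c(0L, cumsum(lengths(ev)))
  noise_times <- as.numeric(unlist(ev))

  out <- run_network_cpp(
    gks, dc, is_exc,
    config$neuron$C, config$neuron$gNa, config$neuron$gKdr, config$neuron$gL,
    config$neuron$VNa, config$neuron$VK, config$neuron$VL,
    scsr$ptr, scsr$tgt, scsr$w,
    as.integer(p_src), as.integer(p_tgt), p_w0,
    by_src$ptr, by_src$idx, by_tgt$ptr, by_tgt$idx,
    config$stdp, config$stdp_par$A_plus, config$stdp_par$A_minus,
    config$stdp_par$tau_plus, config$stdp_par$tau_minus,
    config$stdp_par$w_min, config$stdp_par$w_max,
    config$syn$tau, config$syn$E_exc, config$syn$E_inh,
    as.integer(noise_ptr), noise_times,
    config$noise$amplitude, config$noise$pulse_width,
    v0, config$dt, config$duration,
    v_thresh = -20, lockout = 2,
    snap_times = sort(config$snapshot_times))

  disp <- c(module_display_ids(1), module_display_ids(2))
  internal <- out$spike_cell + 1L
  spikes <- data.frame(
    cell = disp[internal],
    time = out$spike_time,
    module = ifelse(internal <= N_MOD, 1L, 2L),
    kind = ifelse(is_exc[internal], "E", "I"))

  res <- list(spikes = spikes, wiring = inter,
              w_final = list(w12 = out$w_final[seq_len(n12)],
                             w21 = out$w_final[n12 + seq_len(n_syn - n12)]),
              config = config)
  if (length(config$snapshot_times) > 0) {
    res$w_snapshots <- out$w_snapshots
    res$snapshot_times <- sort(config$snapshot_times)
  }
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Two-module simulation result: %d spikes over %g ms\n",
              nrow(x$spikes), x$config$duration))
  for (m in 1:2) {
    dw <- module_delta_w(x, into = m)
    cat(sprintf("  mean incoming dW module %d: %+.3g%%\n", m, dw))
  }
  invisible(x)
}

#' Raster plot of a simulation result
#'
#' Cells on the vertical axis by display index (module 2 E cells 1-400 at
#' the bottom, module 1 I cells 901-1000 at the top), E spikes in black
#' and I spikes in green.
#'
#' @param x a `sim_result`.
#' @param window time window `c(from, to)` in ms (default last 300 ms).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sim_result <- function(x, window = NULL, ...) {
  sp <- x$spikes
  if (is.null(window))
    window <- c(max(0, x$config$duration - 300), x$config$duration)
  sp <- sp[sp$time >= window[1] & sp$time <= window[2], ]
  graphics::plot(sp$time, sp$cell, pch = ".", cex = 2,
                 col = ifelse(sp$kind == "E", "black", "darkgreen"),
                 xlab = "time (ms)", ylab = "cell (display index)", ...)
  graphics::abline(h = c(400.5, 500.5, 900.5), col = "grey70", lty = 3)
}

#' Spike times of one module's E cells
#'
#' @param result a `sim_result`.
#' @param module 1 or 2.
#' @return Numeric vector of spike times (ms).
#' @export
module_e_spikes <- function(result, module) {
  sp <- result$spikes
  sp$time[sp$module == module & sp$kind == "E"]
}

#' Mean percentage weight change of synapses incoming to a module
#'
#' @param result a `sim_result`.
#' @param into target module (1 or 2).
#' @return Mean of `100 * (w_final - w_initial) / w_initial` over the
#'   synapses targeting that module.
#' @export
module_delta_w <- function(result, into) {
  dir <- if (into == 2) "w12" else "w21"
  wi <- result$wiring[[dir]]$w
  wf <- result$w_final[[dir]]
  mean(100 * (wf - wi) / wi)
}

#' Run repeated trials of one configuration
#'
#' Repeats the simulation `n_trials` times with distinct trial seeds
#' derived from the master seed (fresh wiring, initial conditions and
#' noise per trial) and summarizes the mean incoming weight change per
#' module with its standard error across trials.
#'
#' @param config a [sim_config()].
#' @param n_trials number of trials (the figure protocols use 4).
#' @return A list with `trials` (list of `sim_result`s) and `summary`
#'   (data frame: `into_module`, `mean_dw`, `se_dw`, `n_trials`).
#' @export
run_trials <- function(config, n_trials = 4) {
  stopifnot(n_trials >= 1)
  trials <- lapply(seq_len(n_trials), function(k) {
    cfg <- config
    cfg$seed <- as.integer((as.numeric(config$seed) + 104729 * (k - 1)) %%
                             2147483647)
    run_simulation(cfg)
  })
  dw <- vapply(1:2, function(m)
    vapply(trials, module_delta_w, numeric(1), into = m), numeric(n_trials))
  dw <- matrix(dw, nrow = n_trials)
  summary <- data.frame(
    into_module = 1:2,
    mean_dw = colMeans(dw),
    se_dw = apply(dw, 2, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_),
    n_trials = n_trials)
  list(trials = trials, summary = summary)
}

#' Write spikes, weights and metadata of a simulation to a directory
#'
#' Spikes go to `spikes.tsv` (display id, time), initial and final
#' inter-module weights to MatrixMarket files per direction, snapshot
#' times (if any) to a JSON index, and the run metadata (seed, duration,
#' wiring mode, noise rate) to `meta.json`.
#'
#' @param result a `sim_result`.
#' @param dir output directory (created if missing).
#' @export
write_simulation <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$spikes[, c("cell", "time")],
              file.path(dir, "spikes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (d in c("w12", "w21")) {
    ed <- result$wiring[[d]]
    write_weights_mtx(ed, file.path(dir, paste0(d, "_initial.mtx")))
    ed$w <- result$w_final[[d]]
    write_weights_mtx(ed, file.path(dir, paste0(d, "_final.mtx")))
  }
  meta <- list(seed = result$config$seed,
               duration_ms = result$config$duration,
               dt_ms = result$config$dt,
               wiring = result$config$wiring,
               in_degree = result$config$in_degree,
               noise_rate_hz = result$config$noise_rate,
               stdp = result$config$stdp,
               snapshot_times = result$snapshot_times)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
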