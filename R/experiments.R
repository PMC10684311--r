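# Protocol registry -----------------------------------------------------
#
# Single source of the per-protocol parameters. Homogeneous-modulation
# examples list scalar module values; hotspot protocols reference the
# named map presets. Wiring: the random protocols use in-degree 40, the
# topographic ones in-degree 5 (high local in-degree obliterates the
# topographic specificity the hotspot protocols probe). Hotspot radius,
# sigmoid steepness and center placement are free parameters (see the
# vignette); two-hotspot placements use centers (5,5) and (15,15).

registry_table <- function() {
  rows <- list(
    # name,     gks1, dc1, module2 spec,         wiring,        in_deg
    E        = list(0.3, 0.5, "homog_0.6_2.0", "random", 40),
    F        = list(0.6, 3.0, "homog_0.6_2.0", "random", 40),
    G        = list(1.2, 2.0, "homog_0.6_2.0", "random", 40),
    H        = list(1.2, 3.5, "homog_0.6_2.0", "random", 40),
    fig5_E   = list(0.2, 2.0, "homog_0.6_2.0", "random", 40),
    fig5_F   = list(0.6, 2.0, "homog_0.6_2.0", "random", 40),
    fig5_G   = list(1.1, 2.0, "homog_0.6_2.0", "random", 40),
    fig6_E   = list(0.9, 1.5, "fig6_module2", "random", 40),
    fig6_F   = list(0.3, 3.5, "fig6_module2", "random", 40),
    fig6_G   = list(0.9, 3.5, "fig6_module2", "random", 40),
    fig7_C   = list(0.6, 1.5, "fig7_module2", "random", 40),
    fig7_D   = list(0.0, 3.5, "fig7_module2", "random", 40),
    fig7_E   = list(1.2, 3.0, "fig7_module2", "random", 40),
    fig8_C   = list(0.9, 1.0, "fig8_module2", "topographic", 5),
    fig8_D   = list(0.3, 3.0, "fig8_module2", "topographic", 5),
    fig8_E   = list(1.5, 2.5, "fig8_module2", "topographic", 5))
  data.frame(
    name = names(rows),
    gks1 = vapply(rows, function(r) r[[1]], numeric(1)),
    dc1 = vapply(rows, function(r) r[[2]], numeric(1)),
    module2 = vapply(rows, function(r) r[[3]], character(1)),
    wiring = vapply(rows, function(r) r[[4]], character(1)),
    in_degree = vapply(rows, function(r) as.integer(r[[5]]), integer(1)),
    row.names = NULL)
}

# hotspot gKs values for the colocalized-hotspot protocol (representative
# low / intermediate / high modulation; the sweep varies this value)
FIG9_GKS <- c(fig9_C = 0.2, fig9_D = 0.6, fig9_E = 1.2)

#' Table of scripted example protocols
#'
#' One row per named example: module 1 homogeneous gKs/DC, the module 2
#' map set, wiring mode and inter-module in-degree. Module 2 specs:
#' `"homog_0.6_2.0"` is the homogeneous reference module (gKs 0.6 mS/cm^2,
#' DC 2.0 uA/cm^2); the `fig*_module2` entries are [ach_preset()] hotspot
#' maps. Examples E-H are the four homogeneous-modulation case studies;
#' `fig5_*` vary only gKs at matched DC; `fig6_*`-`fig8_*` are the
#' single-hotspot protocols. The colocalized- and two-hotspot topographic
#' protocols (`fig9_*`, `fig10_*`) are constructed by [example_config()]
#' directly.
#'
#' @return A data frame with columns `name`, `gks1`, `dc1`, `module2`,
#'   `wiring`, `in_degree`.
#' @export
example_registry <- function() registry_table()

#' Build the simulation config of a named example protocol
#'
#' @param name a name from [example_registry()], or one of `"fig9_C"`,
#'   `"fig9_D"`, `"fig9_E"` (colocalized single hotspots, gKs 0.2/0.6/1.2),
#'   `"fig10_A"` (one colocalized hotspot pair), `"fig10_B"` (two hotspots
#'   in module 1, one shared with module 2), `"fig10_C"` (two colocalized
#'   pairs), `"fig10_D"` (one hotspot per module, not aligned).
#' @param noise_rate Poisson pulse rate (Hz).
#' @param duration simulated time (ms).
#' @param seed master seed.
#' @param ... further arguments to [sim_config()].
#' @return A [sim_config()].
#' @export
example_config <- function(name, noise_rate = 0, duration = 5000, seed = 1,
                           ...) {
  tab <- registry_table()
  if (name %in% tab$name) {
    row <- tab[tab$name == name, ]
    m2 <- if (row$module2 == "homog_0.6_2.0") {
      list(gks = homogeneous_map(0.6), dc = homogeneous_map(2.0))
    } else {
      ach_preset(row$module2)
    }
    return(sim_config(gks1 = row$gks1, dc1 = row$dc1,
                      gks2 = m2$gks, dc2 = m2$dc,
                      wiring = row$wiring, in_degree = row$in_degree,
                      noise_rate = noise_rate, duration = duration,
                      seed = seed, ...))
  }
  if (name %in% names(FIG9_GKS)) {
    g <- FIG9_GKS[[name]]
    m <- list(gks = hotspot_map(cbind(10, 10), g, 1.5),
              dc = homogeneous_map(3.0))
    return(sim_config(gks1 = m$gks, dc1 = m$dc, gks2 = m$gks, dc2 = m$dc,
                      wiring = "topographic", in_degree = 5,
                      noise_rate = noise_rate, duration = duration,
                      seed = seed, ...))
  }
  if (grepl("^fig10_[ABCD]$", name)) {
    one <- cbind(10, 10)
    two <- rbind(c(5, 5), c(15, 15))
    centers <- switch(sub("fig10_", "", name),
      A = list(m1 = one, m2 = one),
      B = list(m1 = two, m2 = cbind(5, 5)),
      C = list(m1 = two, m2 = two),
      D = list(m1 = cbind(5, 5), m2 = cbind(15, 15)))
    return(sim_config(
      gks1 = hotspot_map(centers$m1, 0.2, 1.5),
      dc1 = homogeneous_map(3.0),
      gks2 = hotspot_map(centers$m2, 0.2, 1.5),
      dc2 = homogeneous_map(3.0),
      wiring = "topographic", in_degree = 5,
      noise_rate = noise_rate, duration = duration, seed = seed, ...))
  }
  stop("unknown example name: ", name)
}

#' Run a named example protocol
#'
#' Runs `n_trials` trials of the example configuration and returns the
#' per-trial results together with burst statistics and weight-change
#' summaries.
#'
#' @inheritParams example_config
#' @param n_trials number of trials.
#' @param out_dir optional directory: spikes/weights of trial 1 and the
#'   per-cell incoming weight-change grids are written there.
#' @return A list with `config`, `trials`, `summary` (from [run_trials()]),
#'   `bursts` (module burst trains of trial 1), and `weight_change`
#'   ([weight_change()] objects of trial 1, per target module).
#' @export
run_example <- function(name, noise_rate = 0, n_trials = 1,
                        duration = 5000, seed = 1, out_dir = NULL, ...) {
  cfg <- example_config(name, noise_rate = noise_rate, duration = duration,
                        seed = seed, ...)
  rt <- run_trials(cfg, n_trials = n_trials)
  r1 <- rt$trials[[1]]
  res <- list(config = cfg, trials = rt$trials, summary = rt$summary,
              bursts = list(module1 = module_bursts(r1, 1),
                            module2 = module_bursts(r1, 2)),
              weight_change = list(into1 = weight_change(r1, 1),
                                   into2 = weight_change(r1, 2)))
  if (!is.null(out_dir)) {
    write_simulation(r1, out_dir)
    for (m in 1:2)
      write.table(weight_change_grid(res$weight_change[[m]]),
                  file.path(out_dir, sprintf("dw_into_module%d.csv", m)),
                  sep = ",", row.names = FALSE, col.names = FALSE)
  }
  res
}

#' Specification of a gKs x DC x noise parameter sweep
#'
#' Module 1's homogeneous gKs and DC are varied on a grid while module 2
#' is held fixed; each grid point is run at each noise rate. The default
#' reduced grid (4 x 4, 2 trials) is far coarser than a publication-scale
#' map and is meant for desk-scale exploration; pass denser grids for
#' higher resolution.
#'
#' @param gks_values,dc_values module 1 grids (mS/cm^2, uA/cm^2).
#' @param noise_rates Poisson rates to cross with the grid (Hz).
#' @param gks2,dc2 module 2 maps (scalar or [spatial_map]).
#' @param wiring,in_degree inter-module wiring.
#' @param n_trials trials per grid point.
#' @param duration per-trial duration (ms).
#' @param seed master seed (each grid point derives its own).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(gks_values = seq(0, 1.5, by = 0.5),
                       dc_values = seq(0.5, 3.5, by = 1),
                       noise_rates = 0,
                       gks2 = 0.6, dc2 = 2.0,
                       wiring = "random", in_degree = 40,
                       n_trials = 2, duration = 5000, seed = 1) {
  stopifnot(length(gks_values) >= 1, length(dc_values) >= 1)
  structure(list(gks_values = gks_values, dc_values = dc_values,
                 noise_rates = noise_rates, gks2 = gks2, dc2 = dc2,
                 wiring = wiring, in_degree = in_degree,
                 n_trials = n_trials, duration = duration, seed = seed),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Runs every (gKs, DC, noise rate) combination of the spec and collects
#' trial-averaged statistics in a tidy table. A grid point whose
#' simulation fails (numerical instability) is recorded with `NA`
#' statistics and the sweep continues. Results do not depend on the order
#' in which grid points are evaluated: each point derives its own seed
#' from the spec seed and its grid position.
#'
#' @param spec a [sweep_spec()].
#' @return A data frame with one row per grid point and columns `gks1`,
#'   `dc1`, `noise_rate`, `dw_into1`, `dw_into1_se`, `dw_into2`,
#'   `dw_into2_se`, `mpc`, `freq_diff` (module 2 minus module 1 bursting
#'   frequency, Hz), `n_trials`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(gks1 = spec$gks_values, dc1 = spec$dc_values,
                      noise_rate = spec$noise_rates,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    # seed from the parameter values, so results are independent of the
    # order in which grid points are evaluated
    point_seed <- as.integer((as.numeric(spec$seed) +
                                round(g$gks1 * 1e3) * 131 +
                                round(g$dc1 * 1e3) * 419 +
                                round(g$noise_rate * 10) * 877) %% 2147483647)
    cfg <- sim_config(gks1 = g$gks1, dc1 = g$dc1,
                      gks2 = spec$gks2, dc2 = spec$dc2,
                      wiring = spec$wiring, in_degree = spec$in_degree,
                      noise_rate = g$noise_rate, duration = spec$duration,
                      seed = point_seed)
    out <- data.frame(gks1 = g$gks1, dc1 = g$dc1,
                      noise_rate = g$noise_rate,
                      dw_into1 = NA_real_, dw_into1_se = NA_real_,
                      dw_into2 = NA_real_, dw_into2_se = NA_real_,
                      mpc = NA_real_, freq_diff = NA_real_,
                      n_trials = spec$n_trials)
    tryCatch({
      rt <- run_trials(cfg, n_trials = spec$n_trials)
      out$dw_into1 <- rt$summary$mean_dw[1]
      out$dw_into1_se <- rt$summary$se_dw[1]
      out$dw_into2 <- rt$summary$mean_dw[2]
      out$dw_into2_se <- rt$summary$se_dw[2]
      stats <- vapply(rt$trials, function(r) {
        b1 <- module_bursts(r, 1)
        b2 <- module_bursts(r, 2)
        c(mpc = mean_phase_coherence(b1, b2),
          fd = bursting_frequency(b2) - bursting_frequency(b1))
      }, numeric(2))
      out$mpc <- mean(stats["mpc", ], na.rm = TRUE)
      out$freq_diff <- mean(stats["fd", ], na.rm = TRUE)
      out
    }, error = function(e) out)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic spike-volley fixture
#'
#' Produces spike records for two modules firing in periodic population
#' volleys with known ground truth, for testing the analysis stack
#' (burst detection, MPC, lead times) independently of the simulator. Each
#' cell joins each volley with probability `participation`; a joining
#' cell's spike time is the volley time plus Gaussian jitter. Module 2
#' volleys lag module 1 volleys by `lag`.
#'
#' @param volley_times module 1 volley times (ms).
#' @param n_cells cells per module.
#' @param participation per-cell volley participation probability.
#' @param jitter_sd spike-time jitter SD (ms).
#' @param lag module 2 lag (ms).
#' @return A list with `spikes` (data frame `cell`, `time`, `module`) and
#'   `truth` (list `volleys1`, `volleys2`, `lag`).
#' @export
volley_fixture <- function(volley_times, n_cells = 400, participation = 1,
                           jitter_sd = 0, lag = 0) {
  stopifnot(participation > 0, participation <= 1, jitter_sd >= 0)
  volley_times <- sort(volley_times)
  draw_module <- function(times, module) {
    do.call(rbind, lapply(times, function(tv) {
      cells <- which(runif(n_cells) <= participation)
      if (!length(cells)) return(NULL)
      data.frame(cell = cells,
                 time = tv + rnorm(length(cells), 0, jitter_sd),
                 module = module)
    }))
  }
  sp <- rbind(draw_module(volley_times, 1L),
              draw_module(volley_times + lag, 2L))
  sp <- sp[sp$time >= 0, ]
  sp <- sp[order(sp$time), ]
  rownames(sp) <- NULL
  list(spikes = sp,
       truth = list(volleys1 = volley_times, volleys2 = volley_times + lag,
                    lag = lag))
}

#' @importFrom stats rnorm
NULL
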