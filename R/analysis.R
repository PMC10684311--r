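#' Gaussian-convolved population activity trace
#'
#' Each spike contributes a Gaussian kernel (`sigma` = 1 ms by default)
#' centered at its time; the kernels of all spikes are summed on a regular
#' grid to form the cumulative network activity trace whose peaks mark
#' population volleys.
#'
#' @param spikes spike times (ms).
#' @param t_max trace length (ms); defaults to the last spike plus
#'   `5 * sigma`.
#' @param sigma kernel width (ms).
#' @param grid_dt grid resolution (ms).
#' @return A data frame with columns `time`, `activity`.
#' @export
population_trace <- function(spikes, t_max = NULL, sigma = 1, grid_dt = 0.1) {
  stopifnot(sigma > 0, grid_dt > 0)
  if (is.null(t_max))
    t_max <- if (length(spikes)) max(spikes) + 5 * sigma else 0
  grid <- seq(0, t_max, by = grid_dt)
  act <- numeric(length(grid))
  if (length(spikes)) {
    # bin the spikes, then convolve with a truncated Gaussian kernel
    half <- ceiling(5 * sigma / grid_dt)
    kern <- exp(-((-half:half) * grid_dt)^2 / (2 * sigma^2))
    # spikes snap to the nearest grid point (error < grid_dt/2 << sigma)
    idx <- pmin(pmax(round(spikes / grid_dt), 0), length(grid) - 1) + 1
    counts <- tabulate(idx, nbins = length(grid))
    padded <- c(numeric(half), counts, numeric(half))
    conv <- stats::filter(padded, kern, sides = 2)
    act <- as.numeric(conv[half + seq_along(counts)])
  }
  data.frame(time = grid, activity = act)
}

#' Detect population bursts (volleys) from an activity trace
#'
#' Local maxima of the population trace exceeding
#' `min_height_fraction * n_cells` are returned in time order; maxima
#' closer than `merge_ms` are merged, keeping the higher peak.
#'
#' @param trace a data frame from [population_trace()].
#' @param n_cells number of E cells in the module (the height reference).
#' @param min_height_fraction detection threshold as a fraction of
#'   `n_cells`.
#' @param merge_ms refractory merge radius (ms).
#' @return Numeric vector of burst peak times (ms), strictly increasing.
#' @export
detect_bursts <- function(trace, n_cells = 400, min_height_fraction = 0.1,
                          merge_ms = 5) {
  a <- trace$activity
  n <- length(a)
  if (n < 3) return(numeric(0))
  thr <- min_height_fraction * n_cells
  is_peak <- c(FALSE, a[2:(n - 1)] > a[1:(n - 2)] &
                 a[2:(n - 1)] >= a[3:n], FALSE) & a > thr
  pk_t <- trace$time[is_peak]
  pk_h <- a[is_peak]
  if (!length(pk_t)) return(numeric(0))
  # merge peaks closer than merge_ms, keeping the higher one
  keep_t <- pk_t[1]
  keep_h <- pk_h[1]
  out_t <- numeric(0)
  for (i in seq_along(pk_t)[-1]) {
    if (pk_t[i] - keep_t < merge_ms) {
      if (pk_h[i] > keep_h) {
        keep_t <- pk_t[i]
        keep_h <- pk_h[i]
      }
    } else {
      out_t <- c(out_t, keep_t)
      keep_t <- pk_t[i]
      keep_h <- pk_h[i]
    }
  }
  c(out_t, keep_t)
}

#' Burst times of one module of a simulation result
#'
#' Convenience wrapper: population trace of the module's E cells followed
#' by burst detection.
#'
#' @param result a `sim_result`.
#' @param module 1 or 2.
#' @param ... passed to [detect_bursts()].
#' @return Burst peak times (ms).
#' @export
module_bursts <- function(result, module, ...) {
  sp <- module_e_spikes(result, module)
  detect_bursts(population_trace(sp, t_max = result$config$duration), ...)
}

# one-directional MPC: phases of the other train's bursts within the
# reference train's inter-burst intervals
mpc_directional <- function(ref, other) {
  if (length(ref) < 2) return(NA_real_)
  phases <- c()
  for (k in seq_len(length(ref) - 1)) {
    inside <- other[other >= ref[k] & other < ref[k + 1]]
    if (length(inside))
      phases <- c(phases, 2 * pi * (inside[1] - ref[k]) /
                    (ref[k + 1] - ref[k]))
  }
  if (!length(phases)) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Mean phase coherence between two burst trains
#'
#' For each inter-burst interval of the reference train, the phase of the
#' paired burst of the other train is
#' `2 * pi * (t_other - t_ref_k) / (t_ref_k+1 - t_ref_k)`; the MPC is the
#' modulus of the mean unit phasor over intervals containing a burst
#' (unmatched intervals are skipped; if several bursts fall in one
#' interval the first is paired). The reported value is the average of the
#' two directional MPCs, so it is symmetric in the two modules.
#'
#' @param bursts1,bursts2 strictly increasing burst time vectors (ms).
#' @param symmetrize average the two directional MPCs (the reported
#'   statistic); `FALSE` returns the one-directional MPC with `bursts1` as
#'   the reference train, which is the natural form for null calibrations
#'   where the phases of `bursts2` within `bursts1`'s intervals are
#'   controlled.
#' @return MPC in \[0, 1\]; 1 means perfect phase locking, values near 0
#'   mean uniformly scattered phases. `NA` if either train has fewer than
#'   two bursts or no pairings exist.
#' @export
mean_phase_coherence <- function(bursts1, bursts2, symmetrize = TRUE) {
  m12 <- mpc_directional(bursts1, bursts2)
  if (!symmetrize) return(m12)
  m21 <- mpc_directional(bursts2, bursts1)
  mean(c(m12, m21))
}

#' Percentage weight-change statistics of inter-module synapses
#'
#' Computes `100 * (w_final - w_initial) / w_initial` per synapse for one
#' direction of a simulation, plus the per-target-cell incoming average
#' (the quantity mapped over the lattice in the hotspot protocols) and the
#' module-wide average over all E cells.
#'
#' @param result a `sim_result`.
#' @param into target module (1 or 2).
#' @return An object of class `weight_change`: list with `edges` (data
#'   frame `src`, `dst`, `w_initial`, `w_final`, `dw_pct`), `per_cell`
#'   (length-400 incoming average per target E cell, `NaN` where a cell
#'   has no incoming plastic synapse), and `module_mean`.
#' @export
weight_change <- function(result, into) {
  dir <- if (into == 2) "w12" else "w21"
  ed <- result$wiring[[dir]]
  wf <- result$w_final[[dir]]
  if (any(ed$w <= 0))
    stop("zero initial weight on an existing edge")
  dw <- 100 * (wf - ed$w) / ed$w
  per_cell <- vapply(seq_len(N_E), function(cell) {
    rows <- ed$dst == cell
    if (any(rows)) mean(dw[rows]) else NaN
  }, numeric(1))
  structure(list(
    edges = data.frame(src = ed$src, dst = ed$dst, w_initial = ed$w,
                       w_final = wf, dw_pct = dw),
    per_cell = per_cell,
    module_mean = mean(dw),
    into = into), class = "weight_change")
}

#' @export
print.weight_change <- function(x, ...) {
  cat(sprintf(
    "Inter-module weight change into module %d: mean %+.3g%% (%d synapses)\n",
    x$into, x$module_mean, nrow(x$edges)))
  invisible(x)
}

#' Lattice map of per-cell incoming weight change
#'
#' @param wc a [weight_change()] object.
#' @return A 20 x 20 matrix (rows = lattice x, columns = lattice y) of the
#'   per-cell incoming average weight change (percent).
#' @export
weight_change_grid <- function(wc) {
  matrix(wc$per_cell, nrow = E_SIDE, byrow = TRUE)
}

#' Linear-logarithmic display transform for percentage weight changes
#'
#' Identity on \[-2, 2\] percent; outside, one display unit per decade:
#' `sign(x) * (2 + log10(|x| / 2))`. Odd, continuous and monotone, so small
#' and large changes are comparable on one color scale.
#'
#' @param x percentage change(s), vectorized.
#' @return Display coordinate(s).
#' @examples
#' linlog_display(c(-100, -2, 0, 2, 20, 100))
#' @export
linlog_display <- function(x) {
  ifelse(abs(x) <= 2, x, sign(x) * (2 + log10(abs(x) / 2)))
}

#' Network bursting frequency
#'
#' Mean burst rate from a burst train: `(N - 1) / (t_last - t_first)`,
#' in Hz.
#'
#' @param bursts burst peak times (ms).
#' @return Frequency (Hz); `NA` with fewer than two bursts.
#' @export
bursting_frequency <- function(bursts) {
  if (length(bursts) < 2) return(NA_real_)
  1000 * (length(bursts) - 1) / (bursts[length(bursts)] - bursts[1])
}

#' Median lead of module 1 bursts over module 2 bursts
#'
#' Pairs each module 1 burst with the nearest module 2 burst and returns
#' the median of (module 2 time - module 1 time); positive values mean
#' module 1 volleys lead.
#'
#' @param bursts1,bursts2 burst time vectors (ms).
#' @return Median lead (ms); `NA` if either train is empty.
#' @export
burst_lead <- function(bursts1, bursts2) {
  if (!length(bursts1) || !length(bursts2)) return(NA_real_)
  lead <- vapply(bursts1, function(t1) {
    bursts2[which.min(abs(bursts2 - t1))] - t1
  }, numeric(1))
  stats::median(lead)
}
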