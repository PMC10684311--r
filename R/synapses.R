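#' Synaptic current parameters
#'
#' Synapses are modeled as conductances that jump by the synaptic weight at
#' each presynaptic spike and decay exponentially with a single time
#' constant shared by all synapse types; the current onto target `i` is
#' `g(t) * (V_i - E_syn)` with `E_syn` set by the presynaptic cell type.
#'
#' @param tau conductance decay constant (ms).
#' @param E_exc,E_inh reversal potentials for excitatory / inhibitory
#'   synapses (mV).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau = 3.0, E_exc = 0, E_inh = -75) {
  stopifnot(tau > 0)
  structure(list(tau = tau, E_exc = E_exc, E_inh = E_inh),
            class = "synapse_params")
}

#' Poisson noise pulse parameters
#'
#' Each cell independently receives current pulses at Poisson-distributed
#' event times: a pulse sets the noise current to `amplitude` (depolarizing)
#' for `pulse_width` ms. Overlapping pulses saturate at one amplitude by
#' default (an event never stacks the current above `amplitude`).
#'
#' @param rate pulse rate per cell (Hz); the network protocols use
#'   0, 2.5, 5 or 10 Hz.
#' @param amplitude pulse current (uA/cm^2).
#' @param pulse_width pulse duration (ms).
#' @param e_only restrict noise to E cells (default `FALSE`: all cells of
#'   both modules receive noise at the same rate).
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(rate = 0, amplitude = 6, pulse_width = 1,
                         e_only = FALSE) {
  stopifnot(rate >= 0, amplitude >= 0, pulse_width > 0)
  structure(list(rate = rate, amplitude = amplitude,
                 pulse_width = pulse_width, e_only = e_only),
            class = "noise_params")
}

#' Literal-sum synaptic current from a presynaptic spike history
#'
#' Direct evaluation of
#' \deqn{I_{syn}(t) = (V - E_{syn}) \sum_j w_j \sum_k e^{-(t - t_{jk})/\tau}}
#' over all presynaptic spikes at times `<= t`. This is the reference form;
#' the simulation engine realizes the same current incrementally as a
#' decaying per-target conductance (the two agree to rounding error).
#'
#' @param spike_times list of numeric vectors, one per presynaptic neuron.
#' @param w numeric vector of synaptic weights (mS/cm^2), one per neuron.
#' @param t evaluation time (ms).
#' @param V postsynaptic membrane potential (mV).
#' @param E_syn synaptic reversal potential (mV).
#' @param tau decay constant (ms).
#' @return Synaptic current (uA/cm^2; positive values hyperpolarize).
#' @examples
#' synaptic_current(list(0), w = 0.01, t = 3, V = -75, E_syn = 0) # inward
#' @export
synaptic_current <- function(spike_times, w, t, V, E_syn, tau = 3.0) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  stopifnot(length(w) == length(spike_times))
  g <- sum(vapply(seq_along(w), function(j) {
    ts <- spike_times[[j]]
    ts <- ts[ts <= t]
    w[j] * sum(exp(-(t - ts) / tau))
  }, numeric(1)))
  g * (V - E_syn)
}

#' Incrementally evaluated synaptic conductance on a time grid
#'
#' Advances a single decaying conductance through a merged spike sequence:
#' `g` decays by `exp(-dt/tau)` each step and jumps by the corresponding
#' weight at each spike. Returns the conductance sampled at `times`
#' (assumed sorted). Used to validate the engine's incremental state
#' against [synaptic_current()].
#'
#' @param spike_times,w as in [synaptic_current()].
#' @param times sorted evaluation grid (ms).
#' @param tau decay constant (ms).
#' @return Numeric vector of conductances at `times`.
#' @export
incremental_conductance <- function(spike_times, w, times, tau = 3.0) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  ev <- data.frame(
    t = unlist(spike_times),
    w = rep(w, lengths(spike_times)))
  ev <- ev[order(ev$t), , drop = FALSE]
  g <- 0
  t_cur <- -Inf
  k <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    tt <- times[i]
    while (k <= nrow(ev) && ev$t[k] <= tt) {
      g <- if (is.finite(t_cur)) g * exp(-(ev$t[k] - t_cur) / tau) else 0
      g <- g + ev$w[k]
      t_cur <- ev$t[k]
      k <- k + 1
    }
    out[i] <- if (is.finite(t_cur)) g * exp(-(tt - t_cur) / tau) else 0
  }
  out
}

#' Draw per-cell Poisson noise event trains
#'
#' Event times are pre-drawn from R's RNG stream (event count per cell is
#' Poisson with mean `rate * duration`, times uniform on the interval and
#' sorted), so noise is reproducible from the seed and independent across
#' cells.
#'
#' @param rate events per second per cell (Hz).
#' @param n_cells number of cells.
#' @param duration simulated interval (ms).
#' @return A list of `n_cells` sorted numeric vectors of event times (ms).
#' @export
draw_noise_events <- function(rate, n_cells, duration) {
  stopifnot(rate >= 0, duration > 0)
  if (rate == 0) return(replicate(n_cells, numeric(0), simplify = FALSE))
  counts <- rpois(n_cells, rate * duration / 1000)
  lapply(counts, function(k) sort(runif(k, 0, duration)))
}

#' Noise pulse current at a time point
#'
#' Reference evaluation of the pulse train: `amplitude` if `t` lies within
#' `pulse_width` ms after any event, else 0 (overlaps saturate).
#'
#' @param events sorted event times for one cell (ms).
#' @param t evaluation time(s), vectorized (ms).
#' @param params a [noise_params()] object.
#' @return Noise current (uA/cm^2).
#' @export
noise_current <- function(events, t, params = noise_params(rate = 1)) {
  vapply(t, function(tt) {
    if (any(events <= tt & tt < events + params$pulse_width))
      params$amplitude else 0
  }, numeric(1))
}

#' Export noise event trains as delimited text
#'
#' Two tab-separated columns `cell_id`, `time_ms`, for reproducibility
#' audits of a simulation's stochastic input.
#'
#' @param events list of per-cell event time vectors.
#' @param path output path.
#' @export
write_noise_events <- function(events, path) {
  df <- data.frame(cell_id = rep(seq_along(events), lengths(events)),
                   time_ms = unlist(events))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
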