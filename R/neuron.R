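#' Biophysical parameters of the cortical neuron model
#'
#' The cell is a Hodgkin-Huxley-type model with a fast inward Na+ current,
#' a delayed-rectifier K+ current, a leak current, and a slow, low-threshold
#' M-type K+ current whose maximal conductance `gKs` encodes the local
#' acetylcholine (ACh) level: `gKs = 0` corresponds to strong ACh modulation
#' (M-current fully blocked, high excitability, Type 1 firing onset) and
#' `gKs = 1.5` mS/cm^2 to no ACh modulation (Type 2 onset, pronounced
#' spike-frequency adaptation).
#'
#' @param gKs maximal M-current conductance (mS/cm^2). Values outside
#'   `[0, 1.5]` are permitted but trigger a warning, as they fall outside
#'   the modulation range the model was designed for.
#' @param C membrane capacitance (uF/cm^2).
#' @param gNa,gKdr,gL maximal conductances of the Na+, delayed-rectifier K+
#'   and leak currents (mS/cm^2).
#' @param VNa,VK,VL reversal potentials (mV).
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' p <- neuron_params(gKs = 0.6)
#' p$gKs
#' @export
neuron_params <- function(gKs = 1.5, C = 1, gNa = 24.0, gKdr = 3.0,
                          gL = 0.02, VNa = 55.0, VK = -90.0, VL = -60.0) {
  vals <- c(gKs = gKs, C = C, gNa = gNa, gKdr = gKdr, gL = gL,
            VNa = VNa, VK = VK, VL = VL)
  if (any(!is.finite(vals)))
    stop("all neuron parameters must be finite")
  if (any(c(gKs, gNa, gKdr, gL) < 0))
    stop("conductances must be non-negative")
  if (gKs < 0 || gKs > 1.5)
    warning("gKs = ", gKs, " mS/cm^2 is outside the modeled ACh range [0, 1.5]")
  structure(list(gKs = gKs, C = C, gNa = gNa, gKdr = gKdr, gL = gL,
                 VNa = VNa, VK = VK, VL = VL),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Cortical neuron parameters (mS/cm^2, mV, uF/cm^2):\n")
  cat(sprintf("  gNa = %g, gKdr = %g, gKs = %g (ACh level), gL = %g\n",
              x$gNa, x$gKdr, x$gKs, x$gL))
  cat(sprintf("  VNa = %g, VK = %g, VL = %g, C = %g\n", x$VNa, x$VK, x$VL, x$C))
  invisible(x)
}

#' Steady-state activation/inactivation curves of the gating variables
#'
#' Logistic steady states for the instantaneous Na+ activation `m`, Na+
#' inactivation `h`, delayed-rectifier activation `n`, and the M-current
#' gate `z`. Midpoints are at -30 (m), -53 (h), -30 (n) and -39 (z) mV
#' with slope factors 9.5, 7, 10 and 5 mV; `m`, `n`, `z` increase with
#' voltage, `h` decreases.
#'
#' @param V membrane potential (mV), vectorized.
#' @return A list with numeric components `m`, `h`, `n`, `z` in (0, 1).
#' @examples
#' steady_state_gates(-30)$m  # 0.5 at the activation midpoint
#' @export
steady_state_gates <- function(V) {
  stopifnot(is.numeric(V), all(is.finite(V)))
  list(m = 1 / (1 + exp(-(V + 30) / 9.5)),
       h = 1 / (1 + exp((V + 53) / 7)),
       n = 1 / (1 + exp(-(V + 30) / 10)),
       z = 1 / (1 + exp(-(V + 39) / 5)))
}

#' Relaxation time constants of the gating variables
#'
#' `tau_h` and `tau_n` are voltage dependent (logistic plus a floor of
#' 0.37 ms); the M-current gate `z` relaxes with a fixed 75 ms time
#' constant, which is what makes the adaptation current slow relative to
#' the spike generating currents.
#'
#' @param V membrane potential (mV), vectorized.
#' @return A list with components `tau_h`, `tau_n`, `tau_z` (ms).
#' @export
gate_time_constants <- function(V) {
  stopifnot(is.numeric(V), all(is.finite(V)))
  list(tau_h = 0.37 + 2.78 / (1 + exp((V + 40.5) / 6)),
       tau_n = 0.37 + 1.85 / (1 + exp((V + 27) / 15)),
       tau_z = rep(75.0, length(V)))
}

#' Right-hand side of the membrane current-balance equation
#'
#' Evaluates the time derivatives of the membrane potential and the three
#' dynamic gates at a given state. The membrane equation is
#' \deqn{C dV/dt = -gNa m_\infty^3 h (V - VNa) - gKdr n^4 (V - VK)
#'   - gKs z (V - VK) - gL (V - VL) + I_{drive} - I_{syn} + I_{noise}}
#'
#' @param state a list with numeric fields `V`, `h`, `n`, `z`.
#' @param params a [neuron_params()] object.
#' @param I_drive constant depolarizing/hyperpolarizing drive (uA/cm^2).
#' @param I_syn total synaptic current (uA/cm^2, positive = hyperpolarizing,
#'   entering the balance with a minus sign).
#' @param I_noise noise pulse current (uA/cm^2, positive = depolarizing).
#' @return A list with `dV` (mV/ms) and `dh`, `dn`, `dz` (1/ms).
#' @export
membrane_rhs <- function(state, params, I_drive = 0, I_syn = 0, I_noise = 0) {
  stopifnot(inherits(params, "neuron_params"))
  V <- state$V
  ss <- steady_state_gates(V)
  tc <- gate_time_constants(V)
  dV <- (-params$gNa * ss$m^3 * state$h * (V - params$VNa) -
           params$gKdr * state$n^4 * (V - params$VK) -
           params$gKs * state$z * (V - params$VK) -
           params$gL * (V - params$VL) +
           I_drive - I_syn + I_noise) / params$C
  list(dV = dV,
       dh = (ss$h - state$h) / tc$tau_h,
       dn = (ss$n - state$n) / tc$tau_n,
       dz = (ss$z - state$z) / tc$tau_z)
}

#' Simulate an isolated neuron under constant current drive
#'
#' Fixed-step integration (exponential update for the gates, explicit update
#' for V). Spikes are upward crossings of -20 mV with a 2 ms lockout; the
#' model's spikes overshoot 0 mV, so any threshold in \[-20, 0\] detects the
#' same events.
#'
#' @param params a [neuron_params()] object.
#' @param I_drive constant input current (uA/cm^2).
#' @param duration simulation length (ms).
#' @param dt integration step (ms), default 0.05.
#' @param v0 initial membrane potential (mV); gates start at their steady
#'   state for `v0`.
#' @param record_traces if `TRUE`, also return `V(t)`, `z(t)` and the
#'   instantaneous adaptation conductance `gKs * z(t)` on the grid.
#' @return A list with `spikes` (spike times, ms) and, if requested,
#'   `time`, `V`, `z`, `gKs_z`.
#' @examples
#' sim <- simulate_neuron(neuron_params(gKs = 1.5), I_drive = 1.5,
#'                        duration = 500)
#' diff(sim$spikes)  # inter-spike intervals lengthen: adaptation
#' @export
simulate_neuron <- function(params, I_drive, duration, dt = 0.05,
                            v0 = -70, record_traces = FALSE) {
  stopifnot(inherits(params, "neuron_params"), duration > 0, dt > 0)
  if (!is.finite(I_drive)) stop("I_drive must be finite")
  out <- run_neuron_cpp(params$gKs, I_drive, params$C, params$gNa,
                        params$gKdr, params$gL, params$VNa, params$VK,
                        params$VL, v0, duration, dt,
                        v_thresh = -20, lockout = 2,
                        record_traces = record_traces)
  res <- list(spikes = out$spikes)
  if (record_traces) {
    res$time <- seq(0, by = dt, length.out = length(out$V))
    res$V <- out$V
    res$z <- out$z
    res$gKs_z <- params$gKs * out$z
  }
  res
}

#' Frequency-current (f-I) curve
#'
#' Steady-state firing frequency as a function of injected current, after
#' discarding an initial adaptation transient. With `gKs = 0` (high ACh)
#' the onset of firing is continuous from zero frequency (Type 1
#' excitability); with `gKs = 1.5` (no ACh) firing starts discontinuously
#' at a nonzero frequency (Type 2) and the curve is flatter (lower gain).
#'
#' @param params a [neuron_params()] object.
#' @param I_values injected currents to probe (uA/cm^2).
#' @param duration per-current simulation length (ms), default 2000.
#' @param dt integration step (ms).
#' @param discard initial transient discarded from the rate estimate (ms),
#'   default 500.
#' @return A data frame with columns `I` and `freq` (Hz); the analysis
#'   window is recorded in `attr(, "window_ms")`.
#' @export
fi_curve <- function(params, I_values, duration = 2000, dt = 0.05,
                     discard = 500) {
  stopifnot(duration > discard)
  freq <- vapply(I_values, function(I) {
    sp <- simulate_neuron(params, I, duration, dt)$spikes
    sp <- sp[sp > discard]
    1000 * length(sp) / (duration - discard)
  }, numeric(1))
  out <- data.frame(I = I_values, freq = freq)
  attr(out, "window_ms") <- c(discard, duration)
  out
}
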