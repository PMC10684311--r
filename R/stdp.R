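#' Parameters of the asymmetric pair-based STDP rule
#'
#' Potentiation for post-after-pre pairs decays with `tau_plus`; depression
#' for pre-after-post pairs decays with `tau_minus`, with maximal
#' amplitudes `A_plus` and `A_minus`. Weights are hard-bounded to
#' `[w_min, w_max]`. The rule is applied only to the inter-module E-to-E
#' synapses; intra-module weights are fixed.
#'
#' @param A_plus,A_minus maximal potentiation / depression increments
#'   (mS/cm^2).
#' @param tau_plus,tau_minus decay constants of the potentiation /
#'   depression windows (ms).
#' @param w_min,w_max hard weight bounds (mS/cm^2).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(A_plus = 0.0025, A_minus = 0.00125,
                        tau_plus = 14, tau_minus = 34,
                        w_min = 0, w_max = 0.01) {
  stopifnot(A_plus >= 0, A_minus >= 0, tau_plus > 0, tau_minus > 0,
            w_min <= w_max)
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max),
            class = "stdp_params")
}

#' STDP weight change for a single spike pair
#'
#' The asymmetric exponential kernel as a function of the post-minus-pre
#' spike time difference `delta_t`:
#' \deqn{\Delta w = A_+ e^{-\Delta t/\tau_+} \textrm{ if } \Delta t \ge 0;
#'   \quad -A_- e^{\Delta t/\tau_-} \textrm{ if } \Delta t < 0.}
#' `delta_t = 0` falls on the potentiation branch.
#'
#' @param delta_t post-minus-pre spike time difference (ms), vectorized.
#' @param params an [stdp_params()] object.
#' @return Weight change (mS/cm^2).
#' @examples
#' pair_delta_w(0)     #  0.0025 (maximal potentiation)
#' pair_delta_w(-1e-9) # -0.00125 in the limit (maximal depression)
#' @export
pair_delta_w <- function(delta_t, params = stdp_params()) {
  stopifnot(all(is.finite(delta_t)))
  ifelse(delta_t >= 0,
         params$A_plus * exp(-delta_t / params$tau_plus),
         -params$A_minus * exp(delta_t / params$tau_minus))
}

#' Clip a synaptic weight to the STDP bounds
#'
#' @param w weight(s) (mS/cm^2).
#' @param params an [stdp_params()] object.
#' @return `min(max(w, w_min), w_max)`.
#' @export
clip_weight <- function(w, params = stdp_params()) {
  pmin(pmax(w, params$w_min), params$w_max)
}

#' Apply STDP to a pre/post spike-train pair
#'
#' Online trace-based realization of the pair rule for one synapse: each
#' presynaptic spike depresses the weight by `A_minus` times the
#' postsynaptic eligibility trace and increments the presynaptic trace;
#' each postsynaptic spike potentiates by `A_plus` times the presynaptic
#' trace and increments the postsynaptic trace. With `pairing = "all"`
#' (default, traces accumulate) the cumulative change equals the explicit
#' sum of the kernel over all spike pairs; `pairing = "nearest"` resets
#' traces to 1 at each spike so only nearest-neighbour pairs interact.
#' Simultaneous pre/post spikes are processed as post-after-pre, taking
#' the `delta_t = 0` potentiation branch. Clipping to `[w_min, w_max]` is
#' applied after every update.
#'
#' @param pre,post spike time vectors (ms), each sorted increasing.
#' @param w0 initial weight (mS/cm^2).
#' @param params an [stdp_params()] object.
#' @param pairing `"all"` (all-pairs) or `"nearest"` (nearest-neighbour).
#' @return Final weight (mS/cm^2).
#' @examples
#' p <- stdp_params(w_max = Inf, w_min = -Inf)
#' stdp_trains(pre = 10, post = 24, w0 = 0) # equals pair_delta_w(14)
#' @export
stdp_trains <- function(pre, post, w0 = 0.005, params = stdp_params(),
                        pairing = c("all", "nearest")) {
  pairing <- match.arg(pairing)
  if (is.unsorted(pre) || is.unsorted(post))
    stop("spike trains must be sorted in time")
  ev <- data.frame(t = c(pre, post),
                   kind = rep(1:2, c(length(pre), length(post))))
  # stable sort; at equal times pre (kind 1) processed before post (kind 2)
  ev <- ev[order(ev$t, ev$kind), , drop = FALSE]
  w <- w0
  x_pre <- 0   # decays with tau_plus
  x_post <- 0  # decays with tau_minus
  t_last <- -Inf
  for (i in seq_len(nrow(ev))) {
    tt <- ev$t[i]
    if (is.finite(t_last)) {
      x_pre <- x_pre * exp(-(tt - t_last) / params$tau_plus)
      x_post <- x_post * exp(-(tt - t_last) / params$tau_minus)
    }
    t_last <- tt
    if (ev$kind[i] == 1L) {
      w <- clip_weight(w - params$A_minus * x_post, params)
      x_pre <- if (pairing == "all") x_pre + 1 else 1
    } else {
      w <- clip_weight(w + params$A_plus * x_pre, params)
      x_post <- if (pairing == "all") x_post + 1 else 1
    }
  }
  w
}
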