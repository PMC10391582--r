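#' Create a plasticity trace state
#'
#' Each excitatory neuron carries a fast trace `z` (time constant
#' `tau_stdp`) and a slow trace `z_slow` (`tau_stdp_slow`); both gain +1 at
#' every spike of their own neuron and decay exponentially to zero.
#'
#' @param n number of neurons tracked.
#' @param params a [plasticity_params()].
#' @return a list of class `trace_state` with vectors `z`, `z_slow`.
#' @export
trace_state <- function(n = 1, params = plasticity_params()) {
  structure(list(z = numeric(n), z_slow = numeric(n), params = params),
            class = "trace_state")
}

#' Advance plasticity traces by one interval, then register spikes
#'
#' Exponential decay over `dt` followed by a +1 increment for every spiking
#' neuron.
#'
#' @param traces a [trace_state()].
#' @param spikes indices of neurons that spiked at the end of the interval
#'   (may be empty).
#' @param dt elapsed time, ms.
#' @return the updated `trace_state`.
#' @export
trace_update <- function(traces, spikes = integer(0), dt = 0) {
  stopifnot(dt >= 0)
  p <- traces$params
  traces$z <- traces$z * exp(-dt / p$tau_stdp)
  traces$z_slow <- traces$z_slow * exp(-dt / p$tau_stdp_slow)
  if (length(spikes)) {
    traces$z[spikes] <- traces$z[spikes] + 1
    traces$z_slow[spikes] <- traces$z_slow[spikes] + 1
  }
  traces
}

clamp_weight <- function(w, params) {
  w <- pmax(w, params$w_min)
  if (!is.na(params$w_max)) w <- pmin(w, params$w_max)
  w
}

#' Weight update at a presynaptic spike
#'
#' Doublet depression plus transmitter-induced potentiation:
#' `w' = clamp(w - B * z_post + delta1)`, with the postsynaptic fast trace
#' taken at its value before the spike registers.
#'
#' @param w current weight(s).
#' @param z_post postsynaptic fast trace(s), pre-update.
#' @param params a [plasticity_params()].
#' @return updated weight(s), floored at `w_min`.
#' @export
on_pre_spike <- function(w, z_post, params = plasticity_params()) {
  clamp_weight(w - params$B * z_post + params$delta1, params)
}

#' Weight update at a postsynaptic spike
#'
#' Triplet potentiation plus heterosynaptic stabilisation:
#' `w' = clamp(w + A * z_pre * z_slow_post
#'             - beta * z_post^3 * ((w - w_tilde)/w_tilde)^3)`,
#' with all traces at their pre-update values. The cubic term restores
#' weights toward `w_tilde`: negative above it, positive below.
#'
#' @param w current weight(s).
#' @param z_pre presynaptic fast trace(s).
#' @param z_post_slow postsynaptic slow trace(s).
#' @param z_post postsynaptic fast trace(s).
#' @param params a [plasticity_params()].
#' @return updated weight(s), floored at `w_min`.
#' @export
on_post_spike <- function(w, z_pre, z_post_slow, z_post,
                          params = plasticity_params()) {
  het <- params$beta * z_post^3 * ((w - params$w_tilde) / params$w_tilde)^3
  clamp_weight(w + params$A * z_pre * z_post_slow - het, params)
}
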