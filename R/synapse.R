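#' Bi-exponential receptor kernel
#'
#' Value of the conductance kernel
#' \deqn{S_R(t) = \mu \Theta(t-\tau_l)/(\tau_d-\tau_r)
#'  (e^{-(t-\tau_l)/\tau_d} - e^{-(t-\tau_l)/\tau_r})}
#' at time `t` (ms) after a presynaptic spike. Zero before the latency,
#' strictly positive afterwards; the time integral equals `mu`. When the two
#' time constants coincide to within 1e-9 ms the analytic alpha-function
#' limit \eqn{\mu (t-\tau_l)/\tau^2 e^{-(t-\tau_l)/\tau}} is used.
#'
#' @param t time since the presynaptic spike, ms (vectorised).
#' @param tau_r,tau_d rise and decay time constants, ms.
#' @param mu kernel amplitude (integral).
#' @param latency transmission latency, ms.
#' @return kernel values, same length as `t`.
#' @export
kernel_value <- function(t, tau_r, tau_d, mu = 1, latency = 0) {
  s <- t - latency
  out <- numeric(length(s))
  on <- s >= 0 & is.finite(s)
  if (abs(tau_d - tau_r) < 1e-9) {
    tau <- (tau_d + tau_r) / 2
    out[on] <- mu * s[on] / tau^2 * exp(-s[on] / tau)
  } else {
    out[on] <- mu / (tau_d - tau_r) *
      (exp(-s[on] / tau_d) - exp(-s[on] / tau_r))
  }
  out
}

#' Direct conductance trace from a spike train
#'
#' Sums the receptor kernel over all past spikes,
#' `G(t) = w * sum_n S_R(t - t_n)`, evaluating the closed form directly.
#' This is the reference path against which the simulator's exact
#' two-exponential recursion is verified; it is also convenient for plotting
#' single-synapse responses.
#'
#' @param t evaluation times, ms.
#' @param spike_times presynaptic spike times, ms.
#' @param tau_r,tau_d,mu,latency kernel parameters, see [kernel_value()].
#' @param weight synaptic weight multiplying the kernel.
#' @return conductance values at `t`.
#' @export
conductance_trace <- function(t, spike_times, tau_r, tau_d, mu = 1,
                              latency = 0, weight = 1) {
  vapply(t, function(ti)
    weight * sum(kernel_value(ti - spike_times, tau_r, tau_d, mu, latency)),
    numeric(1))
}

#' Peak time of the receptor kernel
#'
#' @param tau_r,tau_d rise and decay time constants, ms.
#' @param latency transmission latency, ms.
#' @return the time (ms after the spike) at which the kernel is maximal:
#'   `latency + tau_d*tau_r/(tau_d - tau_r) * log(tau_d/tau_r)`.
#' @export
kernel_peak_time <- function(tau_r, tau_d, latency = 0) {
  if (abs(tau_d - tau_r) < 1e-9) return(latency + tau_d)
  latency + tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Create a short-term plasticity state
#'
#' @param n number of presynaptic neurons tracked.
#' @param params an [stp_params()].
#' @return a list of class `stp_state` with vectors `u` (release
#'   probability, initialised at `U`) and `x` (resource, initialised at 1).
#' @export
stp_state <- function(n = 1, params = stp_params()) {
  structure(list(u = rep(params$U, n), x = rep(1, n), params = params),
            class = "stp_state")
}

#' Apply a presynaptic spike to the short-term plasticity state
#'
#' Facilitation is applied before release: `u <- u + U (1 - u)`, then the
#' released fraction `u_new * x` is returned and subtracted from `x`. The
#' release factor scales the conductance increment of the ensuing kernel.
#'
#' @param state an [stp_state()].
#' @param which indices of the spiking neurons (default all).
#' @return list with the updated `state` and the `release` factors.
#' @export
stp_on_spike <- function(state, which = seq_along(state$u)) {
  U <- state$params$U
  state$u[which] <- state$u[which] + U * (1 - state$u[which])
  release <- state$u[which] * state$x[which]
  state$x[which] <- state$x[which] - release
  list(state = state, release = release)
}

#' Relax the short-term plasticity state over a silent interval
#'
#' Exact exponential relaxation of `u` toward `U` (time constant `tau_F`)
#' and of `x` toward 1 (time constant `tau_D`).
#'
#' @param state an [stp_state()].
#' @param dt elapsed time, ms.
#' @return the relaxed `stp_state`.
#' @export
stp_decay <- function(state, dt) {
  stopifnot(dt >= 0)
  p <- state$params
  state$u <- p$U + (state$u - p$U) * exp(-dt / p$tau_F)
  state$x <- 1 + (state$x - 1) * exp(-dt / p$tau_D)
  state
}
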