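#' Membrane parameters of the integrate-and-fire neurons
#'
#' Conductance-based leaky integrate-and-fire dynamics
#' \deqn{\tau_k dV/dt = V_L - V + G^E (E_E - V) + G^I (E_I - V)}
#' for neuron types k in {E, I}. Values follow the conductance-based E-I
#' circuit family these models derive from and are fully configurable.
#'
#' @param tau_E,tau_I membrane time constants (ms) of excitatory and
#'   inhibitory neurons.
#' @param V_L leak (resting) potential, mV.
#' @param V_th spike threshold, mV.
#' @param V_reset post-spike reset potential, mV.
#' @param E_E,E_I excitatory and inhibitory reversal potentials, mV.
#' @param t_ref absolute refractory period, ms.
#' @return a named list of class `neuron_params`.
#' @export
neuron_params <- function(tau_E = 20, tau_I = 10, V_L = -70, V_th = -50,
                          V_reset = -60, E_E = 0, E_I = -80, t_ref = 2) {
  stopifnot(tau_E > 0, tau_I > 0, t_ref >= 0,
            E_I < V_L, V_L < V_th, V_th < E_E)
  structure(list(tau_E = tau_E, tau_I = tau_I, V_L = V_L, V_th = V_th,
                 V_reset = V_reset, E_E = E_E, E_I = E_I, t_ref = t_ref),
            class = "neuron_params")
}

#' Receptor kernel parameters
#'
#' Each receptor class (AMPA, NMDA, GABA) contributes a bi-exponential
#' conductance kernel
#' \deqn{S_R(t) = \mu_R \Theta(t-\tau_l) / (\tau_d - \tau_r)
#'   \, (e^{-(t-\tau_l)/\tau_d} - e^{-(t-\tau_l)/\tau_r})}
#' whose time integral equals \eqn{\mu_R}. A single transmission latency
#' \eqn{\tau_l} applies to all recurrent synapses.
#'
#' @param ampa,nmda,gaba lists with elements `tau_r`, `tau_d` (ms, decay >
#'   rise > 0) and `mu` (dimensionless amplitude).
#' @param latency synaptic latency \eqn{\tau_l}, ms (at least one integration
#'   step).
#' @return a named list of class `receptor_params`.
#' @export
receptor_params <- function(ampa = list(tau_r = 0.5, tau_d = 2, mu = 0.145),
                            nmda = list(tau_r = 2, tau_d = 100, mu = 0.0725),
                            gaba = list(tau_r = 0.5, tau_d = 5, mu = 0.145),
                            latency = 1) {
  for (r in list(ampa, nmda, gaba))
    stopifnot(r$tau_d > r$tau_r, r$tau_r > 0, r$mu > 0)
  stopifnot(latency >= 0)
  structure(list(ampa = ampa, nmda = nmda, gaba = gaba, latency = latency),
            class = "receptor_params")
}

#' Short-term plasticity parameters (Tsodyks-Markram)
#'
#' Presynaptic release probability u facilitates toward 1 with increment
#' U(1-u) at each spike and relaxes to U with time constant `tau_F`;
#' neurotransmitter resource x is depleted by u*x at each spike and recovers
#' to 1 with `tau_D`. The facilitation-dominated regime `tau_F >> tau_D`
#' supports persistent activity.
#'
#' @param U baseline release probability, in (0, 1].
#' @param tau_F facilitation time constant, ms.
#' @param tau_D depression (recovery) time constant, ms.
#' @return a named list of class `stp_params`.
#' @export
stp_params <- function(U = 0.2, tau_F = 1500, tau_D = 200) {
  stopifnot(U > 0, U <= 1, tau_F > 0, tau_D > 0)
  structure(list(U = U, tau_F = tau_F, tau_D = tau_D), class = "stp_params")
}

#' Long-term plasticity parameters
#'
#' Composite rule on all E-to-E synapses:
#' triplet STDP (potentiation `A * z_pre * z_slow_post` at each postsynaptic
#' spike, depression `B * z_post` at each presynaptic spike), heterosynaptic
#' stabilisation `- beta * z_post^3 * ((w - w_tilde)/w_tilde)^3` at each
#' postsynaptic spike, and transmitter-induced potentiation `delta1` at each
#' presynaptic spike. Fast traces decay with `tau_stdp`, the slow
#' postsynaptic trace with `tau_stdp_slow`; every trace gains +1 per spike of
#' its own neuron. Weights are floored at `w_min`.
#'
#' Amplitudes default to values calibrated so that, in the full learning
#' protocol at high connectivity, weights inside the learnt engram settle
#' near the preferred weight `w_tilde` (the regime where a learnt engram is
#' comparable to a preset one).
#'
#' @param A triplet potentiation amplitude.
#' @param B doublet depression amplitude.
#' @param beta heterosynaptic amplitude.
#' @param w_tilde preferred synaptic weight of the heterosynaptic term.
#' @param delta1 transmitter-induced increment per presynaptic spike.
#' @param tau_stdp fast trace time constant, ms.
#' @param tau_stdp_slow slow postsynaptic trace time constant, ms.
#' @param w_min hard lower bound on plastic weights.
#' @param w_max optional upper cap; `NA` (default) disables it, the
#'   heterosynaptic term being the intended stabiliser.
#' @return a named list of class `plasticity_params`.
#' @export
plasticity_params <- function(A = 2e-4, B = 1.2e-4, beta = 0.05,
                              w_tilde = 0.5, delta1 = 2e-5,
                              tau_stdp = 20, tau_stdp_slow = 100,
                              w_min = 0.001, w_max = NA) {
  stopifnot(A >= 0, B >= 0, beta >= 0, delta1 >= 0, w_tilde > 0,
            tau_stdp > 0, tau_stdp_slow > tau_stdp, w_min > 0)
  structure(list(A = A, B = B, beta = beta, w_tilde = w_tilde,
                 delta1 = delta1, tau_stdp = tau_stdp,
                 tau_stdp_slow = tau_stdp_slow, w_min = w_min,
                 w_max = w_max),
            class = "plasticity_params")
}

#' Network configuration
#'
#' All structural and synaptic parameters of the engram network. The default
#' geometry is the full-scale circuit (2000 E / 400 I neurons, ten
#' non-overlapping engrams of 200 excitatory neurons each); tests and desk
#' runs typically use `scaled_config()`.
#'
#' Baseline synaptic weights are assigned by pre/post type
#' (`g_EE`, `g_IE`, `g_EI`, `g_II`); synapses between two neurons of the same
#' engram are strengthened to `g_M_EE`. Each neuron receives `n_ext_trains`
#' independent background Poisson trains at `f_background` Hz through weight
#' `g_O_E` (E targets) or `g_O_I` (I targets); the trains are aggregated into
#' a single Poisson process of the summed rate, which is distributionally
#' identical.
#'
#' @param nE,nI numbers of excitatory and inhibitory neurons.
#' @param C connection probability for every ordered pair, in \[0, 1\].
#' @param n_engrams number of engrams.
#' @param engram_size excitatory neurons per engram.
#' @param g_EE,g_IE,g_EI,g_II baseline weights by (pre -> post) type:
#'   E->E, I->E, E->I, I->I.
#' @param g_M_EE intra-engram E->E weight.
#' @param g_O_E,g_O_I external-input weights onto E and I neurons.
#' @param n_ext_trains external Poisson trains per neuron.
#' @param f_background background rate per train, Hz.
#' @param seed RNG seed of the connectivity stream.
#' @param neuron,receptor,stp,plasticity parameter blocks, see
#'   [neuron_params()], [receptor_params()], [stp_params()],
#'   [plasticity_params()].
#' @return a list of class `network_config`.
#' @export
network_config <- function(nE = 2000, nI = 400, C = 0.25,
                           n_engrams = 10, engram_size = 200,
                           g_EE = 0.006, g_IE = 0.123, g_EI = 0.168,
                           g_II = 0.042, g_M_EE = 0.68,
                           g_O_E = 0.082, g_O_I = 0.172,
                           n_ext_trains = 400, f_background = 2.5,
                           seed = 1,
                           neuron = neuron_params(),
                           receptor = receptor_params(),
                           stp = stp_params(),
                           plasticity = plasticity_params()) {
  if (C < 0 || C > 1) stop("connection probability C must lie in [0, 1]")
  if (n_engrams * engram_size > nE)
    stop("engram layout overflows the excitatory population: ",
         "n_engrams * engram_size must not exceed nE")
  w <- c(g_EE, g_IE, g_EI, g_II, g_M_EE, g_O_E, g_O_I)
  if (any(w < 0)) stop("synaptic weights must be non-negative")
  stopifnot(nE >= 1, nI >= 0, n_engrams >= 0, engram_size >= 1,
            n_ext_trains >= 1, f_background >= 0)
  structure(list(nE = nE, nI = nI, C = C, n_engrams = n_engrams,
                 engram_size = engram_size,
                 g_EE = g_EE, g_IE = g_IE, g_EI = g_EI, g_II = g_II,
                 g_M_EE = g_M_EE, g_O_E = g_O_E, g_O_I = g_O_I,
                 n_ext_trains = n_ext_trains, f_background = f_background,
                 seed = seed, neuron = neuron, receptor = receptor,
                 stp = stp, plasticity = plasticity),
            class = "network_config")
}

#' Scaled-down network configuration for desk-scale runs
#'
#' The same circuit at 30% population scale (600 E / 120 I). The engram size
#' (200 neurons) and hence the intra-engram input statistics of the full
#' model are preserved; only the number of engrams and the sizes of the
#' background and inhibitory pools shrink, with the count-sensitive weights
#' (baseline E->E and everything involving the inhibitory pool) scaled up by
#' the population ratio so that per-neuron input sums match. This keeps the
#' qualitative regime of the full model: a low-rate asynchronous background
#' (< 5 spikes/s), a bistable persistent state of a cued engram at
#' C around 0.25, and loss of persistence below C of roughly 0.15.
#'
#' @param n_engrams,engram_size engram layout (default 3 engrams of 200).
#' @param C connection probability.
#' @param g_EE,g_IE,g_EI,g_II,g_M_EE,g_O_E,g_O_I calibrated scaled weights.
#' @param ... further overrides passed to [network_config()].
#' @return a `network_config`.
#' @export
scaled_config <- function(n_engrams = 3, engram_size = 200, C = 0.25,
                          g_EE = 0.02, g_IE = 0.41, g_EI = 0.56,
                          g_II = 0.14, g_M_EE = 0.68,
                          g_O_E = 0.082, g_O_I = 0.172, ...) {
  network_config(nE = 600, nI = 120, C = C,
                 n_engrams = n_engrams, engram_size = engram_size,
                 g_EE = g_EE, g_IE = g_IE, g_EI = g_EI, g_II = g_II,
                 g_M_EE = g_M_EE, g_O_E = g_O_E, g_O_I = g_O_I,
                 ...)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("engram network config: %d E + %d I neurons, C = %.3g\n",
              x$nE, x$nI, x$C))
  cat(sprintf("  engrams: %d x %d neurons (g_M_EE = %.3g, baseline g_EE = %.3g)\n",
              x$n_engrams, x$engram_size, x$g_M_EE, x$g_EE))
  cat(sprintf("  background: %d trains x %.3g Hz per neuron\n",
              x$n_ext_trains, x$f_background))
  invisible(x)
}
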