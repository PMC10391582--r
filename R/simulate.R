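#' Piecewise-constant external drive schedule
#'
#' Background external input plus additive rate windows (cues, learning
#' signals). Rates are given per external train; each neuron receives
#' `n_ext_trains` independent trains, aggregated into one Poisson process of
#' the summed rate.
#'
#' @param graph an `engram_graph`.
#' @param duration_ms total simulated time, ms.
#' @param f_E,f_I background rate per train for excitatory / inhibitory
#'   neurons, Hz (default the config background for both).
#' @param windows list of additive windows, each a list with `start_ms`,
#'   `end_ms`, `neurons` (ids) and `add_hz` (extra per-train rate).
#' @return a list of class `drive_schedule` with `block_end` (ms) and `rate`
#'   (neurons x blocks matrix of aggregated rates, Hz).
#' @export
make_drive <- function(graph, duration_ms, f_E = NULL, f_I = NULL,
                       windows = list()) {
  cfg <- graph$config
  if (is.null(f_E)) f_E <- cfg$f_background
  if (is.null(f_I)) f_I <- cfg$f_background
  stopifnot(f_E >= 0, f_I >= 0)
  n <- n_neurons(graph)
  bounds <- sort(unique(c(
    unlist(lapply(windows, function(w) c(w$start_ms, w$end_ms))),
    duration_ms)))
  bounds <- bounds[bounds > 0 & bounds <= duration_ms]
  if (!length(bounds) || max(bounds) < duration_ms)
    bounds <- c(bounds, duration_ms)
  base <- ifelse(graph$type == "E", f_E, f_I) * cfg$n_ext_trains
  rate <- matrix(base, nrow = n, ncol = length(bounds))
  starts <- c(0, bounds[-length(bounds)])
  for (w in windows) {
    if (w$add_hz < 0) stop("window rates must be non-negative")
    blk <- which(starts >= w$start_ms - 1e-9 & bounds <= w$end_ms + 1e-9)
    rate[w$neurons, blk] <- rate[w$neurons, blk] + w$add_hz * cfg$n_ext_trains
  }
  structure(list(block_end = bounds, rate = rate), class = "drive_schedule")
}

#' Rescue stimulation specification
#'
#' Duty-cycled membrane resets abstracting optogenetic suppression of
#' interneurons: during the on-phase of each cycle, every targeted
#' inhibitory neuron that is not refractory is reset to the leak potential
#' independently with probability `prob` per integration step.
#'
#' @param frequency_hz stimulation frequency, Hz (10-120 in the protocols).
#' @param duty on-fraction of each cycle, in (0, 1).
#' @param fraction fraction of inhibitory neurons targeted (chosen at random
#'   once, at simulation start).
#' @param prob per-step reset probability during the on-phase.
#' @param start_ms stimulation onset (default after the 5 s transient).
#' @return a list of class `rescue_spec`.
#' @export
rescue_spec <- function(frequency_hz = 40, duty = 0.5, fraction = 0.5,
                        prob = 0.5, start_ms = 5000) {
  stopifnot(frequency_hz > 0, duty > 0, duty < 1,
            fraction > 0, fraction <= 1, prob >= 0, prob <= 1)
  structure(list(frequency_hz = frequency_hz, duty = duty,
                 fraction = fraction, prob = prob, start_ms = start_ms),
            class = "rescue_spec")
}

#' Simulate the network
#'
#' Clock-driven integration of the full model (membrane dynamics, receptor
#' kernels, short-term plasticity, optional long-term plasticity and rescue
#' stimulation) at a fixed step, with threshold crossings located by linear
#' interpolation within the step.
#'
#' @param graph an `engram_graph`.
#' @param duration_ms simulated time, ms.
#' @param drive a [make_drive()] schedule (default: background only).
#' @param rescue optional [rescue_spec()].
#' @param plasticity_window optional `c(start_ms, end_ms)` during which the
#'   long-term rule updates all E->E weights; outside it weights are frozen.
#' @param snapshot_ms cadence of weight snapshots while plasticity is
#'   enabled, ms.
#' @param record_traces record 1 ms-resolution population traces (mean E
#'   membrane potential, mean excitatory and inhibitory currents onto E
#'   neurons)?
#' @param dt integration step, ms.
#' @param seed seed of the input/rescue RNG streams (independent of the
#'   connectivity seed).
#' @return an object of class `engram_sim`: list with `raster` (data frame
#'   `time_ms`, `neuron`), `traces` (data frame `time_ms`, `mean_V_E`,
#'   `exc_current`, `inh_current`), `weights` (final edge table), and, when
#'   plasticity was on, `snapshots` (`time_ms`, per-engram mean intra-engram
#'   weight, global minimum plastic weight).
#' @export
simulate_network <- function(graph, duration_ms, drive = NULL,
                             rescue = NULL, plasticity_window = NULL,
                             snapshot_ms = 1000, record_traces = TRUE,
                             dt = 0.05, seed = 1) {
  stopifnot(inherits(graph, "engram_graph"), duration_ms > 0, dt > 0)
  cfg <- graph$config
  n <- n_neurons(graph)
  if (is.null(drive)) drive <- make_drive(graph, duration_ms)
  stopifnot(inherits(drive, "drive_schedule"), nrow(drive$rate) == n)

  e <- graph$edges
  ord <- order(e$pre, e$post)
  e <- e[ord, , drop = FALSE]
  edge_ptr <- c(0L, cumsum(tabulate(e$pre, nbins = n)))
  plastic <- as.integer(e$plastic)

  # incoming plastic edges grouped by postsynaptic neuron
  pl_idx <- which(e$plastic)
  po <- order(e$post[pl_idx])
  pl_idx <- pl_idx[po]
  in_ptr <- c(0L, cumsum(tabulate(e$post[pl_idx], nbins = n)))

  # snapshot groups: intra-engram E->E edges, by engram
  grp <- integer(nrow(e))
  same <- !is.na(e$engram_pre) & !is.na(e$engram_post) &
    e$engram_pre == e$engram_post & e$plastic
  grp[same] <- e$engram_pre[same]
  n_groups <- max(1L, cfg$n_engrams)

  resc <- list(enabled = FALSE)
  if (!is.null(rescue)) {
    stopifnot(inherits(rescue, "rescue_spec"))
    inh <- which(graph$type == "I")
    set.seed(seed + 7L)
    chosen <- sort(sample(inh, round(rescue$fraction * length(inh))))
    period <- 1000 / rescue$frequency_hz
    resc <- list(enabled = TRUE, period_ms = period,
                 on_ms = rescue$duty * period, start_ms = rescue$start_ms,
                 prob = rescue$prob, chosen = as.integer(chosen - 1L))
  }

  pl <- list(enabled = FALSE)
  if (!is.null(plasticity_window)) {
    p <- cfg$plasticity
    pl <- list(enabled = TRUE, t_start = plasticity_window[1],
               t_end = plasticity_window[2],
               A = p$A, B = p$B, beta = p$beta, w_tilde = p$w_tilde,
               delta1 = p$delta1, tau_stdp = p$tau_stdp,
               tau_stdp_slow = p$tau_stdp_slow, w_min = p$w_min,
               w_max = if (is.na(p$w_max)) -1 else p$w_max,
               snapshot_ms = snapshot_ms)
  }

  is_e <- as.integer(graph$type == "E")
  g_O <- ifelse(graph$type == "E", cfg$g_O_E, cfg$g_O_I)

  res <- .sim_core(n, is_e, edge_ptr, as.integer(e$post - 1L), e$weight,
                   plastic, in_ptr, as.integer(pl_idx - 1L),
                   as.integer(e$pre[pl_idx] - 1L),
                   unclass(cfg$neuron), unclass(cfg$receptor),
                   unclass(cfg$stp),
                   drive$block_end, drive$rate, g_O,
                   resc, pl, grp, n_groups,
                   duration_ms, dt, record_traces, as.integer(seed))

  out <- list(
    raster = data.frame(time_ms = res$spike_t, neuron = res$spike_id + 1L),
    duration_ms = duration_ms, graph_config = cfg, seed = seed)
  if (record_traces) {
    tr <- res$traces
    out$traces <- data.frame(time_ms = tr[, 1], mean_V_E = tr[, 2],
                             exc_current = tr[, 3], inh_current = tr[, 4])
  }
  e$weight <- res$weights
  out$weights <- e
  if (!is.null(plasticity_window)) {
    sm <- res$snapshot_mean
    colnames(sm) <- paste0("engram_", seq_len(ncol(sm)))
    out$snapshots <- data.frame(time_ms = res$snapshot_t, sm,
                                min_weight = res$snapshot_min)
  }
  class(out) <- "engram_sim"
  out
}

#' @export
print.engram_sim <- function(x, ...) {
  cat(sprintf("engram_sim: %.3g s, %d spikes from %d neurons\n",
              x$duration_ms / 1000, nrow(x$raster),
              length(unique(x$raster$neuron))))
  invisible(x)
}

#' Sample aggregated external Poisson events
#'
#' The background input of each neuron is `n_ext_trains` independent Poisson
#' trains, simulated as one Poisson process of the summed rate (identical in
#' distribution). This helper draws such an aggregated event train, as used
#' for the external drive inside the simulator.
#'
#' @param rate_hz aggregated rate (trains x per-train rate), Hz.
#' @param duration_ms span, ms.
#' @param seed RNG seed.
#' @return sorted event times, ms.
#' @export
sample_external_events <- function(rate_hz, duration_ms, seed = 1) {
  stopifnot(rate_hz >= 0, duration_ms > 0)
  if (rate_hz == 0) return(numeric(0))
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_ms / 1000)
  sort(runif(n, 0, duration_ms))
}
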