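#' Simulate one plastic synapse between two imposed Poisson neurons
#'
#' The two-neuron laboratory: presynaptic and postsynaptic spike trains are
#' drawn as independent homogeneous Poisson processes (firing is imposed, so
#' the membrane model and the causal effect of the synapse on postsynaptic
#' firing are bypassed), and the composite long-term plasticity rule is
#' applied to the single weight for the whole duration. Optionally both
#' trains are passed through [burstify()] first.
#'
#' Two numerically distinct integration paths are available: `"event"`
#' advances the traces analytically between spikes; `"clock"` steps them at
#' `dt` with exact per-step exponential decay. They agree to floating-point
#' accuracy and serve as mutual checks.
#'
#' @param pre_rate,post_rate firing rates, Hz.
#' @param duration_s duration, s.
#' @param params a [plasticity_params()].
#' @param w0 initial weight.
#' @param p_pick burst-manipulation pick probability applied to both trains
#'   (0 = none).
#' @param seed RNG seed.
#' @param method `"event"` (default) or `"clock"`.
#' @param dt clock step, ms.
#' @param record_s trajectory cadence, s.
#' @return list of class `pair_experiment` with `w_final`, `trajectory`
#'   (data frame `time_s`, `w`), and the generated `pre`/`post` trains (ms).
#' @export
simulate_pair <- function(pre_rate, post_rate, duration_s = 100,
                          params = plasticity_params(), w0 = 0.02,
                          p_pick = 0, seed = 1, method = c("event", "clock"),
                          dt = 0.05, record_s = 1) {
  method <- match.arg(method)
  stopifnot(pre_rate >= 0, post_rate >= 0, duration_s > 0)
  set.seed(seed)
  span <- duration_s * 1000
  pre <- poisson_train(pre_rate, span)
  post <- poisson_train(post_rate, span)
  if (p_pick > 0) {
    pre <- burstify(pre, p_pick, seed = seed + 1L)
    post <- burstify(post, p_pick, seed = seed + 2L)
  }
  # event times live on the integration grid (0.05 ms resolution), making
  # the event-based and clock-driven paths exactly comparable
  pre <- unname(round(pre / dt) * dt)
  post <- unname(round(post / dt) * dt)

  ev <- rbind(
    if (length(pre)) cbind(pre, 0) else NULL,
    if (length(post)) cbind(post, 1) else NULL)
  w <- w0
  rec_t <- seq(0, span, by = record_s * 1000)
  rec_w <- numeric(length(rec_t)); rec_w[1] <- w0
  if (!is.null(ev) && nrow(ev)) {
    # pre before post at ties
    ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
    z_pre <- z_post <- z_slow <- 0
    tprev <- 0
    ri <- 2
    step_traces <- function(from, to) {
      if (method == "event") {
        d <- to - from
        z_pre <<- z_pre * exp(-d / params$tau_stdp)
        z_post <<- z_post * exp(-d / params$tau_stdp)
        z_slow <<- z_slow * exp(-d / params$tau_stdp_slow)
      } else {
        n_steps <- round(to / dt) - round(from / dt)
        if (n_steps > 0) {
          z_pre <<- z_pre * exp(-dt / params$tau_stdp)^n_steps
          z_post <<- z_post * exp(-dt / params$tau_stdp)^n_steps
          z_slow <<- z_slow * exp(-dt / params$tau_stdp_slow)^n_steps
        }
      }
    }
    for (i in seq_len(nrow(ev))) {
      tnow <- ev[i, 1]
      while (ri <= length(rec_t) && rec_t[ri] <= tnow) {
        rec_w[ri] <- w; ri <- ri + 1
      }
      step_traces(tprev, tnow)
      tprev <- tnow
      if (ev[i, 2] == 0) {          # presynaptic spike
        w <- on_pre_spike(w, z_post, params)
        z_pre <- z_pre + 1
      } else {                      # postsynaptic spike
        w <- on_post_spike(w, z_pre, z_slow, z_post, params)
        z_post <- z_post + 1
        z_slow <- z_slow + 1
      }
    }
    if (ri <= length(rec_t)) rec_w[ri:length(rec_t)] <- w
  } else rec_w[] <- w0

  structure(list(w_final = unname(w), pre = pre, post = post,
                 trajectory = data.frame(time_s = rec_t / 1000, w = rec_w)),
            class = "pair_experiment")
}

poisson_train <- function(rate_hz, span_ms) {
  if (rate_hz <= 0) return(numeric(0))
  n <- rpois(1, rate_hz * span_ms / 1000)
  sort(runif(n, 0, span_ms))
}

#' Burst manipulation of a spike train
#'
#' Each spike is picked independently with probability `p_pick`; two new
#' spikes are appended 2 ms and 4 ms after every picked spike (collisions
#' with existing spikes are moved to the next free 0.05 ms slot), then twice
#' the number of picked spikes are removed uniformly at random from the
#' augmented train, so the total spike count is conserved while the train
#' becomes burstier (2-3 spike bursts), raising its CV_ISI.
#'
#' @param train spike times, ms.
#' @param p_pick pick probability in \[0, 1\].
#' @param seed RNG seed.
#' @param resolution time grid for collision resolution, ms.
#' @return the manipulated train (same length as the input), sorted.
#' @export
burstify <- function(train, p_pick, seed = 1, resolution = 0.05) {
  stopifnot(p_pick >= 0, p_pick <= 1)
  if (!length(train) || p_pick == 0) return(sort(train))
  set.seed(seed)
  grid <- round(sort(train) / resolution)
  picked <- which(runif(length(grid)) < p_pick)
  n_pick <- length(picked)
  if (n_pick == 0) return(sort(train))
  occupied <- new.env(hash = TRUE)
  for (g in grid) assign(as.character(g), TRUE, envir = occupied)
  added <- integer(0)
  for (p in picked) {
    for (off in c(2, 4) / resolution) {
      slot <- grid[p] + off
      while (exists(as.character(slot), envir = occupied)) slot <- slot + 1
      assign(as.character(slot), TRUE, envir = occupied)
      added <- c(added, slot)
    }
  }
  aug <- c(grid, added)
  drop <- sample(length(aug), 2 * n_pick)
  sort(aug[-drop]) * resolution
}
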