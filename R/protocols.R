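#' Sequential cue schedule
#'
#' Engrams are cued one after another: after a warmup, engram k receives an
#' additional external cue of `f_cue` Hz per train for `cue_s` seconds,
#' followed by a `gap_s` cue-free period before the next engram's cue, so
#' consecutive cue onsets are `cue_s + gap_s` apart. The ideal persistent
#' duration `T_ideal` is the time from one cue's offset to the next cue's
#' onset (`gap_s`).
#'
#' @param n_engrams number of engrams cued (in index order).
#' @param warmup_s initial transient discarded from analysis, s.
#' @param cue_s cue duration, s.
#' @param gap_s gap between cue offset and the next onset, s.
#' @param f_cue cue rate per external train, Hz.
#' @param f_background background rate per train, Hz.
#' @return a list of class `cue_schedule` with per-engram `onset_ms`,
#'   `offset_ms`, `t_ideal_s`, and the total `duration_ms`.
#' @export
cue_schedule <- function(n_engrams, warmup_s = 5, cue_s = 5, gap_s = 10,
                         f_cue = 12.5, f_background = 2.5) {
  stopifnot(n_engrams >= 0, cue_s > 0, gap_s > 0, f_cue >= 0)
  period <- (cue_s + gap_s) * 1000
  onset <- warmup_s * 1000 + (seq_len(n_engrams) - 1) * period
  structure(list(n_engrams = n_engrams,
                 onset_ms = onset, offset_ms = onset + cue_s * 1000,
                 warmup_ms = warmup_s * 1000, t_ideal_s = gap_s,
                 f_cue = f_cue, f_background = f_background,
                 duration_ms = warmup_s * 1000 + n_engrams * period),
            class = "cue_schedule")
}

schedule_windows <- function(graph, schedule, f_extra = schedule$f_cue) {
  lapply(seq_len(schedule$n_engrams), function(k)
    list(start_ms = schedule$onset_ms[k], end_ms = schedule$offset_ms[k],
         neurons = engram_neurons(graph, k), add_hz = f_extra))
}

#' Analysis window of one engram's recall
#'
#' The 10 s (by default `t_ideal_s`) window from that engram's cue offset in
#' which recall metrics are evaluated.
#'
#' @param schedule a [cue_schedule()].
#' @param k engram index.
#' @return `c(start_ms, end_ms)`.
#' @export
recall_window <- function(schedule, k) {
  c(schedule$offset_ms[k], schedule$offset_ms[k] + schedule$t_ideal_s * 1000)
}

#' Run the sequential memory-recall protocol
#'
#' Background drive everywhere; each engram additionally receives its cue
#' per the schedule. The first `warmup_s` seconds are a transient and are
#' excluded from analysis by the metric helpers.
#'
#' @param graph an `engram_graph`.
#' @param schedule a [cue_schedule()] (default: one per engram in the graph).
#' @param rescue optional [rescue_spec()] active from the end of the warmup
#'   (the rescue variant of the protocol).
#' @param seed input/rescue RNG seed.
#' @param ... passed to [simulate_network()].
#' @return an `engram_sim` with the `schedule` attached.
#' @export
run_recall <- function(graph, schedule = NULL, rescue = NULL, seed = 1, ...) {
  if (is.null(schedule))
    schedule <- cue_schedule(graph$config$n_engrams,
                             f_background = graph$config$f_background)
  drv <- make_drive(graph, schedule$duration_ms,
                    windows = schedule_windows(graph, schedule))
  sim <- simulate_network(graph, schedule$duration_ms, drive = drv,
                          rescue = rescue, seed = seed, ...)
  sim$schedule <- schedule
  sim
}

#' Run the rescue-stimulation protocol
#'
#' Identical to [run_recall()] with duty-cycled membrane-reset stimulation
#' of a random half of the inhibitory neurons active throughout (from the
#' end of the warmup).
#'
#' @param graph an `engram_graph`.
#' @param schedule a [cue_schedule()].
#' @param rescue a [rescue_spec()].
#' @param seed input/rescue RNG seed.
#' @param ... passed to [simulate_network()].
#' @return an `engram_sim` with `schedule` attached.
#' @export
run_rescue <- function(graph, schedule = NULL, rescue = rescue_spec(),
                       seed = 1, ...) {
  run_recall(graph, schedule, rescue = rescue, seed = seed, ...)
}

#' Run recall with increased excitatory background drive
#'
#' The excitability-rescue variant: excitatory neurons receive a stronger
#' background rate `f_background_exc` per train while inhibitory neurons
#' stay at the standard background.
#'
#' @param graph an `engram_graph`.
#' @param f_background_exc background rate per train onto E neurons, Hz.
#' @param schedule a [cue_schedule()].
#' @param seed input RNG seed.
#' @param ... passed to [simulate_network()].
#' @return an `engram_sim` with `schedule` attached.
#' @export
run_excitability_rescue <- function(graph, f_background_exc,
                                    schedule = NULL, seed = 1, ...) {
  cfg <- graph$config
  if (f_background_exc < cfg$f_background)
    stop("f_background_exc must be at least the background rate")
  if (is.null(schedule))
    schedule <- cue_schedule(cfg$n_engrams, f_background = cfg$f_background)
  drv <- make_drive(graph, schedule$duration_ms,
                    f_E = f_background_exc, f_I = cfg$f_background,
                    windows = schedule_windows(graph, schedule))
  sim <- simulate_network(graph, schedule$duration_ms, drive = drv,
                          seed = seed, ...)
  sim$schedule <- schedule
  sim
}

#' Run the learning-then-recall protocol
#'
#' The graph must have been built with `learning_engram = 1`, so engram 1
#' starts at the naive baseline weight while the other engrams are preset.
#' After the warmup, a learning signal (`f_learn` Hz per train) drives
#' engram 1 for `learn_s` seconds during which all E->E weights evolve under
#' the long-term plasticity rule; weights are then frozen and every engram
#' is cued sequentially for recall.
#'
#' @param graph an `engram_graph` (engram 1 = learning engram).
#' @param learn_s learning duration, s.
#' @param f_learn learning-signal rate per train, Hz.
#' @param schedule recall [cue_schedule()] appended after learning (its
#'   warmup is re-used as a settling period with frozen weights).
#' @param warmup_s transient before learning, s.
#' @param snapshot_ms weight snapshot cadence during learning, ms.
#' @param seed input RNG seed.
#' @param ... passed to [simulate_network()].
#' @return list of class `learning_run` with `learning` (`engram_sim` of the
#'   learning phase, including weight `snapshots`), `recall` (`engram_sim`
#'   of the post-learning recall), and `graph_after` (graph with learnt
#'   weights).
#' @export
run_learning <- function(graph, learn_s = 100, f_learn = 12.5,
                         schedule = NULL, warmup_s = 5, snapshot_ms = 1000,
                         seed = 1, ...) {
  cfg <- graph$config
  if (cfg$n_engrams < 1) stop("learning requires at least one engram")
  t0 <- warmup_s * 1000
  t1 <- t0 + learn_s * 1000
  drv <- make_drive(graph, t1, windows = list(
    list(start_ms = t0, end_ms = t1,
         neurons = engram_neurons(graph, 1), add_hz = f_learn)))
  learn <- simulate_network(graph, t1, drive = drv,
                            plasticity_window = c(t0, t1),
                            snapshot_ms = snapshot_ms, seed = seed, ...)
  graph_after <- graph
  graph_after$edges <- learn$weights
  if (is.null(schedule))
    schedule <- cue_schedule(cfg$n_engrams, f_background = cfg$f_background)
  recall <- run_recall(graph_after, schedule, seed = seed + 1L, ...)
  structure(list(learning = learn, recall = recall,
                 graph_after = graph_after),
            class = "learning_run")
}

#' Bifurcation (hysteresis) ramp of a single engram
#'
#' With exactly one engram present, its external rate f_M1 is stepped by
#' `step_hz` every `block_s` seconds: up from the background rate to
#' background + `span_hz`, then down to background - `span_hz`. The
#' engram's population rate is measured per block; the switch points are the
#' f_M1 values at which the rate first crosses `threshold` on the ascending
#' and descending branches, giving the stability of the low-activity state
#' (S_l = ascending point - background) and of the persistent state
#' (S_p = background - descending point).
#'
#' @param graph an `engram_graph` with one engram (extra engrams are an
#'   error).
#' @param f_background background rate per train, Hz.
#' @param rescue optional [rescue_spec()] active during the ramp.
#' @param warmup_s settling time at f_M1 = background before the ramp, s.
#' @param step_hz,block_s,span_hz ramp geometry.
#' @param threshold persistent-state rate threshold, spikes/s.
#' @param literal_sl if `TRUE`, report S_l as the raw ascending switch point
#'   rather than its distance from the background rate.
#' @param seed input RNG seed.
#' @param ... passed to [simulate_network()].
#' @return list of class `bifurcation_result`: `ramp` (data frame `f_M1`,
#'   `rate`, `phase`), `switch_up`, `switch_down`, `S_p`, `S_l`,
#'   `bistable`. Missing crossings yield `NA` (flagged absent, not zero).
#' @export
run_bifurcation <- function(graph, f_background = 2.5, rescue = NULL,
                            warmup_s = 5, step_hz = 0.2, block_s = 1,
                            span_hz = 2, threshold = 5,
                            literal_sl = FALSE, seed = 1, ...) {
  if (graph$config$n_engrams != 1)
    stop("bifurcation analysis requires a network with exactly one engram")
  up <- seq(f_background, f_background + span_hz, by = step_hz)
  down <- seq(f_background + span_hz - step_hz, f_background - span_hz,
              by = -step_hz)
  fM1 <- c(up, down)
  phase <- rep(c("up", "down"), c(length(up), length(down)))
  m1 <- engram_neurons(graph, 1)

  t0 <- warmup_s * 1000
  block_ms <- block_s * 1000
  windows <- lapply(seq_along(fM1), function(b)
    list(start_ms = t0 + (b - 1) * block_ms, end_ms = t0 + b * block_ms,
         neurons = m1, add_hz = max(0, fM1[b] - f_background)))
  # rates below background are realised by lowering the M1 baseline directly
  duration <- t0 + length(fM1) * block_ms
  drv <- make_drive(graph, duration, f_E = f_background, f_I = f_background,
                    windows = windows)
  neg <- which(fM1 < f_background)
  for (b in neg) {
    blk <- which(c(0, drv$block_end[-length(drv$block_end)]) >=
                   t0 + (b - 1) * block_ms - 1e-9 &
                 drv$block_end <= t0 + b * block_ms + 1e-9)
    drv$rate[m1, blk] <- fM1[b] * graph$config$n_ext_trains
  }

  sim <- simulate_network(graph, duration, drive = drv, rescue = rescue,
                          seed = seed, ...)
  rate <- vapply(seq_along(fM1), function(b)
    population_rate(sim$raster, m1,
                    t0 + (b - 1) * block_ms, t0 + b * block_ms),
    numeric(1))
  ramp <- data.frame(f_M1 = fM1, rate = rate, phase = phase)
  res <- compute_switch_points(ramp, f_background, threshold,
                               literal_sl = literal_sl)
  res$sim <- sim
  res
}

#' Locate hysteresis switch points on a ramp table
#'
#' Pure table-driven computation (no simulation): the ascending switch point
#' is the f_M1 of the first ascending block whose rate exceeds `threshold`;
#' the descending switch point is the f_M1 of the first descending block
#' whose rate falls below it. Detection is interpolation-free: the ramp
#' resolution is the precision.
#'
#' @param ramp data frame with columns `f_M1`, `rate`, `phase`
#'   ("up"/"down", in ramp order).
#' @param f_background background rate, Hz.
#' @param threshold rate threshold, spikes/s.
#' @param literal_sl report S_l without subtracting the background rate.
#' @return a list of class `bifurcation_result` (see [run_bifurcation()]).
#' @export
compute_switch_points <- function(ramp, f_background = 2.5, threshold = 5,
                                  literal_sl = FALSE) {
  up <- ramp[ramp$phase == "up", , drop = FALSE]
  down <- ramp[ramp$phase == "down", , drop = FALSE]
  iu <- which(up$rate > threshold)[1]
  id <- which(down$rate < threshold)[1]
  switch_up <- if (is.na(iu)) NA_real_ else up$f_M1[iu]
  switch_down <- if (is.na(id)) NA_real_ else down$f_M1[id]
  structure(list(
    ramp = ramp,
    switch_up = switch_up, switch_down = switch_down,
    S_p = if (is.na(switch_down)) NA_real_ else f_background - switch_down,
    S_l = if (is.na(switch_up)) NA_real_ else
      if (literal_sl) switch_up else switch_up - f_background,
    bistable = !is.na(switch_up) && !is.na(switch_down) &&
      switch_up >= switch_down),
    class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("bifurcation ramp: ascending switch %.2f Hz, descending %.2f Hz\n",
              x$switch_up, x$switch_down))
  cat(sprintf("  S_p = %.2f, S_l = %.2f, bistable: %s\n",
              x$S_p, x$S_l, x$bistable))
  invisible(x)
}
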