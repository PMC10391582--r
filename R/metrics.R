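# ---- interval algebra (half-open [start, end) intervals in ms) -----------

normalize_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_ms", "end_ms"))))
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (nrow(iv) == 0)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_ms", "end_ms"))))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv[r, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[r, 2])
    else out <- rbind(out, iv[r, ])
  }
  dimnames(out) <- list(NULL, c("start_ms", "end_ms"))
  out
}

interval_measure <- function(iv) {
  iv <- normalize_intervals(iv)
  if (nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])
}

interval_intersect <- function(a, b) {
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1]); e <- pmin(a[i, 2], b[, 2])
    keep <- e > s
    if (any(keep)) out <- rbind(out, cbind(s[keep], e[keep]))
  }
  normalize_intervals(out)
}

interval_union <- function(a, b) normalize_intervals(rbind(a, b))

interval_diff <- function(a, b) {
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  if (nrow(b) == 0) return(a)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    segs <- matrix(a[i, ], ncol = 2)
    for (j in seq_len(nrow(b))) {
      nxt <- NULL
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1]; e <- segs[k, 2]
        if (b[j, 2] <= s || b[j, 1] >= e) { nxt <- rbind(nxt, c(s, e)); next }
        if (b[j, 1] > s) nxt <- rbind(nxt, c(s, b[j, 1]))
        if (b[j, 2] < e) nxt <- rbind(nxt, c(b[j, 2], e))
      }
      segs <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
      if (nrow(segs) == 0) break
    }
    out <- rbind(out, segs)
  }
  normalize_intervals(out)
}

# ---- persistent states ----------------------------------------------------

#' Detect persistent-state intervals of an engram
#'
#' Slides a window (default 1 s, stepped at 1 ms and assigned to its left
#' edge) over the engram's spikes; times where the population mean rate
#' exceeds `threshold` form candidate intervals, and sub-second
#' low-rate gaps between consecutive intervals are merged.
#'
#' @param raster data frame with `time_ms`, `neuron`.
#' @param neurons neuron ids of the engram (non-empty).
#' @param t_start,t_end analysed span, ms.
#' @param window_ms moving-window length, ms.
#' @param step_ms window step, ms.
#' @param threshold population mean rate threshold, spikes/s.
#' @param merge_gap_ms gaps shorter than this are ignored, ms.
#' @return matrix of half-open intervals (`start_ms`, `end_ms`).
#' @export
detect_persistent_states <- function(raster, neurons, t_start, t_end,
                                     window_ms = 1000, step_ms = 1,
                                     threshold = 5, merge_gap_ms = 1000) {
  if (!length(neurons)) stop("empty engram")
  stopifnot(t_end > t_start)
  t <- raster$time_ms[raster$neuron %in% neurons]
  t <- t[t >= t_start & t < t_end]
  n_steps <- floor((t_end - t_start - window_ms) / step_ms) + 1
  if (n_steps < 1) return(normalize_intervals(NULL))
  # spike counts per step bin, then windowed sums via cumulative counts
  bin <- floor((t - t_start) / step_ms) + 1
  counts <- tabulate(bin, nbins = floor((t_end - t_start) / step_ms))
  cs <- c(0, cumsum(counts))
  wbins <- window_ms / step_ms
  win_counts <- cs[(wbins + 1):(wbins + n_steps)] - cs[1:n_steps]
  rate <- win_counts / (length(neurons) * window_ms / 1000)
  high <- rate > threshold
  if (!any(high)) return(normalize_intervals(NULL))
  r <- rle(high)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- cbind(t_start + (starts[r$values] - 1) * step_ms,
              t_start + ends[r$values] * step_ms)
  # merge sub-second gaps
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] - merged[nrow(merged), 2] < merge_gap_ms)
      merged[nrow(merged), 2] <- iv[i, 2]
    else merged <- rbind(merged, iv[i, ])
  }
  normalize_intervals(merged)
}

#' Persistence score
#'
#' Per engram, closeness of the total persistent duration to the ideal
#' duration: `x_i = 1 - |T_persist_i - T_ideal| / T_ideal`, rectified at
#' zero and averaged over engrams. Equals 1 when every engram persists for
#' exactly `t_ideal_s`.
#'
#' @param t_persist_s per-engram total persistent durations (s), cue
#'   periods excluded.
#' @param t_ideal_s ideal duration (s), cue offset to next cue onset.
#' @return score in \[0, 1\].
#' @export
persistence_score <- function(t_persist_s, t_ideal_s) {
  if (t_ideal_s <= 0) stop("t_ideal_s must be positive")
  mean(pmax(0, 1 - abs(t_persist_s - t_ideal_s) / t_ideal_s))
}

#' Overlapping proportion of persistent-state time sets
#'
#' Intersection-over-union of the engrams' persistent-state interval sets
#' (cue windows excluded from both), measuring spurious co-activation of
#' memories. Zero when the union is empty.
#'
#' @param interval_list list (one per engram, at least two) of interval
#'   matrices as returned by [detect_persistent_states()].
#' @param exclude optional interval matrix (for example, all cue windows)
#'   removed from every set first.
#' @return proportion in \[0, 1\].
#' @export
overlapping_proportion <- function(interval_list, exclude = NULL) {
  if (length(interval_list) < 2)
    stop("overlapping proportion needs at least two engrams")
  sets <- lapply(interval_list, function(iv) {
    iv <- normalize_intervals(iv)
    if (!is.null(exclude)) iv <- interval_diff(iv, exclude) else iv
  })
  inter <- Reduce(interval_intersect, sets)
  uni <- Reduce(interval_union, sets)
  u <- interval_measure(uni)
  if (u == 0) 0 else interval_measure(inter) / u
}

#' Per-engram recall metrics of a simulation
#'
#' For each engram: persistent-state intervals over the post-warmup span
#' (its own cue window excluded), total persistent duration, population mean
#' rate and high-firing proportion in the 10 s window after its cue offset.
#' Also reports the overall persistence score and overlapping proportion.
#'
#' @param sim an `engram_sim` from [run_recall()] and friends (must carry a
#'   schedule).
#' @param threshold persistent-state rate threshold, spikes/s.
#' @return list with `per_engram` (data frame), `persistence_score`,
#'   `overlapping_proportion` (NA with fewer than two engrams).
#' @export
recall_metrics <- function(sim, threshold = 5) {
  sch <- sim$schedule
  if (is.null(sch)) stop("simulation carries no cue schedule")
  cfg <- sim$graph_config
  span0 <- sch$warmup_ms
  span1 <- sim$duration_ms
  cues <- cbind(sch$onset_ms, sch$offset_ms)
  states <- vector("list", sch$n_engrams)
  rows <- lapply(seq_len(sch$n_engrams), function(k) {
    nk <- seq.int((k - 1) * cfg$engram_size + 1, k * cfg$engram_size)
    iv <- detect_persistent_states(sim$raster, nk, span0, span1,
                                   threshold = threshold)
    own_cue <- cues[k, , drop = FALSE]
    iv_x <- interval_diff(iv, own_cue)
    states[[k]] <<- interval_diff(iv, cues)
    win <- recall_window(sch, k)
    data.frame(engram = k,
               t_persist_s = interval_measure(iv_x) / 1000,
               rate = population_rate(sim$raster, nk, win[1], win[2]),
               high_prop = high_firing_proportion(sim$raster, nk,
                                                  win[1], win[2], threshold))
  })
  per <- do.call(rbind, rows)
  list(per_engram = per,
       persistence_score = persistence_score(per$t_persist_s, sch$t_ideal_s),
       overlapping_proportion =
         if (sch$n_engrams >= 2) overlapping_proportion(states) else NA_real_)
}

# ---- firing statistics ----------------------------------------------------

#' Population mean firing rate
#'
#' Spikes of the given neurons in `[t_start, t_end)` divided by window
#' length and neuron count.
#'
#' @param raster data frame with `time_ms`, `neuron`.
#' @param neurons neuron ids.
#' @param t_start,t_end window, ms.
#' @return rate, spikes/s per neuron.
#' @export
population_rate <- function(raster, neurons, t_start, t_end) {
  if (t_end <= t_start) stop("zero-length window")
  sel <- raster$neuron %in% neurons &
    raster$time_ms >= t_start & raster$time_ms < t_end
  sum(sel) / (length(neurons) * (t_end - t_start) / 1000)
}

#' Proportion of high-firing neurons
#'
#' Fraction of the given neurons whose individual rate in the window
#' exceeds `threshold`.
#'
#' @inheritParams population_rate
#' @param threshold individual-rate threshold, spikes/s.
#' @return proportion in \[0, 1\].
#' @export
high_firing_proportion <- function(raster, neurons, t_start, t_end,
                                   threshold = 5) {
  if (t_end <= t_start) stop("zero-length window")
  sel <- raster$neuron %in% neurons &
    raster$time_ms >= t_start & raster$time_ms < t_end
  counts <- table(factor(raster$neuron[sel], levels = neurons))
  mean(counts / ((t_end - t_start) / 1000) > threshold)
}

#' Pairwise synchrony index
#'
#' Both trains are binned at `bin_ms`; the index is
#' `sum(B_i B_j) / sqrt(sum(B_i) * sum(B_j))` with binary bin indicators, so
#' identical trains score 1 and trains with no coincident bins score 0. Set
#' `sqrt_norm = FALSE` for the unrooted denominator `sum(B_i) * sum(B_j)`.
#'
#' @param t_i,t_j spike times of the two neurons, ms.
#' @param t_start,t_end common span, ms.
#' @param bin_ms bin width, ms.
#' @param sqrt_norm use the square-root normalisation (default).
#' @return synchrony index, or NA if either train has no spikes in span.
#' @export
synchrony_index <- function(t_i, t_j, t_start, t_end, bin_ms = 1,
                            sqrt_norm = TRUE) {
  nb <- ceiling((t_end - t_start) / bin_ms)
  binit <- function(t) {
    t <- t[t >= t_start & t < t_end]
    b <- tabulate(floor((t - t_start) / bin_ms) + 1, nbins = nb)
    as.integer(b > 0)
  }
  bi <- binit(t_i); bj <- binit(t_j)
  si <- sum(bi); sj <- sum(bj)
  if (si == 0 || sj == 0) return(NA_real_)
  den <- if (sqrt_norm) sqrt(si * sj) else si * sj
  sum(bi * bj) / den
}

#' Population synchrony over sampled within-engram pairs
#'
#' Mean pairwise [synchrony_index()] over up to `max_pairs` randomly sampled
#' unordered pairs of the given neurons; pairs with a silent member are
#' excluded from the mean.
#'
#' @inheritParams population_rate
#' @param max_pairs pair sample cap.
#' @param seed sampling seed.
#' @param ... passed to [synchrony_index()].
#' @return mean synchrony index (NA if no valid pair).
#' @export
population_synchrony <- function(raster, neurons, t_start, t_end,
                                 max_pairs = 2000, seed = 1, ...) {
  trains <- split(raster$time_ms[raster$neuron %in% neurons],
                  factor(raster$neuron[raster$neuron %in% neurons],
                         levels = neurons))
  n <- length(neurons)
  all_pairs <- n * (n - 1) / 2
  set.seed(seed)
  if (all_pairs <= max_pairs) {
    pairs <- t(utils::combn(n, 2))
  } else {
    i <- sample(n, max_pairs, replace = TRUE)
    j <- sample(n - 1, max_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1, j)
    pairs <- cbind(i, j)
  }
  k <- apply(pairs, 1, function(p)
    synchrony_index(trains[[p[1]]], trains[[p[2]]], t_start, t_end, ...))
  if (all(is.na(k))) NA_real_ else mean(k, na.rm = TRUE)
}

#' Coefficient of variation of inter-spike intervals
#'
#' `sd(ISI)/mean(ISI)`: 0 for periodic firing, about 1 for Poisson firing,
#' above 1 for bursting.
#'
#' @param times spike times of one neuron, ms (any monotone unit).
#' @return CV, or NA with fewer than 3 spikes.
#' @export
cv_isi <- function(times) {
  if (length(times) < 3) return(NA_real_)
  isi <- diff(sort(times))
  sd(isi) / mean(isi)
}

#' Evolution of the mean CV_ISI of a neuron group
#'
#' CV_ISI per neuron in consecutive blocks, averaged over neurons with
#' enough spikes.
#'
#' @param raster data frame with `time_ms`, `neuron`.
#' @param neurons neuron ids.
#' @param t_start,t_end span, ms.
#' @param block_ms block length, ms.
#' @return data frame `time_ms` (block start), `cv_isi`.
#' @export
cv_isi_evolution <- function(raster, neurons, t_start, t_end,
                             block_ms = 10000) {
  starts <- seq(t_start, t_end - block_ms, by = block_ms)
  sel <- raster$neuron %in% neurons
  data.frame(time_ms = starts, cv_isi = vapply(starts, function(s) {
    tt <- raster$time_ms[sel & raster$time_ms >= s &
                           raster$time_ms < s + block_ms]
    id <- raster$neuron[sel & raster$time_ms >= s &
                          raster$time_ms < s + block_ms]
    cv <- vapply(split(tt, factor(id, levels = neurons)), cv_isi, numeric(1))
    mean(cv, na.rm = TRUE)
  }, numeric(1)))
}

#' Normalise firing rates across rescue frequencies
#'
#' Each row (one GABA decay-constant condition, columns = rescue
#' frequencies) is divided by its own mean, so every output row averages 1.
#'
#' @param rate_table numeric matrix or vector of firing rates.
#' @return the normalised table.
#' @export
normalized_firing_rate <- function(rate_table) {
  if (is.null(dim(rate_table))) {
    m <- mean(rate_table)
    if (m == 0) stop("zero mean rate row")
    return(rate_table / m)
  }
  m <- rowMeans(rate_table)
  if (any(m == 0)) stop("zero mean rate row")
  sweep(rate_table, 1, m, "/")
}

#' Oscillation band power of the mean membrane potential
#'
#' Removes the mean from the trace (sampled at `fs` Hz), takes the FFT
#' power spectrum, normalises it to its own mean, and sums the normalised
#' power in the theta (4-12 Hz), slow-gamma (30-60 Hz) and fast-gamma
#' (60-120 Hz) bands.
#'
#' @param trace mean membrane potential samples (typically the 10 s window
#'   after a cue offset at 1 kHz).
#' @param fs sampling rate, Hz.
#' @param expected_s expected window length, s; shorter traces are analysed
#'   with `short_window = TRUE` flagged.
#' @return list of class `band_power` with `spectrum` (data frame
#'   `freq_hz`, `power`), `theta`, `slow_gamma`, `fast_gamma`,
#'   `short_window`.
#' @export
oscillation_power <- function(trace, fs = 1000, expected_s = 10) {
  short <- length(trace) / fs < expected_s
  if (short) warning("analysis window shorter than ", expected_s, " s")
  x <- trace - mean(trace)
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  half <- 2:floor(n / 2 + 1)           # drop DC, keep positive frequencies
  freq <- (half - 1) * fs / n
  p <- p[half]
  if (mean(p) > 0) p <- p / mean(p)
  band <- function(lo, hi) sum(p[freq >= lo & freq <= hi])
  structure(list(spectrum = data.frame(freq_hz = freq, power = p),
                 theta = band(4, 12), slow_gamma = band(30, 60),
                 fast_gamma = band(60, 120), short_window = short),
            class = "band_power")
}

#' Excitatory-to-inhibitory current ratio
#'
#' From recorded population traces: `|I_E| / |I_I|` per time point, with
#' `I_E = G_E (E_E - V)` and `I_I = G_I (E_I - V)`, plus the time mean over
#' the window. Times with (near-)zero inhibitory current are excluded and
#' flagged.
#'
#' @param traces data frame with `time_ms`, `exc_current`, `inh_current`
#'   (as recorded by [simulate_network()]).
#' @param t_start,t_end window, ms (default: full trace).
#' @param eps inhibitory-current magnitude below which a time point is
#'   treated as undefined.
#' @return list with `ratio` (data frame `time_ms`, `ei_ratio`), `mean`,
#'   `undefined_fraction`.
#' @export
ei_ratio <- function(traces, t_start = -Inf, t_end = Inf, eps = 1e-12) {
  sel <- traces$time_ms >= t_start & traces$time_ms < t_end
  tr <- traces[sel, , drop = FALSE]
  ok <- abs(tr$inh_current) > eps
  r <- rep(NA_real_, nrow(tr))
  r[ok] <- abs(tr$exc_current[ok]) / abs(tr$inh_current[ok])
  list(ratio = data.frame(time_ms = tr$time_ms, ei_ratio = r),
       mean = if (any(ok)) mean(r[ok]) else NA_real_,
       undefined_fraction = mean(!ok))
}
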