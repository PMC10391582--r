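#' Generate a synthetic spike raster with prescribed persistent intervals
#'
#' Fixture generator for the metric layer: each engram's neurons fire as
#' inhomogeneous Poisson processes at `baseline_hz` outside and
#' `elevated_hz` inside that engram's prescribed intervals, yielding a
#' raster whose ground-truth persistent states are known. Engram k occupies
#' neurons `(k-1)*n_per_engram + 1 .. k*n_per_engram`.
#'
#' @param intervals list (one element per engram) of two-column matrices of
#'   half-open intervals (ms); an engram with no elevated epochs gets an
#'   empty matrix.
#' @param span_ms raster length, ms.
#' @param n_per_engram neurons per engram.
#' @param baseline_hz,elevated_hz firing rates outside / inside intervals.
#' @param seed RNG seed.
#' @return list with `raster` (data frame `time_ms`, `neuron`),
#'   `engrams` (list of neuron-id vectors), and the echoing `intervals`.
#' @export
generate_fixture_raster <- function(intervals, span_ms,
                                    n_per_engram = 50,
                                    baseline_hz = 1, elevated_hz = 20,
                                    seed = 1) {
  stopifnot(baseline_hz >= 0, elevated_hz >= 0, span_ms > 0)
  set.seed(seed)
  rasters <- list()
  engrams <- list()
  for (k in seq_along(intervals)) {
    iv <- normalize_intervals(intervals[[k]])
    if (nrow(iv) && (min(iv) < 0 || max(iv) > span_ms))
      stop("intervals must lie within the raster span")
    ids <- seq.int((k - 1) * n_per_engram + 1, k * n_per_engram)
    engrams[[k]] <- ids
    low <- interval_diff(matrix(c(0, span_ms), ncol = 2), iv)
    segs <- rbind(cbind(low, baseline_hz),
                  if (nrow(iv)) cbind(iv, elevated_hz))
    tt <- lapply(ids, function(i) {
      unlist(lapply(seq_len(nrow(segs)), function(s) {
        len <- segs[s, 2] - segs[s, 1]
        n <- rpois(1, segs[s, 3] * len / 1000)
        runif(n, segs[s, 1], segs[s, 2])
      }))
    })
    rasters[[k]] <- data.frame(
      time_ms = unlist(tt),
      neuron = rep(ids, lengths(tt)))
  }
  raster <- do.call(rbind, rasters)
  raster <- raster[order(raster$time_ms), , drop = FALSE]
  rownames(raster) <- NULL
  list(raster = raster, engrams = engrams, intervals = intervals)
}
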