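#' Write / read a spike raster as CSV
#'
#' Plain CSV with header `time_ms,neuron_id`; neuron ids are serialised
#' 0-based (the package uses 1-based ids in memory). Times are written at
#' 0.05 ms resolution.
#'
#' @param raster data frame with `time_ms`, `neuron`.
#' @param path file path.
#' @return `read_raster` returns the raster data frame (1-based ids).
#' @export
write_raster <- function(raster, path) {
  out <- data.frame(time_ms = round(raster$time_ms / 0.05) * 0.05,
                    neuron_id = raster$neuron - 1L)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  d <- read.csv(path)
  data.frame(time_ms = d$time_ms, neuron = d$neuron_id + 1L)
}

#' Write / read a synaptic graph as CSV
#'
#' Edge list with header
#' `pre,post,weight,receptor,plastic,engram_pre,engram_post` (0-based ids,
#' empty engram fields for non-engram neurons). `read_graph` restores a
#' usable `engram_graph` given the originating config.
#'
#' @param graph an `engram_graph`.
#' @param path file path.
#' @param config the [network_config()] to attach on read.
#' @return `read_graph` returns an `engram_graph`.
#' @export
write_graph <- function(graph, path) {
  e <- graph$edges
  out <- data.frame(pre = e$pre - 1L, post = e$post - 1L,
                    weight = e$weight, receptor = e$receptor,
                    plastic = e$plastic,
                    engram_pre = e$engram_pre, engram_post = e$engram_post)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path, config) {
  d <- read.csv(path)
  n <- config$nE + config$nI
  edges <- data.frame(pre = d$pre + 1L, post = d$post + 1L,
                      weight = d$weight, receptor = d$receptor,
                      plastic = as.logical(d$plastic),
                      engram_pre = suppressWarnings(as.integer(d$engram_pre)),
                      engram_post = suppressWarnings(as.integer(d$engram_post)))
  type <- rep(c("E", "I"), c(config$nE, config$nI))
  engram <- rep(NA_integer_, n)
  if (config$n_engrams > 0)
    engram[seq_len(config$n_engrams * config$engram_size)] <-
      rep(seq_len(config$n_engrams), each = config$engram_size)
  structure(list(edges = edges, type = type, engram = engram,
                 config = config),
            class = "engram_graph")
}

#' Read a network configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [network_config()]; the nested
#' blocks `neuron`, `receptor`, `stp`, `plasticity` mirror their parameter
#' constructors. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `network_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  blocks <- list(neuron = neuron_params, receptor = receptor_params,
                 stp = stp_params, plasticity = plasticity_params)
  args <- y[setdiff(names(y), names(blocks))]
  for (b in names(blocks))
    args[[b]] <- do.call(blocks[[b]], if (is.null(y[[b]])) list() else y[[b]])
  do.call(network_config, args)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run bit-for-bit: the full
#' configuration, the seeds of each RNG stream, the package version and the
#' output file index.
#'
#' @param path output path.
#' @param config a `network_config`.
#' @param seeds named list of stream seeds.
#' @param files named list of output files.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config, seeds, files = list()) {
  m <- list(package = "engramsim",
            version = as.character(utils::packageVersion("engramsim")),
            created = format(Sys.time(), tz = "UTC"),
            seeds = seeds, files = files, config = unclass_deep(config))
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
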