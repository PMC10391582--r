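#' Build the random E-I network with embedded engrams
#'
#' Draws a directed Erdos-Renyi graph: every ordered pair (pre, post) of
#' distinct neurons is connected independently with probability `C`. Weights
#' follow the pre/post type assignment (`g_EE`, `g_IE`, `g_EI`, `g_II`);
#' E->E synapses whose endpoints share an engram are strengthened to
#' `g_M_EE`. Engrams occupy contiguous blocks of excitatory neurons
#' (engram 1 = neurons 1..engram_size, and so on). Neurons are numbered
#' 1..nE (excitatory) then nE+1..nE+nI (inhibitory); serialisation to CSV
#' uses 0-based ids.
#'
#' @param config a [network_config()].
#' @param learning_engram optional engram index whose internal weights are
#'   left at the naive baseline `g_EE` instead of `g_M_EE` (the "to be
#'   learnt" engram of the learning protocol).
#' @return an object of class `engram_graph`: a list with `edges` (data frame
#'   `pre`, `post`, `weight`, `receptor`, `plastic`, `engram_pre`,
#'   `engram_post`), `type` (character vector "E"/"I"), `engram` (integer or
#'   NA per neuron), and the originating `config`.
#' @export
build_network <- function(config, learning_engram = NULL) {
  stopifnot(inherits(config, "network_config"))
  n <- config$nE + config$nI
  type <- rep(c("E", "I"), c(config$nE, config$nI))
  engram <- rep(NA_integer_, n)
  if (config$n_engrams > 0)
    engram[seq_len(config$n_engrams * config$engram_size)] <-
      rep(seq_len(config$n_engrams), each = config$engram_size)

  set.seed(config$seed)
  pre <- post <- vector("list", n)
  if (config$C > 0) {
    for (j in seq_len(n)) {
      tgt <- which(runif(n) < config$C)
      tgt <- tgt[tgt != j]
      pre[[j]] <- rep.int(j, length(tgt))
      post[[j]] <- tgt
    }
  }
  pre <- unlist(pre); post <- unlist(post)
  if (is.null(pre)) pre <- post <- integer(0)

  edges <- data.frame(pre = pre, post = post)
  edges$weight <- edge_baseline_weight(edges$pre, edges$post, type, config)
  edges$receptor <- ifelse(type[edges$pre] == "E", "ampa_nmda", "gaba")
  edges$plastic <- type[edges$pre] == "E" & type[edges$post] == "E"
  edges$engram_pre <- engram[edges$pre]
  edges$engram_post <- engram[edges$post]
  intra <- !is.na(edges$engram_pre) & !is.na(edges$engram_post) &
    edges$engram_pre == edges$engram_post
  if (!is.null(learning_engram))
    intra <- intra & edges$engram_pre != learning_engram
  edges$weight[intra] <- config$g_M_EE

  structure(list(edges = edges, type = type, engram = engram,
                 config = config),
            class = "engram_graph")
}

edge_baseline_weight <- function(pre, post, type, config) {
  w <- numeric(length(pre))
  pe <- type[pre] == "E"; po <- type[post] == "E"
  w[pe & po] <- config$g_EE
  w[!pe & po] <- config$g_IE
  w[pe & !po] <- config$g_EI
  w[!pe & !po] <- config$g_II
  w
}

#' @export
print.engram_graph <- function(x, ...) {
  cat(sprintf("engram_graph: %d neurons (%d E, %d I), %d edges\n",
              length(x$type), sum(x$type == "E"), sum(x$type == "I"),
              nrow(x$edges)))
  ne <- sum(!is.na(x$engram))
  cat(sprintf("  %d engram neurons in %d engrams\n", ne,
              length(unique(stats::na.omit(x$engram)))))
  invisible(x)
}

n_neurons <- function(graph) length(graph$type)

#' Degradation specification
#'
#' Remaining fractions of neurons (`R_N`), connections (`R_C`) and synaptic
#' strength (`R_w`), each relative to the intact reference circuit (all
#' neurons present, connectivity at its construction value, original
#' weights). A fraction of 1 leaves that aspect untouched.
#'
#' @param R_N,R_C,R_w fractions in (0, 1].
#' @return a list of class `degradation_spec`.
#' @export
degradation_spec <- function(R_N = 1, R_C = 1, R_w = 1) {
  for (r in c(R_N, R_C, R_w))
    if (r <= 0 || r > 1) stop("degradation fractions must lie in (0, 1]")
  structure(list(R_N = R_N, R_C = R_C, R_w = R_w),
            class = "degradation_spec")
}

#' Apply degradation transforms to a network
#'
#' `R_N` removes a random fraction 1 - R_N of neurons (with all incident
#' edges), stratified so that the E:I ratio is preserved; surviving neurons
#' are renumbered contiguously. `R_C` deletes each edge independently with
#' probability 1 - R_C. `R_w` multiplies every weight by R_w. The three
#' transforms are independent and composable.
#'
#' @param graph an `engram_graph`.
#' @param spec a [degradation_spec()].
#' @param seed RNG seed of the removal draws.
#' @return the degraded `engram_graph`.
#' @export
apply_degradation <- function(graph, spec, seed = 1) {
  stopifnot(inherits(graph, "engram_graph"),
            inherits(spec, "degradation_spec"))
  set.seed(seed)
  edges <- graph$edges

  if (spec$R_N < 1) {
    is_e <- graph$type == "E"
    keep_e <- sort(sample(which(is_e), round(spec$R_N * sum(is_e))))
    keep_i <- sort(sample(which(!is_e), round(spec$R_N * sum(!is_e))))
    keep <- c(keep_e, keep_i)
    remap <- rep(NA_integer_, length(graph$type))
    remap[keep] <- seq_along(keep)
    edges <- edges[edges$pre %in% keep & edges$post %in% keep, , drop = FALSE]
    edges$pre <- remap[edges$pre]
    edges$post <- remap[edges$post]
    graph$type <- graph$type[keep]
    graph$engram <- graph$engram[keep]
  }
  if (spec$R_C < 1)
    edges <- edges[runif(nrow(edges)) < spec$R_C, , drop = FALSE]
  if (spec$R_w < 1)
    edges$weight <- edges$weight * spec$R_w

  rownames(edges) <- NULL
  graph$edges <- edges
  graph
}

#' Set the excitatory-to-inhibitory synaptic weight
#'
#' Replaces the weight of every E->I edge by `g_EI_new`, the manipulation
#' used to tip the excitation-inhibition balance. All other weights are left
#' untouched.
#'
#' @param graph an `engram_graph`.
#' @param g_EI_new new E->I weight (non-negative).
#' @return the modified `engram_graph`.
#' @export
set_ei_manipulation <- function(graph, g_EI_new) {
  stopifnot(inherits(graph, "engram_graph"))
  if (g_EI_new < 0) stop("synaptic weights must be non-negative")
  sel <- graph$type[graph$edges$pre] == "E" &
    graph$type[graph$edges$post] == "I"
  graph$edges$weight[sel] <- g_EI_new
  graph$config$g_EI <- g_EI_new
  graph
}

#' Neuron ids of one engram
#'
#' @param graph an `engram_graph`.
#' @param k engram index.
#' @return integer vector of (1-based) neuron ids.
#' @export
engram_neurons <- function(graph, k) which(!is.na(graph$engram) & graph$engram == k)
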