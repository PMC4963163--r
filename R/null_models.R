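#' Null-model configuration
#'
#' Settings for the dual-constrained null networks: the number of
#' attempted Maslov-Sneppen double-edge swaps per edge, the number of
#' replicate nulls, and the seed every replicate's randomness is derived
#' from.
#'
#' @param swaps_per_edge positive integer; `swaps_per_edge * E` swaps are
#'   attempted (default 10, a standard burn-in for degree-preserving
#'   rewiring).
#' @param n_replicates positive integer number of null replicates
#'   (default 1, matching one null per network; 20 or more is
#'   recommended when the dispersion of gamma/lambda matters).
#' @param rng_seed integer seed.
#' @return an object of class `null_model_config`.
#' @export
null_model_config <- function(swaps_per_edge = 10, n_replicates = 1,
                              rng_seed = 1) {
  stopifnot(swaps_per_edge >= 1, n_replicates >= 1)
  structure(list(swaps_per_edge = as.integer(swaps_per_edge),
                 n_replicates = as.integer(n_replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "null_model_config")
}

#' Degree-preserving rewiring of a binary graph
#'
#' Randomizes the topology with `swaps_per_edge * E` attempted
#' double-edge swaps, rejecting swaps that would create self-loops or
#' duplicate edges, so the output is a simple graph with exactly the
#' input's degree sequence. Graphs that admit no legal swap (for example
#' a complete graph or a single triangle) come back unchanged with a
#' message.
#'
#' @param g a `binary_graph` (or `connectome`, reduced to its skeleton)
#'   with at least 2 edges.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @param rng_seed optional integer seed; when supplied the result is
#'   reproducible.
#' @return a rewired `binary_graph`.
#' @export
rewire_degree_preserving <- function(g, swaps_per_edge = 10,
                                     rng_seed = NULL) {
  a <- adjacency_of(g)
  labels <- rownames(a)
  e <- sum(a[upper.tri(a)] > 0)
  if (e < 2) stop("rewiring requires at least 2 edges")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  rg <- igraph::rewire(ig,
                       igraph::keeping_degseq(loops = FALSE,
                                              niter = swaps_per_edge * e))
  out <- igraph::as_adjacency_matrix(rg, sparse = FALSE)
  dimnames(out) <- list(labels, labels)
  if (identical(out, a)) {
    message("no legal double-edge swap changed the graph; ",
            "returned unchanged")
  }
  binary_graph(out, labels = labels)
}

#' Place a source's edge weights onto a null topology
#'
#' Randomly permutes the source connectome's edge weights onto the edges
#' of the (typically rewired) null graph, without replacement, so the
#' null's edge-weight multiset equals the source's exactly. The null
#' connectome carries no streamline counts: it is an abstract reference
#' network, not a tractography result.
#'
#' @param null_g a `binary_graph` with the same number of edges as the
#'   source.
#' @param source a `connectome` supplying the weight list.
#' @param rng_seed optional integer seed.
#' @return a `connectome` on the null topology.
#' @export
assign_weights_from_source <- function(null_g, source, rng_seed = NULL) {
  stopifnot(inherits(null_g, "binary_graph"), inherits(source, "connectome"))
  wlist <- source$weights[upper.tri(source$weights) & source$weights > 0]
  a <- null_g$adjacency
  idx <- which(upper.tri(a) & a > 0)
  if (length(idx) != length(wlist)) {
    stop(sprintf("edge-count mismatch: null graph has %d edges, source %d",
                 length(idx), length(wlist)))
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  perm <- sample.int(length(wlist))
  w <- matrix(0, nrow(a), ncol(a), dimnames = dimnames(a))
  w[idx] <- wlist[perm]
  w <- w + t(w)
  connectome(w, counts = NULL, labels = null_g$labels,
             metadata = list(source = "null model"))
}

#' Generate an ensemble of dual-constrained null networks
#'
#' Each replicate rewires the source's binary skeleton with
#' degree-preserving double-edge swaps and then permutes the source's
#' edge weights onto the rewired edges. Every replicate therefore shares
#' the source's node count, exact degree sequence and exact edge-weight
#' multiset; everything else (which pairs are joined, which weight sits
#' on which edge) is randomized. Sub-seeds for the replicates are
#' derived deterministically from `rng_seed`, so the ensemble is fully
#' reproducible.
#'
#' @param x the source `connectome`.
#' @param config a [null_model_config()].
#' @return an object of class `null_ensemble` with fields `fingerprint`
#'   (node count, sorted degree sequence, sorted weight list of the
#'   source), `replicates` (list of `connectome`) and `config`.
#' @export
generate_null_ensemble <- function(x, config = null_model_config()) {
  stopifnot(inherits(x, "connectome"), inherits(config, "null_model_config"))
  g <- binarize(x)
  fp <- list(
    n_nodes = n_nodes(x),
    degree_sequence = sort(unname(node_degree(g))),
    weights_sorted = sort(x$weights[upper.tri(x$weights) & x$weights > 0])
  )
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    sub_seed <- (config$rng_seed + 11587 * r) %% 2147483647L
    null_g <- rewire_degree_preserving(g, config$swaps_per_edge,
                                       rng_seed = sub_seed)
    reps[[r]] <- assign_weights_from_source(null_g, x)
    reps[[r]]$metadata$rng_seed <- sub_seed
    reps[[r]]$metadata$parent_seed <- config$rng_seed
  }
  structure(list(fingerprint = fp, replicates = reps, config = config),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "Null ensemble: %d replicate(s) over %d nodes, %d edges (seed %d)\n",
    length(x$replicates), x$fingerprint$n_nodes,
    length(x$fingerprint$weights_sorted), x$config$rng_seed))
  cat("  constraints: degree sequence and edge-weight multiset preserved\n")
  invisible(x)
}
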