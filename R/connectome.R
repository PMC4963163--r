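#' Weighted connectome objects
#'
#' A `connectome` is an undirected network over `N` labelled nodes with a
#' symmetric, zero-diagonal matrix of non-negative edge weights and,
#' optionally, a matching matrix of streamline counts. Edge existence is
#' strict positivity of the weight: `weights[i, j] > 0` means an edge is
#' present. When counts are supplied they must agree with the weights on
#' edge presence (`weights > 0` exactly where `counts > 0`).
#'
#' @param weights square numeric matrix of non-negative edge weights,
#'   symmetric with zero diagonal.
#' @param counts optional square matrix of non-negative integer streamline
#'   counts with the same pattern of non-zero entries as `weights`.
#' @param labels character vector of unique node labels; defaults to the
#'   dimnames of `weights` or `n1 ... nN`.
#' @param metadata free-form named list recording provenance (source file,
#'   applied threshold, generator settings, ...).
#' @return An object of class `connectome` with elements `labels`,
#'   `weights`, `counts` (or `NULL`) and `metadata`.
#' @seealso [binarize()], [threshold_counts()], [graph_density()],
#'   [validate_connectome()]
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 0.5
#' cn <- connectome(w, labels = c("A", "B", "C"))
#' edge_count(cn)
#' @export
connectome <- function(weights, counts = NULL, labels = NULL,
                       metadata = list()) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- default_labels(nrow(weights))
  }
  labels <- as.character(labels)
  dimnames(weights) <- list(labels, labels)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    dimnames(counts) <- list(labels, labels)
  }
  x <- structure(
    list(labels = labels, weights = weights, counts = counts,
         metadata = metadata),
    class = "connectome"
  )
  bad <- validate_connectome(x)
  if (length(bad)) {
    stop("invalid connectome:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  x
}

#' Validate a connectome against its invariants
#'
#' Checks symmetry, zero diagonal, non-negativity, integer counts, and
#' the edge-presence consistency between weights and counts. Returns a
#' character vector of human-readable violations, empty when the object
#' is valid. The constructor [connectome()] stops on any violation; this
#' function is the non-throwing check.
#'
#' @param x object to check.
#' @return character vector of violation descriptions (empty if valid).
#' @export
validate_connectome <- function(x) {
  v <- character()
  w <- x$weights
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    return("weights must be a square matrix")
  }
  n <- nrow(w)
  if (n < 1) v <- c(v, "at least one node required")
  if (length(x$labels) != n) {
    v <- c(v, sprintf("expected %d node labels, got %d", n, length(x$labels)))
  }
  if (anyDuplicated(x$labels)) {
    v <- c(v, sprintf("duplicate node labels: %s",
                      paste(unique(x$labels[duplicated(x$labels)]),
                            collapse = ", ")))
  }
  if (anyNA(w)) v <- c(v, "weights contain missing values")
  v <- c(v, .check_sym_matrix(w, "weights"))
  if (!is.null(x$counts)) {
    k <- x$counts
    if (!is.matrix(k) || nrow(k) != n || ncol(k) != n) {
      v <- c(v, "counts must be a square matrix matching weights")
    } else {
      v <- c(v, .check_sym_matrix(k, "counts"))
      off <- which(abs(k - round(k)) > 0, arr.ind = TRUE)
      if (nrow(off)) {
        v <- c(v, sprintf("non-integer count at (%d,%d)",
                          off[1, 1], off[1, 2]))
      }
      mism <- which((w > 0) != (k > 0), arr.ind = TRUE)
      if (nrow(mism)) {
        v <- c(v, sprintf(
          "edge-presence mismatch between weights and counts at (%d,%d)",
          mism[1, 1], mism[1, 2]))
      }
    }
  }
  v
}

.check_sym_matrix <- function(m, what) {
  v <- character()
  asym <- which(m != t(m), arr.ind = TRUE)
  if (nrow(asym)) {
    v <- c(v, sprintf("%s not symmetric at (%d,%d)",
                      what, asym[1, 1], asym[1, 2]))
  }
  if (any(diag(m) != 0)) {
    v <- c(v, sprintf("%s diagonal must be zero (self-edges undefined)", what))
  }
  if (any(m < 0)) {
    neg <- which(m < 0, arr.ind = TRUE)
    v <- c(v, sprintf("negative %s at (%d,%d)", what, neg[1, 1], neg[1, 2]))
  }
  v
}

#' Binary graph objects
#'
#' A `binary_graph` is the 0/1 skeleton of a connectome: a symmetric
#' adjacency matrix with zero diagonal over labelled nodes.
#'
#' @param adjacency square 0/1 symmetric matrix with zero diagonal.
#' @param labels character vector of unique node labels.
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- default_labels(nrow(adjacency))
  }
  labels <- as.character(labels)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  dimnames(adjacency) <- list(labels, labels)
  structure(list(labels = labels, adjacency = adjacency),
            class = "binary_graph")
}

#' Reduce a connectome to its binary skeleton
#'
#' Any strictly positive weight is an edge; zero means absent.
#'
#' @param x a `connectome`.
#' @return a `binary_graph` with the same node labels.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "connectome"))
  binary_graph((x$weights > 0) + 0, labels = x$labels)
}

#' Threshold a connectome on streamline counts
#'
#' Removes every edge carried by fewer than `min_count` streamlines:
#' both the weight and the count of such edges are zeroed. The cutoff is
#' inclusive (edges with exactly `min_count` streamlines are kept), and
#' `min_count = 0` is the identity. Thresholding is defined on streamline
#' counts, never on the weight value, so a connectome without a counts
#' matrix cannot be thresholded.
#'
#' @param x a `connectome` with a counts matrix.
#' @param min_count non-negative integer; edges with `counts < min_count`
#'   are removed.
#' @return a new `connectome`; the applied threshold is recorded in
#'   `metadata$min_count`.
#' @export
threshold_counts <- function(x, min_count) {
  stopifnot(inherits(x, "connectome"))
  if (is.null(x$counts)) {
    stop("connectome has no streamline counts; ",
         "count thresholding is defined on counts, not weights",
         call. = FALSE)
  }
  if (length(min_count) != 1 || is.na(min_count) || min_count < 0 ||
      min_count != round(min_count)) {
    stop("min_count must be a single non-negative integer")
  }
  drop <- x$counts < min_count
  w <- x$weights
  k <- x$counts
  w[drop] <- 0
  k[drop] <- 0
  md <- x$metadata
  md$min_count <- min_count
  connectome(w, counts = k, labels = x$labels, metadata = md)
}

#' Graph density
#'
#' Ratio of the number of undirected edges to the maximum possible
#' `N(N-1)/2` for a simple undirected graph.
#'
#' @param x a `connectome` or `binary_graph` with at least 2 nodes.
#' @return density in `[0, 1]`.
#' @export
graph_density <- function(x) {
  a <- adjacency_of(x)
  n <- nrow(a)
  if (n < 2) stop("graph density requires at least 2 nodes")
  sum(a[upper.tri(a)] > 0) / (n * (n - 1) / 2)
}

#' @rdname connectome
#' @export
n_nodes <- function(x) length(x$labels)

#' @rdname connectome
#' @export
edge_count <- function(x) {
  a <- adjacency_of(x)
  sum(a[upper.tri(a)] > 0)
}

# zero-padded labels so that lexicographic order equals node order
default_labels <- function(n) {
  paste0("n", formatC(seq_len(n), width = nchar(n), flag = "0"))
}

# 0/1 adjacency from either class
adjacency_of <- function(x) {
  if (inherits(x, "binary_graph")) return(x$adjacency)
  if (inherits(x, "connectome")) return((x$weights > 0) + 0)
  stop("expected a connectome or binary_graph")
}

#' Edge table of a connectome
#'
#' One row per undirected edge (upper triangle), with weight and count.
#'
#' @param x a `connectome`.
#' @return data.frame with columns `node_a`, `node_b`, `weight`, `count`
#'   (`count` is `NA` when the connectome has no counts matrix).
#' @export
edge_table <- function(x) {
  stopifnot(inherits(x, "connectome"))
  idx <- which(upper.tri(x$weights) & x$weights > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    node_a = x$labels[idx[, 1]],
    node_b = x$labels[idx[, 2]],
    weight = x$weights[idx],
    count  = if (is.null(x$counts)) NA_real_ else x$counts[idx],
    stringsAsFactors = FALSE
  )
}

#' Largest connected component of a connectome
#'
#' Path-based metrics are defined on connected graphs; this restricts a
#' connectome to its largest connected component (ties broken by lowest
#' node index).
#'
#' @param x a `connectome`.
#' @return a `connectome` on the component's nodes.
#' @export
largest_component <- function(x) {
  stopifnot(inherits(x, "connectome"))
  g <- igraph::graph_from_adjacency_matrix(adjacency_of(x),
                                           mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  connectome(x$weights[keep, keep, drop = FALSE],
             counts = if (is.null(x$counts)) NULL else
               x$counts[keep, keep, drop = FALSE],
             labels = x$labels[keep],
             metadata = x$metadata)
}

#' @export
print.connectome <- function(x, ...) {
  n <- n_nodes(x)
  e <- edge_count(x)
  cat(sprintf("Weighted connectome: %d nodes, %d edges (density %.3f)\n",
              n, e, if (n >= 2) graph_density(x) else NA))
  if (e > 0) {
    w <- x$weights[upper.tri(x$weights) & x$weights > 0]
    cat(sprintf("  edge weights: %.3g .. %.3g (median %.3g)\n",
                min(w), max(w), stats::median(w)))
  }
  if (!is.null(x$counts)) {
    k <- x$counts[upper.tri(x$counts) & x$counts > 0]
    if (length(k)) {
      cat(sprintf("  streamline counts: %d .. %d\n", min(k), max(k)))
    }
  } else {
    cat("  no streamline counts\n")
  }
  if (!is.null(x$metadata$min_count)) {
    cat(sprintf("  count threshold applied: >= %d\n", x$metadata$min_count))
  }
  invisible(x)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges (density %.3f)\n",
              length(x$labels), edge_count(x),
              if (length(x$labels) >= 2) graph_density(x) else NA))
  invisible(x)
}

#' @export
summary.connectome <- function(object, ...) {
  print(object)
  g <- binarize(object)
  deg <- node_degree(g)
  cat(sprintf("  degree: mean %.1f, range %d..%d\n",
              mean(deg), min(deg), max(deg)))
  s <- node_strength(object)
  cat(sprintf("  strength: mean %.3g, range %.3g..%.3g\n",
              mean(s), min(s), max(s)))
  invisible(object)
}

# internal: connectome -> igraph with weight/count attributes
as_igraph_conn <- function(x) {
  g <- igraph::graph_from_adjacency_matrix(
    x$weights, mode = "undirected", weighted = TRUE, diag = FALSE)
  igraph::V(g)$label <- x$labels
  if (!is.null(x$counts)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$count <- x$counts[el]
  }
  g
}
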