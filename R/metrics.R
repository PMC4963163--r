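#' Node degree and node strength
#'
#' Degree counts a node's neighbors in the binary skeleton; strength sums
#' the weights of its incident edges. With all weights equal to 1 the two
#' coincide.
#'
#' @param x a `binary_graph` or `connectome` (degree accepts either;
#'   strength requires a `connectome`).
#' @return named numeric vector, one value per node.
#' @export
node_degree <- function(x) {
  a <- adjacency_of(x)
  structure(rowSums(a > 0), names = rownames(a))
}

#' @rdname node_degree
#' @export
node_strength <- function(x) {
  stopifnot(inherits(x, "connectome"))
  rowSums(x$weights)
}

#' Complementary cumulative distribution of a node metric
#'
#' For each distinct value `v` in the input, the fraction of nodes whose
#' metric is at least `v`. The fraction at the minimum value is 1 and the
#' fractions are non-increasing in `v`.
#'
#' @param values numeric vector of per-node metric values.
#' @return data.frame with columns `value` (sorted ascending, unique) and
#'   `fraction`.
#' @export
cumulative_distribution <- function(values) {
  if (!length(values)) stop("empty metric vector")
  v <- sort(unique(values))
  frac <- vapply(v, function(t) mean(values >= t), numeric(1))
  data.frame(value = v, fraction = frac)
}

#' Geodesic path matrices
#'
#' `binary_geodesics` returns the hop-count distance between every node
#' pair (breadth-first shortest paths). `weighted_geodesics` implements
#' the modified Dijkstra rule for weighted connectomes: among all paths
#' joining two nodes, first restrict to those with the smallest number of
#' edges (the binary hop distance), then take the path with the highest
#' sum of edge weights. The entry `d^w_ij` is that maximal weight sum.
#'
#' The weighted matrix is computed by a layered max-plus dynamic program
#' over hop counts: the best weight sum over walks of exactly `h` edges
#' is propagated level by level, and a walk of exactly `h` edges between
#' nodes at hop distance `h` is necessarily a simple path, so the value
#' read off at `h = d_ij` is exact.
#'
#' Unreachable pairs are flagged `NA` (never an infinite weight).
#'
#' @param x a `binary_graph` or `connectome` for `binary_geodesics`; a
#'   `connectome` for `weighted_geodesics`.
#' @return an object of class `path_matrix` with fields `mode`
#'   (`"binary"` or `"weighted"`), `values` (symmetric matrix, zero
#'   diagonal, `NA` for unreachable pairs) and `labels`.
#' @export
binary_geodesics <- function(x) {
  a <- adjacency_of(x)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(g, weights = NA)
  d[is.infinite(d)] <- NA_real_
  dimnames(d) <- dimnames(a)
  path_matrix("binary", d, rownames(a))
}

#' @rdname binary_geodesics
#' @export
weighted_geodesics <- function(x) {
  stopifnot(inherits(x, "connectome"))
  w <- x$weights
  n <- nrow(w)
  hops <- binary_geodesics(x)$values
  res <- matrix(NA_real_, n, n, dimnames = dimnames(w))
  diag(res) <- 0
  if (n == 1) return(path_matrix("weighted", res, x$labels))
  # max-plus propagation: wneg[i, j] = weight if edge, -Inf otherwise
  wneg <- ifelse(w > 0, w, -Inf)
  diag(wneg) <- -Inf
  lvl <- wneg                       # best sum over walks of exactly h edges
  one <- which(hops == 1)
  res[one] <- w[one]
  maxh <- suppressWarnings(max(hops[is.finite(hops)], na.rm = TRUE))
  h <- 1
  while (is.finite(maxh) && h < maxh) {
    h <- h + 1
    nxt <- matrix(-Inf, n, n)
    for (k in seq_len(n)) {
      if (all(lvl[, k] == -Inf)) next
      nxt <- pmax(nxt, outer(lvl[, k], wneg[k, ], "+"))
    }
    lvl <- nxt
    sel <- which(hops == h)
    res[sel] <- lvl[sel]
  }
  path_matrix("weighted", res, x$labels)
}

path_matrix <- function(mode, values, labels) {
  structure(list(mode = mode, values = values, labels = labels),
            class = "path_matrix")
}

#' @export
print.path_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("%s geodesic path matrix over %d nodes\n",
              x$mode, length(x$labels)))
  if (anyNA(off)) {
    cat(sprintf("  %d unreachable pair(s)\n", sum(is.na(off))))
  }
  reach <- off[!is.na(off)]
  if (length(reach)) {
    cat(sprintf("  path lengths: %.4g .. %.4g (mean %.4g)\n",
                min(reach), max(reach), mean(reach)))
  }
  invisible(x)
}

#' Mean geodesic path length per node
#'
#' Average of a node's geodesic path lengths to the other `N - 1` nodes.
#' A disconnected graph (any `NA` entry among the requested rows) is an
#' error: averaging only the finite entries would silently bias
#' comparisons between networks. Restrict to [largest_component()] first
#' if a disconnected network must be analysed.
#'
#' @param p a `path_matrix`.
#' @param node optional node label (or vector of labels); default all.
#' @return named numeric vector of per-node means.
#' @export
mean_geodesic <- function(p, node = NULL) {
  stopifnot(inherits(p, "path_matrix"))
  v <- p$values
  n <- nrow(v)
  if (n < 2) stop("mean geodesic path length requires at least 2 nodes")
  if (is.null(node)) node <- p$labels
  idx <- match(node, p$labels)
  if (anyNA(idx)) stop("unknown node label: ",
                       paste(node[is.na(idx)], collapse = ", "))
  out <- vapply(idx, function(i) {
    row <- v[i, -i]
    if (anyNA(row)) {
      stop("graph is disconnected: mean geodesic path length undefined ",
           "(consider largest_component())", call. = FALSE)
    }
    mean(row)
  }, numeric(1))
  names(out) <- node
  out
}

#' Scale edge weights by the network maximum
#'
#' Returns the weight matrix divided by its largest entry, so the scaled
#' weights lie in `[0, 1]` with maximum exactly 1. The maximum is taken
#' over the network as currently thresholded.
#'
#' @param x a `connectome` with at least one edge.
#' @return `N x N` matrix of scaled weights.
#' @export
scale_weights <- function(x) {
  stopifnot(inherits(x, "connectome"))
  mx <- max(x$weights)
  if (mx <= 0) stop("cannot scale weights of an edgeless network")
  x$weights / mx
}

#' Clustering coefficients: binary, Onnela, Zhang-Horvath
#'
#' For node `i` with binary degree `k_i`:
#' \describe{
#'   \item{binary}{fraction of connected neighbor pairs,
#'     `c_i = 2 E_i / (k_i (k_i - 1))` with `E_i` the number of edges
#'     among the neighbors of `i`.}
#'   \item{onnela}{replaces each closed triangle by the geometric mean of
#'     its three scaled weights:
#'     `c_{i,O} = (1 / (k_i (k_i - 1))) * sum_(j,m) (w'_ij w'_jm w'_mi)^(1/3)`,
#'     keeping the binary degree normalization.}
#'   \item{zhang}{fully weighted normalization:
#'     `c_{i,Z} = sum_(j,m) w'_ij w'_jm w'_mi /
#'       ((sum_j w'_ij)^2 - sum_j w'_ij^2)`.}
#' }
#' Scaled weights `w' = w / max(w)` (see [scale_weights()]) are used in
#' both weighted variants, so all three coefficients lie in `[0, 1]` and
#' the weighted variants reduce to the binary one when every edge weight
#' is equal. Nodes with `k_i <= 1` (no neighbor pair) are assigned 0.
#'
#' @param x a `binary_graph` or `connectome` (binary); a `connectome`
#'   (weighted variants).
#' @param node optional node label(s); default all nodes.
#' @return named numeric vector of clustering coefficients in `[0, 1]`.
#' @export
clustering_binary <- function(x, node = NULL) {
  a <- adjacency_of(x)
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a)
  c_i <- ifelse(k > 1, tri / (k * (k - 1)), 0)
  names(c_i) <- rownames(a)
  .pick_nodes(c_i, node)
}

#' @rdname clustering_binary
#' @export
clustering_onnela <- function(x, node = NULL) {
  stopifnot(inherits(x, "connectome"))
  sw <- scale_weights(x)^(1 / 3)
  k <- rowSums(x$weights > 0)
  tri <- diag(sw %*% sw %*% sw)
  c_i <- ifelse(k > 1, tri / (k * (k - 1)), 0)
  names(c_i) <- x$labels
  .pick_nodes(c_i, node)
}

#' @rdname clustering_binary
#' @export
clustering_zhang <- function(x, node = NULL) {
  stopifnot(inherits(x, "connectome"))
  sw <- scale_weights(x)
  num <- diag(sw %*% sw %*% sw)
  s1 <- rowSums(sw)
  s2 <- rowSums(sw^2)
  den <- s1^2 - s2
  c_i <- ifelse(den > 0, num / den, 0)
  names(c_i) <- x$labels
  .pick_nodes(c_i, node)
}

.pick_nodes <- function(v, node) {
  if (is.null(node)) return(v)
  idx <- match(node, names(v))
  if (anyNA(idx)) stop("unknown node label: ",
                       paste(node[is.na(idx)], collapse = ", "))
  v[idx]
}
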