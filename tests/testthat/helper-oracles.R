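# Shared fixtures and independent oracles for the test suite.

# small random weighted connectome with counts; weights uniform-ish so
# oracles stay simple
random_connectome <- function(n = 8, p = 0.5, seed = 1, counts = TRUE,
                              heavy_tail = FALSE) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- runif(length(ut)) < p
  vals <- if (heavy_tail) rlnorm(sum(on), log(1e-3), 2.3) else
    runif(sum(on), 0.05, 1)
  w[ut[on]] <- vals
  w <- w + t(w)
  k <- NULL
  if (counts) {
    k <- matrix(0, n, n)
    k[ut[on]] <- sample(1:200, sum(on), replace = TRUE)
    k <- k + t(k)
  }
  connectome(w, counts = k)
}

# connectome from an explicit undirected edge list
conn_from_edges <- function(n, edges, weights, counts = NULL,
                            labels = NULL) {
  w <- matrix(0, n, n)
  k <- if (is.null(counts)) NULL else matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    w[i, j] <- w[j, i] <- weights[r]
    if (!is.null(k)) k[i, j] <- k[j, i] <- counts[r]
  }
  connectome(w, counts = k, labels = labels)
}

# independent oracle: exhaustive enumeration of simple paths; among the
# minimum-hop paths between each pair, the maximum weight sum
oracle_minhop_maxweight <- function(x) {
  w <- x$weights
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix((w > 0) + 0, mode = "undirected")
  out <- matrix(NA_real_, n, n)
  diag(out) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      paths <- igraph::all_simple_paths(g, from = i, to = j)
      if (!length(paths)) next
      hops <- vapply(paths, function(p) length(p) - 1L, integer(1))
      minh <- min(hops)
      sums <- vapply(paths[hops == minh], function(p) {
        v <- as.integer(p)
        sum(w[cbind(v[-length(v)], v[-1])])
      }, numeric(1))
      out[i, j] <- out[j, i] <- max(sums)
    }
  }
  out
}

# independent oracle: binary clustering by explicit triple loop
oracle_clustering_binary <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    k <- sum(a[i, ])
    if (k < 2) return(0)
    tot <- 0
    for (j in seq_len(n)) {
      for (m in seq_len(n)) {
        tot <- tot + a[i, j] * a[j, m] * a[m, i]
      }
    }
    tot / (k * (k - 1))
  }, numeric(1))
}

# independent oracle: Onnela and Zhang clustering by triple loop over
# scaled weights
oracle_clustering_weighted <- function(w, variant) {
  sw <- w / max(w)
  a <- (w > 0) + 0
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    k <- sum(a[i, ])
    num <- 0
    for (j in seq_len(n)) {
      for (m in seq_len(n)) {
        term <- sw[i, j] * sw[j, m] * sw[m, i]
        if (variant == "onnela") term <- term^(1 / 3)
        num <- num + term
      }
    }
    if (variant == "onnela") {
      if (k < 2) 0 else num / (k * (k - 1))
    } else {
      den <- sum(sw[i, ])^2 - sum(sw[i, ]^2)
      if (den <= 0) 0 else num / den
    }
  }, numeric(1))
}

# independent oracle: hop distances by boolean matrix powers
oracle_hops <- function(a) {
  n <- nrow(a)
  out <- matrix(NA_real_, n, n)
  diag(out) <- 0
  reach <- diag(n) > 0
  pow <- diag(n)
  for (h in seq_len(n)) {
    pow <- (pow %*% a) > 0
    newly <- pow & !reach & is.na(out)
    out[newly] <- h
    reach <- reach | pow
  }
  out
}
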