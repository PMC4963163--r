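#' Read a connectome from a standard format
#'
#' Supported formats:
#' \describe{
#'   \item{`csv_matrix`}{first row = comma-separated node labels, then `N`
#'     rows of `N` comma-separated reals; one file per matrix role. `path`
#'     holds the weights matrix, `counts_path` (optional) the counts.}
#'   \item{`edge_list`}{tab-separated columns `node_a node_b weight count`
#'     with a header row; each undirected edge appears once, in either
#'     orientation. An empty `count` column yields a counts-free
#'     connectome.}
#'   \item{`graphml`}{undirected GraphML with edge attributes `weight` and
#'     (optionally) `count` and node attribute `label`.}
#' }
#'
#' Numeric matrix input that is asymmetric within `1e-12 * max(|a|)` is
#' symmetrized by averaging (with a message); larger asymmetry is an
#' error, since these networks are undirected by construction. A nonzero
#' diagonal is zeroed with a warning.
#'
#' @param path input file.
#' @param format one of `"csv_matrix"`, `"edge_list"`, `"graphml"`.
#' @param counts_path optional counts-matrix file (`csv_matrix` only).
#' @return a validated [connectome()].
#' @export
read_connectome <- function(path,
                            format = c("csv_matrix", "edge_list", "graphml"),
                            counts_path = NULL) {
  format <- match.arg(format)
  switch(format,
    csv_matrix = .read_csv_matrix(path, counts_path),
    edge_list = .read_edge_list(path),
    graphml = .read_graphml(path)
  )
}

#' Write a connectome to a standard format
#'
#' Inverse of [read_connectome()]; the round trip is lossless on labels
#' and counts and preserves weights to full double precision.
#'
#' @param x a `connectome`.
#' @param path output file (weights matrix for `csv_matrix`).
#' @param format one of `"csv_matrix"`, `"edge_list"`, `"graphml"`.
#' @param counts_path optional counts output (`csv_matrix` only); required
#'   there if `x` carries counts that should survive the round trip.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path,
                             format = c("csv_matrix", "edge_list", "graphml"),
                             counts_path = NULL) {
  stopifnot(inherits(x, "connectome"))
  format <- match.arg(format)
  switch(format,
    csv_matrix = {
      .write_csv_matrix(x$weights, x$labels, path)
      if (!is.null(counts_path)) {
        if (is.null(x$counts)) stop("connectome has no counts to write")
        .write_csv_matrix(x$counts, x$labels, counts_path)
      }
    },
    edge_list = {
      et <- edge_table(x)
      et$weight <- sprintf("%.17g", et$weight)
      utils::write.table(et, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
    },
    graphml = {
      igraph::write_graph(as_igraph_conn(x), path, format = "graphml")
    }
  )
  invisible(path)
}

.read_csv_matrix_one <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric %s entry at row %d, column %d of %s",
                 what, bad[1, 1], bad[1, 2], path))
  }
  if (nrow(m) != ncol(m)) {
    stop(sprintf("%s matrix in %s is not square: %d rows x %d columns",
                 what, path, nrow(m), ncol(m)))
  }
  list(m = m, labels = colnames(df))
}

.symmetrize <- function(m, what) {
  mx <- max(abs(m))
  tol <- 1e-12 * max(mx, 1)
  dev <- max(abs(m - t(m)))
  if (dev > tol) {
    bad <- which(abs(m - t(m)) == dev, arr.ind = TRUE)
    stop(sprintf(
      "%s matrix asymmetric beyond tolerance at (%d,%d): |a_ij - a_ji| = %g",
      what, bad[1, 1], bad[1, 2], dev))
  }
  if (dev > 0) {
    message(sprintf("symmetrized %s matrix by averaging (max deviation %g)",
                    what, dev))
    m <- (m + t(m)) / 2
  }
  if (any(diag(m) != 0)) {
    warning(sprintf("nonzero diagonal in %s matrix forced to zero", what))
    diag(m) <- 0
  }
  m
}

.read_csv_matrix <- function(path, counts_path) {
  w <- .read_csv_matrix_one(path, "weights")
  wm <- .symmetrize(w$m, "weights")
  if (any(wm < 0)) {
    bad <- which(wm < 0, arr.ind = TRUE)
    stop(sprintf("negative weight at (%d,%d) in %s",
                 bad[1, 1], bad[1, 2], path))
  }
  counts <- NULL
  if (!is.null(counts_path)) {
    k <- .read_csv_matrix_one(counts_path, "counts")
    if (!identical(k$labels, w$labels)) {
      stop("counts matrix labels do not match weights matrix labels")
    }
    km <- .symmetrize(k$m, "counts")
    off <- which(abs(km - round(km)) > 1e-9, arr.ind = TRUE)
    if (nrow(off)) {
      stop(sprintf("non-integer count at (%d,%d) in %s",
                   off[1, 1], off[1, 2], counts_path))
    }
    counts <- round(km)
  }
  connectome(wm, counts = counts, labels = w$labels,
             metadata = list(source = path, format = "csv_matrix"))
}

.read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "")
  need <- c("node_a", "node_b", "weight", "count")
  if (!all(need %in% names(df))) {
    stop("edge list must have header columns: ", paste(need, collapse = ", "))
  }
  labels <- sort(unique(c(df$node_a, df$node_b)))
  n <- length(labels)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  have_counts <- !all(is.na(df$count))
  k <- matrix(0, n, n, dimnames = list(labels, labels))
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(df))) {
    a <- df$node_a[r]; b <- df$node_b[r]
    if (is.na(a) || is.na(b)) stop("missing node label in edge row ", r)
    if (a == b) stop("self-edge at row ", r, " (", a, ")")
    key <- paste(sort(c(a, b)), collapse = "\r")
    wr <- df$weight[r]
    kr <- if (have_counts) df$count[r] else 0
    if (!is.null(seen[[key]])) {
      prev <- seen[[key]]
      if (prev$w != wr || prev$k != kr) {
        stop(sprintf("conflicting duplicate edge %s--%s at row %d", a, b, r))
      }
      next
    }
    assign(key, list(w = wr, k = kr), envir = seen)
    if (is.na(wr) || wr < 0) stop("invalid weight at row ", r)
    if (have_counts && (is.na(kr) || kr < 0 || kr != round(kr))) {
      stop("invalid (negative or non-integer) count at row ", r)
    }
    w[a, b] <- w[b, a] <- wr
    if (have_counts) k[a, b] <- k[b, a] <- kr
  }
  connectome(w, counts = if (have_counts) k else NULL, labels = labels,
             metadata = list(source = path, format = "edge_list"))
}

.read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  labels <- igraph::vertex_attr(g, "label")
  if (is.null(labels)) labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) labels <- paste0("n", seq_len(igraph::vcount(g)))
  n <- igraph::vcount(g)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  el <- igraph::as_edgelist(g, names = FALSE)
  ew <- igraph::edge_attr(g, "weight")
  if (is.null(ew)) stop("GraphML file lacks the edge attribute 'weight'")
  w[el] <- ew
  w[el[, c(2, 1), drop = FALSE]] <- ew
  counts <- NULL
  ek <- igraph::edge_attr(g, "count")
  if (!is.null(ek)) {
    counts <- matrix(0, n, n, dimnames = list(labels, labels))
    counts[el] <- ek
    counts[el[, c(2, 1), drop = FALSE]] <- ek
  }
  connectome(w, counts = counts, labels = labels,
             metadata = list(source = path, format = "graphml"))
}

.write_csv_matrix <- function(m, labels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = ","), con)
  apply_fmt <- function(row) paste(sprintf("%.17g", row), collapse = ",")
  writeLines(vapply(seq_len(nrow(m)), function(i) apply_fmt(m[i, ]),
                    character(1)), con)
}
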