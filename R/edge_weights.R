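#' Parcellation specification for edge-weight computation
#'
#' Holds the acquisition- and parcellation-level quantities entering the
#' dimensionless edge weight: the MR voxel volume `V` (mm^3), the number
#' of tractography seed points per voxel `P`, and the surface area `A_i`
#' (mm^2) of each node region.
#'
#' @param voxel_volume_mm3 positive scalar, MR voxel volume in mm^3.
#' @param seeds_per_voxel positive integer, seed points per voxel.
#' @param surface_areas_mm2 named positive numeric vector, node surface
#'   areas in mm^2 keyed by node label.
#' @return an object of class `parcellation_spec`.
#' @export
parcellation_spec <- function(voxel_volume_mm3, seeds_per_voxel,
                              surface_areas_mm2) {
  if (!is.numeric(voxel_volume_mm3) || voxel_volume_mm3 <= 0) {
    stop("voxel_volume_mm3 must be positive")
  }
  if (!is.numeric(seeds_per_voxel) || seeds_per_voxel < 1 ||
      seeds_per_voxel != round(seeds_per_voxel)) {
    stop("seeds_per_voxel must be a positive integer")
  }
  if (is.null(names(surface_areas_mm2)) || any(surface_areas_mm2 <= 0)) {
    stop("surface_areas_mm2 must be a named vector of positive areas")
  }
  structure(list(voxel_volume_mm3 = voxel_volume_mm3,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 surface_areas_mm2 = surface_areas_mm2),
            class = "parcellation_spec")
}

#' @export
print.parcellation_spec <- function(x, ...) {
  cat(sprintf(
    "Parcellation: V = %g mm^3, P = %d seeds/voxel, %d node areas\n",
    x$voxel_volume_mm3, x$seeds_per_voxel, length(x$surface_areas_mm2)))
  invisible(x)
}

#' Select the streamline set R for a node pair
#'
#' Returns exactly the streamline records whose two endpoints are nodes
#' `i` and `j` (in either order). Streamlines that originate inside one of
#' their endpoint nodes (seed voxel within the gray-matter region) can be
#' excluded, mirroring the filtering of seed-in-node streamlines during
#' network construction. Records with a missing endpoint belong to no
#' edge and are ignored (a message reports how many were skipped).
#'
#' @param streams data.frame of streamline records with columns
#'   `stream_id`, `seed_voxel`, `length_mm`, `node_a`, `node_b`,
#'   `seed_in_node` (endpoint columns may be `NA` for streamlines that
#'   terminate outside every node).
#' @param i,j distinct node labels.
#' @param exclude_seed_in_node drop records whose seed lies inside an
#'   endpoint node (default `TRUE`).
#' @return the subset of `streams` forming the set `R` for edge `(i, j)`.
#' @export
characteristic_filter <- function(streams, i, j, exclude_seed_in_node = TRUE) {
  if (identical(i, j)) stop("self-edges are undefined: i must differ from j")
  streams <- as.data.frame(streams)
  dangling <- is.na(streams$node_a) | is.na(streams$node_b)
  if (any(dangling)) {
    message(sum(dangling),
            " streamline(s) with a missing endpoint ignored")
    streams <- streams[!dangling, , drop = FALSE]
  }
  hit <- (streams$node_a == i & streams$node_b == j) |
         (streams$node_a == j & streams$node_b == i)
  if (exclude_seed_in_node) hit <- hit & !streams$seed_in_node
  streams[hit, , drop = FALSE]
}

#' Dimensionless edge weight from a streamline set
#'
#' Computes the connection-strength weight for the edge between nodes
#' `i` and `j` from the retained streamline set `R`:
#' \deqn{w(e_{ij}) = \frac{V}{P} \cdot \frac{2}{A_i + A_j}
#'   \sum_{f \in R} \frac{1}{l(f)}}
#' with `V` the voxel volume (mm^3), `P` the seeds per voxel, `A_i`,
#' `A_j` the node surface areas (mm^2) and `l(f)` the streamline length
#' (mm). The inverse-length sum makes each streamline contribute the
#' number of voxels it could have been seeded in, so the `V/P` prefactor
#' cancels the seeding paradigm and the area normalization cancels node
#' size: `w` is dimensionless and invariant under a uniform rescaling of
#' lengths (x s), areas (x s^2) and volume (x s^3).
#'
#' @param R data.frame of streamline records already filtered for the
#'   pair `(i, j)` (see [characteristic_filter()]).
#' @param spec a [parcellation_spec()] covering both node labels.
#' @param i,j node labels.
#' @return non-negative scalar weight; `0` when `R` is empty.
#' @export
edge_weight <- function(R, spec, i, j) {
  stopifnot(inherits(spec, "parcellation_spec"))
  areas <- spec$surface_areas_mm2
  for (lab in c(i, j)) {
    if (!lab %in% names(areas)) {
      stop("no surface area for node label: ", lab)
    }
  }
  if (nrow(R) == 0) return(0)
  l <- R$length_mm
  if (any(!is.finite(l) | l <= 0)) stop("streamline lengths must be positive")
  (spec$voxel_volume_mm3 / spec$seeds_per_voxel) *
    (2 / (areas[[i]] + areas[[j]])) * sum(1 / l)
}

#' Assemble a connectome from a streamline table
#'
#' Applies [characteristic_filter()] and [edge_weight()] to every
#' unordered node pair: the edge count is the size of the retained
#' streamline set and the edge weight its inverse-length sum weight.
#'
#' @param streams streamline data.frame (see [characteristic_filter()]).
#' @param spec a [parcellation_spec()].
#' @param node_labels unique labels of the network's nodes; every
#'   endpoint label appearing in `streams` must be listed here.
#' @param exclude_seed_in_node passed to [characteristic_filter()].
#' @return a [connectome()] with weights and counts.
#' @export
build_connectome <- function(streams, spec, node_labels,
                             exclude_seed_in_node = TRUE) {
  stopifnot(inherits(spec, "parcellation_spec"))
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  streams <- as.data.frame(streams)
  dangling <- is.na(streams$node_a) | is.na(streams$node_b)
  if (any(dangling)) {
    message(sum(dangling),
            " streamline(s) with a missing endpoint ignored")
    streams <- streams[!dangling, , drop = FALSE]
  }
  known <- c(streams$node_a, streams$node_b) %in% node_labels
  if (!all(known)) {
    stop("streamline references unknown node label: ",
         paste(unique(setdiff(c(streams$node_a, streams$node_b),
                              node_labels)), collapse = ", "))
  }
  if (exclude_seed_in_node && nrow(streams)) {
    streams <- streams[!streams$seed_in_node, , drop = FALSE]
  }
  n <- length(node_labels)
  w <- matrix(0, n, n, dimnames = list(node_labels, node_labels))
  k <- matrix(0, n, n, dimnames = list(node_labels, node_labels))
  if (nrow(streams)) {
    ia <- match(streams$node_a, node_labels)
    ib <- match(streams$node_b, node_labels)
    if (any(ia == ib)) stop("streamline with identical endpoints")
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    grp <- split(seq_len(nrow(streams)), paste(lo, hi))
    for (g in grp) {
      i <- lo[g[1]]; j <- hi[g[1]]
      k[i, j] <- k[j, i] <- length(g)
      wij <- (spec$voxel_volume_mm3 / spec$seeds_per_voxel) *
        (2 / (spec$surface_areas_mm2[[node_labels[i]]] +
              spec$surface_areas_mm2[[node_labels[j]]])) *
        sum(1 / streams$length_mm[g])
      w[i, j] <- w[j, i] <- wij
    }
  }
  connectome(w, counts = k, labels = node_labels,
             metadata = list(source = "streamline table",
                             exclude_seed_in_node = exclude_seed_in_node))
}

#' Ceiling on the streamline count of an edge
#'
#' With `P` seeds launched per voxel and an edge whose streamlines are
#' entirely contained in `M` voxels, at most `M * P` streamlines can
#' connect the two nodes. This ceiling anchors the choice of a
#' streamline-count threshold: a threshold of 25 against a ceiling of
#' `2 * 125 = 250` retains edges carrying at least 10% of the
#' streamlines the smallest plausible edge could produce.
#'
#' @param m_voxels positive integer, number of voxels making up the edge.
#' @param spec a [parcellation_spec()].
#' @return positive integer `m_voxels * seeds_per_voxel`.
#' @export
max_possible_streamlines <- function(m_voxels, spec) {
  stopifnot(inherits(spec, "parcellation_spec"))
  if (m_voxels < 1 || m_voxels != round(m_voxels)) {
    stop("m_voxels must be a positive integer")
  }
  as.integer(m_voxels) * spec$seeds_per_voxel
}

#' Read / write streamline tables and parcellation files
#'
#' Streamline tables are tab-separated with header columns `stream_id`,
#' `seed_voxel`, `length_mm`, `node_a`, `node_b`, `seed_in_node`; empty
#' endpoint fields encode streamlines terminating outside every node.
#' Parcellation files are plain key-value text: `voxel_volume_mm3=...`,
#' `seeds_per_voxel=...`, and one `area:<label>=<mm2>` line per node.
#'
#' @param path file path.
#' @return `read_streamlines`: a data.frame; `read_parcellation`: a
#'   [parcellation_spec()].
#' @export
read_streamlines <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "")
  need <- c("stream_id", "seed_voxel", "length_mm", "node_a", "node_b",
            "seed_in_node")
  if (!all(need %in% names(df))) {
    stop("streamline table must have columns: ", paste(need, collapse = ", "))
  }
  df$seed_in_node <- as.logical(df$seed_in_node)
  df
}

#' @rdname read_streamlines
#' @param streams streamline data.frame to write.
#' @export
write_streamlines <- function(streams, path) {
  utils::write.table(streams, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_streamlines
#' @export
read_parcellation <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  is_area <- startsWith(keys, "area:")
  areas <- as.numeric(vals[is_area])
  names(areas) <- sub("^area:", "", keys[is_area])
  getv <- function(k) {
    hit <- which(keys == k)
    if (!length(hit)) stop("parcellation file missing key: ", k)
    as.numeric(vals[hit[1]])
  }
  parcellation_spec(getv("voxel_volume_mm3"), getv("seeds_per_voxel"), areas)
}

#' @rdname read_streamlines
#' @param spec a [parcellation_spec()] to write.
#' @export
write_parcellation <- function(spec, path) {
  stopifnot(inherits(spec, "parcellation_spec"))
  lines <- c(
    sprintf("voxel_volume_mm3=%.17g", spec$voxel_volume_mm3),
    sprintf("seeds_per_voxel=%d", spec$seeds_per_voxel),
    sprintf("area:%s=%.17g", names(spec$surface_areas_mm2),
            spec$surface_areas_mm2)
  )
  writeLines(lines, path)
  invisible(path)
}
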