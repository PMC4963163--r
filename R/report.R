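#' Edge differences between two count thresholds
#'
#' Lists every edge surviving the lower threshold `t1` and marks whether
#' it also survives the higher threshold `t2`: edges with
#' `t1 <= count < t2` are `"removed"`, the rest `"kept"`. This is the
#' tabular analogue of comparing thresholded adjacency matrices.
#'
#' @param x a `connectome` with counts.
#' @param t1,t2 integer thresholds with `t1 <= t2`.
#' @return data.frame with columns `node_a`, `node_b`, `count`,
#'   `weight`, `status`.
#' @export
threshold_difference <- function(x, t1, t2) {
  stopifnot(inherits(x, "connectome"))
  if (is.null(x$counts)) stop("connectome has no streamline counts")
  if (t1 > t2) stop("t1 must not exceed t2")
  et <- edge_table(if (t1 > 0) threshold_counts(x, t1) else x)
  et$status <- ifelse(et$count < t2, "removed", "kept")
  et
}

#' Run the full threshold-sweep analysis and write report files
#'
#' For every requested streamline-count threshold this writes graph
#' density, per-node metric vectors (degree, strength, mean binary and
#' weighted geodesic path length, binary/Onnela/Zhang clustering), the
#' complementary cumulative degree and strength distributions, the
#' small-worldness table across modes, and an edge-difference report
#' between the lowest and each higher threshold. A run manifest records
#' the configuration, seed, package version and an input fingerprint.
#' All outputs are tab-separated text, deterministic given the seed.
#'
#' @param x a `connectome` with counts.
#' @param out_dir output directory (created if absent).
#' @param thresholds ascending integer thresholds (default
#'   `c(0, 25, 50, 125)`).
#' @param modes small-worldness modes to evaluate.
#' @param n_replicates null replicates per small-worldness cell.
#' @param rng_seed integer seed.
#' @param verbose print per-stage progress lines (default `TRUE`).
#' @return invisibly, the named list of written file paths.
#' @export
run_full_analysis <- function(x, out_dir,
                              thresholds = c(0, 25, 50, 125),
                              modes = c("binary", "onnela", "zhang"),
                              n_replicates = 1, rng_seed = 1,
                              verbose = TRUE) {
  stopifnot(inherits(x, "connectome"))
  thresholds <- sort(unique(as.integer(thresholds)))
  if (any(thresholds < 0)) stop("thresholds must be non-negative")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  dens <- list(); nodes <- list(); cum <- list()
  for (t in thresholds) {
    xt <- if (t > 0) threshold_counts(x, t) else x
    say("[density] threshold %d: %d edges over %d nodes", t,
        edge_count(xt), n_nodes(xt))
    dens[[length(dens) + 1]] <- data.frame(
      threshold = t, n_edges = edge_count(xt), density = graph_density(xt))
    deg <- node_degree(xt)
    str <- node_strength(xt)
    metr <- list(degree = deg, strength = str,
                 clustering_binary = clustering_binary(xt),
                 clustering_onnela = clustering_onnela(xt),
                 clustering_zhang = clustering_zhang(xt))
    conn <- !anyNA(binary_geodesics(xt)$values)
    if (conn) {
      metr$mean_path_binary <- mean_geodesic(binary_geodesics(xt))
      metr$mean_path_weighted <- mean_geodesic(weighted_geodesics(xt))
    } else {
      say("[paths] threshold %d: graph disconnected, path metrics skipped", t)
    }
    for (mn in names(metr)) {
      nodes[[length(nodes) + 1]] <- data.frame(
        threshold = t, node = names(metr[[mn]]), metric = mn,
        value = unname(metr[[mn]]), stringsAsFactors = FALSE)
    }
    for (mn in c("degree", "strength")) {
      cd <- cumulative_distribution(metr[[mn]])
      cum[[length(cum) + 1]] <- data.frame(
        threshold = t, metric = mn, value = cd$value,
        fraction = cd$fraction)
    }
  }
  say("[smallworld] %d thresholds x %d modes, %d null replicate(s)",
      length(thresholds), length(modes), n_replicates)
  sweep <- smallworld_sweep(x, thresholds = thresholds, modes = modes,
                            n_replicates = n_replicates,
                            rng_seed = rng_seed)

  diffs <- list()
  tmin <- thresholds[1]
  for (t in thresholds[-1]) {
    td <- threshold_difference(x, tmin, t)
    td <- cbind(t_low = tmin, t_high = t, td)
    diffs[[length(diffs) + 1]] <- td
  }

  wtsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  files <- list(
    density = wtsv(do.call(rbind, dens), "density.tsv"),
    node_metrics = wtsv(do.call(rbind, nodes), "node_metrics.tsv"),
    cumulative = wtsv(do.call(rbind, cum), "cumulative_distributions.tsv"),
    smallworld = wtsv(as.data.frame(sweep), "smallworld.tsv")
  )
  if (length(diffs)) {
    files$threshold_differences <- wtsv(do.call(rbind, diffs),
                                        "threshold_differences.tsv")
  }
  manifest <- c(
    sprintf("package_version=%s",
            as.character(utils::packageVersion("wconn"))),
    sprintf("rng_seed=%d", rng_seed),
    sprintf("thresholds=%s", paste(thresholds, collapse = ",")),
    sprintf("modes=%s", paste(modes, collapse = ",")),
    sprintf("n_null_replicates=%d", n_replicates),
    sprintf("input_nodes=%d", n_nodes(x)),
    sprintf("input_edges=%d", edge_count(x)),
    sprintf("input_total_weight=%.17g", sum(x$weights) / 2)
  )
  mpath <- file.path(out_dir, "run_manifest.txt")
  writeLines(manifest, mpath)
  files$manifest <- mpath
  say("[done] %d report files in %s (%.2f s)", length(files), out_dir,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(files)
}
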