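#' Network-average clustering and path length
#'
#' `network_average_clustering` averages the chosen clustering
#' coefficient over all nodes. `network_average_path` averages the
#' per-node mean geodesic path lengths: hop counts in binary mode, the
#' min-hop/max-weight path sums in weighted mode. The clustering modes
#' `onnela` and `zhang` pair with weighted paths; `binary` with hop
#' counts.
#'
#' @param x a `connectome`.
#' @param mode `"binary"`, `"onnela"` or `"zhang"` for clustering;
#'   `"binary"` or `"weighted"` for paths.
#' @return scalar network average.
#' @export
network_average_clustering <- function(x,
                                       mode = c("binary", "onnela",
                                                "zhang")) {
  mode <- match.arg(mode)
  v <- switch(mode,
    binary = clustering_binary(x),
    onnela = clustering_onnela(x),
    zhang = clustering_zhang(x)
  )
  mean(v)
}

#' @rdname network_average_clustering
#' @export
network_average_path <- function(x, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  p <- if (mode == "binary") binary_geodesics(x) else weighted_geodesics(x)
  mean(mean_geodesic(p))
}

path_mode_for <- function(mode) {
  if (mode == "binary") "binary" else "weighted"
}

#' Small-worldness of a weighted or binary connectome
#'
#' Fits the small-worldness statistic of a connectome against an
#' ensemble of dual-constrained null networks (degree sequence and
#' edge-weight multiset preserved; see [generate_null_ensemble()]):
#' \deqn{\gamma = c_g / c_N, \quad \lambda = l_g / l_N, \quad
#'       sw = \gamma / \lambda}
#' where `c_g`, `l_g` are the source network's average clustering and
#' average geodesic path length in the chosen mode, and `c_N`, `l_N` are
#' the means of the same quantities over the null replicates. A
#' small-world network has `gamma > 1` with `lambda ~ 1`, hence
#' `sw > 1`. Clustering and path length always come from the same
#' framework: binary clustering is never mixed with weighted paths.
#'
#' @param x a connected `connectome`.
#' @param mode `"binary"` (hop paths, binary clustering), `"onnela"` or
#'   `"zhang"` (min-hop/max-weight paths with the respective weighted
#'   clustering).
#' @param config a [null_model_config()]; `n_replicates` controls the
#'   size of the null ensemble.
#' @return an object of class `smallworld`: a list with `mode`, `c_g`,
#'   `l_g`, `c_null`, `l_null`, `gamma`, `lambda`, `sw`, `n_null`, and
#'   `dispersion` (standard deviations of gamma, lambda and sw across
#'   single-replicate nulls; `NA` when `n_replicates = 1`).
#' @examples
#' cn <- generate_connectome(synth_config(n_nodes = 30, rng_seed = 7))
#' sw <- small_worldness(cn, mode = "zhang",
#'                       config = null_model_config(n_replicates = 3,
#'                                                  rng_seed = 7))
#' print(sw)
#' @export
small_worldness <- function(x, mode = c("binary", "onnela", "zhang"),
                            config = null_model_config()) {
  stopifnot(inherits(x, "connectome"))
  mode <- match.arg(mode)
  pm <- path_mode_for(mode)
  c_g <- network_average_clustering(x, mode)
  l_g <- network_average_path(x, pm)
  ens <- generate_null_ensemble(x, config)
  c_reps <- vapply(ens$replicates, network_average_clustering, numeric(1),
                   mode = mode)
  l_reps <- vapply(ens$replicates, network_average_path, numeric(1),
                   mode = pm)
  c_null <- mean(c_reps)
  l_null <- mean(l_reps)
  if (c_null <= 0 || l_null <= 0) {
    stop(sprintf(
      "degenerate null ensemble (c_N = %g, l_N = %g): %s undefined",
      c_null, l_null, "small-worldness"))
  }
  gamma <- c_g / c_null
  lambda <- l_g / l_null
  n <- length(c_reps)
  disp <- if (n > 1) {
    g_r <- c_g / c_reps
    l_r <- l_g / l_reps
    c(gamma = stats::sd(g_r), lambda = stats::sd(l_r),
      sw = stats::sd(g_r / l_r))
  } else {
    c(gamma = NA_real_, lambda = NA_real_, sw = NA_real_)
  }
  structure(
    list(mode = mode, c_g = c_g, l_g = l_g, c_null = c_null,
         l_null = l_null, gamma = gamma, lambda = lambda,
         sw = gamma / lambda, n_null = n, dispersion = disp,
         config = config),
    class = "smallworld"
  )
}

#' @export
print.smallworld <- function(x, ...) {
  cat(sprintf("Small-worldness (%s mode, %d null replicate%s)\n",
              x$mode, x$n_null, if (x$n_null == 1) "" else "s"))
  cat(sprintf("  clustering:   c_g = %.4g, c_N = %.4g  ->  gamma  = %.3f\n",
              x$c_g, x$c_null, x$gamma))
  cat(sprintf("  path length:  l_g = %.4g, l_N = %.4g  ->  lambda = %.3f\n",
              x$l_g, x$l_null, x$lambda))
  cat(sprintf("  sw = gamma / lambda = %.3f\n", x$sw))
  if (!is.na(x$dispersion[["sw"]])) {
    cat(sprintf("  null dispersion: sd(gamma) = %.3f, sd(lambda) = %.3f, sd(sw) = %.3f\n",
                x$dispersion[["gamma"]], x$dispersion[["lambda"]],
                x$dispersion[["sw"]]))
  }
  invisible(x)
}

#' @export
summary.smallworld <- function(object, ...) {
  print(object)
  verdict <- if (object$sw > 1 && object$gamma > 1) {
    "small-world organization (gamma > 1, sw > 1)"
  } else {
    "no small-world organization detected (sw <= 1 or gamma <= 1)"
  }
  cat("  interpretation:", verdict, "\n")
  invisible(object)
}

#' Small-worldness across count thresholds and modes
#'
#' Applies each streamline-count threshold to the connectome, computes
#' the small-worldness statistic in each requested mode, and assembles a
#' long-form table (one row per threshold x mode) with the network and
#' null averages, gamma, lambda, sw and their null-ensemble dispersion.
#'
#' @param x a `connectome` with counts (counts are only required when a
#'   nonzero threshold is requested).
#' @param thresholds integer vector of streamline-count cutoffs,
#'   ascending (default `c(0, 25, 50, 125)`).
#' @param modes subset of `c("binary", "onnela", "zhang")`.
#' @param n_replicates null replicates per cell.
#' @param swaps_per_edge swaps per edge for the rewiring.
#' @param rng_seed integer seed.
#' @return a data.frame of class `smallworld_sweep` with columns
#'   `threshold`, `mode`, `density`, `c_g`, `l_g`, `gamma`, `lambda`,
#'   `sw`, `sd_gamma`, `sd_lambda`, `sd_sw`.
#' @export
smallworld_sweep <- function(x, thresholds = c(0, 25, 50, 125),
                             modes = c("binary", "onnela", "zhang"),
                             n_replicates = 1, swaps_per_edge = 10,
                             rng_seed = 1) {
  stopifnot(inherits(x, "connectome"))
  thresholds <- sort(unique(as.integer(thresholds)))
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    xt <- if (t > 0) threshold_counts(x, t) else x
    for (mi in seq_along(modes)) {
      m <- modes[mi]
      cell_seed <- (rng_seed + 7919 * ti + 104729 * mi) %% 2147483647
      cfg <- null_model_config(swaps_per_edge = swaps_per_edge,
                               n_replicates = n_replicates,
                               rng_seed = cell_seed)
      sw <- small_worldness(xt, mode = m, config = cfg)
      rows[[length(rows) + 1]] <- data.frame(
        threshold = t, mode = m, density = graph_density(xt),
        c_g = sw$c_g, l_g = sw$l_g, gamma = sw$gamma, lambda = sw$lambda,
        sw = sw$sw, sd_gamma = sw$dispersion[["gamma"]],
        sd_lambda = sw$dispersion[["lambda"]],
        sd_sw = sw$dispersion[["sw"]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("smallworld_sweep", "data.frame")
  attr(out, "rng_seed") <- rng_seed
  out
}

#' @export
print.smallworld_sweep <- function(x, ...) {
  cat("Small-worldness across streamline-count thresholds\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Plot a small-worldness sweep
#'
#' Draws `sw` against the count threshold, one line per mode, with the
#' `sw = 1` reference.
#'
#' @param x a `smallworld_sweep`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.smallworld_sweep <- function(x, ...) {
  df <- as.data.frame(x)
  modes <- unique(df$mode)
  thr <- sort(unique(df$threshold))
  m <- sapply(modes, function(md) {
    df$sw[df$mode == md][match(thr, df$threshold[df$mode == md])]
  })
  graphics::matplot(thr, m, type = "b", pch = seq_along(modes), lty = 1,
                    xlab = "streamline-count threshold",
                    ylab = "small-worldness sw", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topleft", legend = modes, pch = seq_along(modes),
                   col = seq_along(modes), lty = 1, bty = "n")
  invisible(x)
}
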