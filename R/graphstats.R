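# Structural and spectral diagnostics of the SCN graph.
#
# Structural metrics (efficiency, clustering) are computed on the unweighted
# edge pattern: weights modulate the dynamics, not the topology. The spectral
# Laplacian uses the weighted adjacency, so weight-reduction experiments are
# visible in the spectrum.

# Accept scn_network or igraph.
as_pattern_graph <- function(network) {
  if (inherits(network, "igraph")) {
    g <- network
    if ("weight" %in% igraph::edge_attr_names(g))
      g <- igraph::delete_edge_attr(g, "weight")
    g
  } else as_igraph(network, weighted = FALSE)
}

#' Global efficiency
#'
#' `E = 1 / (N (N - 1)) * sum_{i != j} 1 / l_ij`, with `l_ij` the unweighted
#' shortest-path length and `1 / Inf = 0` for disconnected pairs. `E` is an
#' indicator of the traffic capacity of the network, inversely related to the
#' mean shortest path but well defined on disconnected graphs; it equals 1
#' for a complete graph and 0 for an edgeless one.
#'
#' @param network an `scn_network` or `igraph` graph.
#' @return Efficiency in `[0, 1]`.
#' @export
efficiency <- function(network) {
  g <- as_pattern_graph(network)
  n <- igraph::vcount(g)
  if (n < 2) stop_scn("efficiency needs at least 2 nodes")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Average clustering coefficient
#'
#' Per node, the fraction of realized links among the `k_i (k_i - 1) / 2`
#' possible links between its neighbours; nodes with fewer than two
#' neighbours contribute 0. `C` is the average over all nodes.
#'
#' @param network an `scn_network` or `igraph` graph.
#' @return Clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(network) {
  g <- as_pattern_graph(network)
  if (igraph::vcount(g) < 1) stop_scn("empty graph")
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  ci[!is.finite(ci)] <- 0
  mean(ci)
}

#' Local-mean-field Laplacian of the network
#'
#' `L_ij = delta_ij - W_ij / k_i`, with `W` the (weighted) adjacency and `k_i`
#' the neighbour count of node `i`. Because of the row normalization by `k_i`
#' the matrix is generally not symmetric, so its singular values rather than
#' eigenvalues characterize synchronization. Rows of isolated nodes (degree
#' 0) are set to the identity row; such nodes are pruned before spectral
#' analysis (see [near_zero_singular_count()]).
#'
#' @param network an `scn_network`.
#' @param weighted use edge weights (default) or the 0/1 pattern.
#' @return A dense base matrix.
#' @export
laplacian <- function(network, weighted = TRUE) {
  stopifnot(inherits(network, "scn_network"))
  W <- as.matrix(adjacency_matrix(network, weighted = weighted))
  k <- network$degree
  kinv <- ifelse(k > 0, 1 / k, 0)
  diag(nrow(W)) - W * kinv          # row i scaled by 1/k_i
}

#' Singular spectrum of the Laplacian and near-zero count
#'
#' Completely disconnected cells are removed first (each contributes a
#' trivial zero singular value); the singular values of the pruned
#' local-mean-field Laplacian are then computed and the number below
#' `threshold` is returned. One near-zero value (the trivial zero of a
#' connected graph) is always present; additional near-zero singular values
#' flag communities of oscillators that are well connected internally but
#' poorly connected to each other and therefore fail to synchronize their
#' phases, broadening the phase distribution.
#'
#' @param network an `scn_network`.
#' @param threshold near-zero threshold (default `1e-6`).
#' @param weighted use edge weights in the Laplacian.
#' @return An object of class `spectral_summary`: list with `singular_values`
#'   (ascending), `n_near_zero`, `n_pruned`, and `threshold`.
#' @export
near_zero_singular_count <- function(network, threshold = 1e-6,
                                     weighted = TRUE) {
  stopifnot(inherits(network, "scn_network"))
  keep <- which(network$degree > 0)
  n_pruned <- network$N - length(keep)
  if (!length(keep)) {
    warning("all nodes are disconnected; empty pruned graph")
    return(structure(list(singular_values = numeric(0), n_near_zero = 0L,
                          n_pruned = n_pruned, threshold = threshold),
                     class = "spectral_summary"))
  }
  W <- as.matrix(adjacency_matrix(network, weighted = weighted))[keep, keep]
  k <- network$degree[keep]
  L <- diag(length(keep)) - W / k
  sv <- sort(svd(L, nu = 0, nv = 0)$d)
  structure(list(singular_values = sv,
                 n_near_zero = sum(sv < threshold),
                 n_pruned = n_pruned, threshold = threshold),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d singular values, %d below %g (%d nodes pruned)\n",
              length(x$singular_values), x$n_near_zero, x$threshold,
              x$n_pruned))
  invisible(x)
}

#' Small-world scan over the long-range connection probability
#'
#' Builds replicate networks across a grid of `delta`, computes the global
#' efficiency `E`, the clustering coefficient `C` and their product `C * E`
#' (the small-world indicator, maximal where clustering and efficiency are
#' jointly high), and reports per-`delta` replicate means. Optionally all
#' three means are min-max rescaled to the unit interval across the scan.
#'
#' @param config a template [network_config()]; its `delta` is overridden.
#' @param delta_grid numeric vector of `delta` values.
#' @param replicates networks per `delta` value.
#' @param seed integer; replicate seeds are derived from it.
#' @param normalize logical; rescale the `E`, `C`, `CE` means to `[0, 1]`.
#' @return data.frame with columns `delta`, `E`, `C`, `CE` (and `E_sd`,
#'   `C_sd`, `CE_sd`).
#' @export
small_world_scan <- function(config, delta_grid, replicates = 10, seed = 1,
                             normalize = FALSE) {
  stopifnot(inherits(config, "network_config"), replicates >= 1)
  rows <- lapply(delta_grid, function(dl) {
    per <- vapply(seq_len(replicates), function(r) {
      cfg <- config
      cfg$delta <- dl
      cfg$seed <- scn_subseed(seed, paste0("sw-", dl, "-", r))
      net <- build_network(cfg)
      E <- efficiency(net)
      C <- clustering_coefficient(net)
      c(E = E, C = C, CE = C * E)
    }, numeric(3))
    data.frame(delta = dl,
               E = mean(per["E", ]), C = mean(per["C", ]),
               CE = mean(per["CE", ]),
               E_sd = stats::sd(per["E", ]), C_sd = stats::sd(per["C", ]),
               CE_sd = stats::sd(per["CE", ]))
  })
  out <- do.call(rbind, rows)
  if (normalize) {
    resc <- function(v) if (diff(range(v)) > 0)
      (v - min(v)) / diff(range(v)) else v * 0
    out$E <- resc(out$E); out$C <- resc(out$C); out$CE <- resc(out$CE)
  }
  out
}
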