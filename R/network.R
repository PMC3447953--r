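#' Configuration of the two-region SCN network
#'
#' The SCN is modelled on the unit square: ventrolateral (VL) cells occupy the
#' lower band `y < f_vl` and receive light; dorsomedial (DM) cells occupy the
#' band above and are coupled as a random geometric graph of short-range
#' connections with target mean degree `k_mean`. Long-range connections are
#' added independently per unordered cell pair with probability `delta`
#' between regions and `delta * intra_factor` within a region. `delta` is the
#' seasonal control parameter: the defaults `delta = 0.005` (summer) and
#' `delta = 0.01` (winter) at `N = 600` add about 450 and 900 long-range
#' connections respectively, and scale as `1/N` for other network sizes.
#'
#' @param N number of cells (>= 2).
#' @param f_vl fraction of VL cells (default 1/3).
#' @param k_mean target mean short-range degree of the DM geometric graph.
#' @param delta long-range inter-region connection probability in `[0, 1]`.
#' @param intra_factor multiplier for same-region long-range pairs (default
#'   0.1, i.e. a ten times smaller probability).
#' @param seed integer root seed; split into independent streams for
#'   placement, geometry and long-range wiring.
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 600, f_vl = 1 / 3, k_mean = 6, delta = 0.005,
                           intra_factor = 0.1, seed = 1) {
  assert_scalar(N, "N", lower = 2)
  assert_scalar(f_vl, "f_vl", lower = 0, upper = 1)
  assert_scalar(k_mean, "k_mean")
  assert_scalar(delta, "delta", lower = 0, upper = 1)
  assert_scalar(intra_factor, "intra_factor", lower = 0, upper = 1)
  assert_scalar(seed, "seed")
  structure(list(N = as.integer(N), f_vl = f_vl, k_mean = k_mean,
                 delta = delta, intra_factor = intra_factor,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Seasonal presets for the network configuration
#'
#' Convenience constructors for the summer (`delta = 0.005`) and winter
#' (`delta = 0.01`) topologies at `N = 600`, with `delta` rescaled by `600/N`
#' for other sizes so that the expected long-range connection count is
#' size-independent.
#'
#' @param N number of cells.
#' @param seed integer seed.
#' @param ... overrides passed to [network_config()].
#' @return A [network_config()].
#' @export
summer_config <- function(N = 600, seed = 1, ...) {
  network_config(N = N, delta = 0.005 * 600 / N, seed = seed, ...)
}

#' @rdname summer_config
#' @export
winter_config <- function(N = 600, seed = 1, ...) {
  network_config(N = N, delta = 0.01 * 600 / N, seed = seed, ...)
}

#' Place cells in the two-region domain
#'
#' `round(N * f_vl)` VL cells are placed uniformly at random in the lower band
#' `[0, 1] x [0, f_vl)` of the unit square and listed first (ids
#' `1..N_VL`); the remaining DM cells are placed uniformly in the band above.
#'
#' @param config a [network_config()].
#' @return data.frame with columns `id`, `x`, `y`, `region` (`"VL"`/`"DM"`),
#'   `rhythmic`.
#' @export
place_cells <- function(config) {
  stopifnot(inherits(config, "network_config"))
  N <- config$N
  n_vl <- as.integer(round(N * config$f_vl))
  n_dm <- N - n_vl
  band <- config$f_vl
  with_rng(scn_subseed(config$seed, "placement"), {
    data.frame(
      id = seq_len(N),
      x = stats::runif(N),
      y = c(stats::runif(n_vl, 0, band), stats::runif(n_dm, band, 1)),
      region = rep(c("VL", "DM"), c(n_vl, n_dm)),
      rhythmic = rep(c(FALSE, TRUE), c(n_vl, n_dm))
    )
  })
}

#' Short-range edges: random geometric graph over the DM region
#'
#' Every pair of DM cells within Euclidean distance `r` of each other is
#' connected, with `r = sqrt(k_mean / (pi * rho))` and `rho` the DM cell
#' density (DM count over the DM band's area), so that the expected mean
#' degree away from the boundary equals `k_mean`. VL cells receive no
#' short-range connections ("core" cells are mutually unconnected).
#'
#' @param cells a cell table from [place_cells()].
#' @param k_mean target mean degree; `k_mean <= 0` yields no edges (with a
#'   warning).
#' @param f_vl height of the VL band (used for the DM area; defaults to the
#'   fraction of VL cells in `cells`).
#' @return data.frame of edges `i`, `j` (`i < j`), `weight` (1), `class`
#'   (`"short"`).
#' @export
connect_rgg <- function(cells, k_mean, f_vl = NULL) {
  empty <- data.frame(i = integer(0), j = integer(0), weight = numeric(0),
                      class = character(0))
  if (k_mean <= 0) {
    warning("k_mean <= 0: no short-range edges")
    return(empty)
  }
  dm <- cells[cells$region == "DM", , drop = FALSE]
  if (nrow(dm) < 2L) return(empty)
  f_vl <- f_vl %||% mean(cells$region == "VL")
  rho <- nrow(dm) / (1 - f_vl)      # density over the DM band area 1*(1-f_vl)
  r <- sqrt(k_mean / (pi * rho))
  d <- as.matrix(stats::dist(cbind(dm$x, dm$y)))
  hit <- which(upper.tri(d) & d <= r, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  data.frame(i = dm$id[hit[, 1L]], j = dm$id[hit[, 2L]],
             weight = 1, class = "short")
}

#' Long-range edges: Bernoulli trials over all cell pairs
#'
#' Each unordered VL-DM pair gains a long-range edge with probability `delta`;
#' same-region pairs (VL-VL and DM-DM) with probability
#' `delta * intra_factor`. Pairs already connected by a short-range edge are
#' skipped.
#'
#' @param cells cell table from [place_cells()].
#' @param existing_edges data.frame of already-present edges (may be empty).
#' @param delta inter-region probability in `[0, 1]`.
#' @param intra_factor same-region probability multiplier in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame of added edges with `class = "long"`.
#' @export
add_long_range <- function(cells, existing_edges, delta, intra_factor = 0.1,
                           seed = 1) {
  assert_scalar(delta, "delta", lower = 0, upper = 1)
  assert_scalar(intra_factor, "intra_factor", lower = 0, upper = 1)
  empty <- data.frame(i = integer(0), j = integer(0), weight = numeric(0),
                      class = character(0))
  if (delta == 0) return(empty)
  N <- nrow(cells)
  pr <- utils::combn(N, 2L)
  i <- cells$id[pr[1L, ]]
  j <- cells$id[pr[2L, ]]
  same <- cells$region[pr[1L, ]] == cells$region[pr[2L, ]]
  p <- ifelse(same, delta * intra_factor, delta)
  if (nrow(existing_edges)) {
    key <- function(a, b) pmin(a, b) * (N + 1) + pmax(a, b)
    p[key(i, j) %in% key(existing_edges$i, existing_edges$j)] <- 0
  }
  take <- with_rng(seed, stats::runif(length(p)) < p)
  if (!any(take)) return(empty)
  data.frame(i = i[take], j = j[take], weight = 1, class = "long")
}

#' Build the full two-region SCN network
#'
#' Composes cell placement, the DM random geometric graph, and the
#' delta-controlled long-range wiring. The edge pattern is symmetric
#' (bidirectional coupling), without self- or duplicate edges; each edge
#' carries a weight in `(0, 1]` (default 1) and a construction class
#' (`"short"` or `"long"`).
#'
#' @param config a [network_config()].
#' @return An object of class `scn_network`: list with `cells`, `edges`,
#'   `degree` (per-node neighbour counts), `N` and `config`.
#' @export
#' @examples
#' net <- build_network(network_config(N = 60, seed = 2))
#' sum(net$degree) == 2 * nrow(net$edges)
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  cells <- place_cells(config)
  short <- connect_rgg(cells, config$k_mean, f_vl = config$f_vl)
  long <- add_long_range(cells, short, config$delta, config$intra_factor,
                         seed = scn_subseed(config$seed, "long_range"))
  edges <- rbind(short, long)
  edges <- edges[order(edges$class != "short", edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(cells = cells, edges = edges, N = config$N,
                        config = config),
                   class = "scn_network")
  net$degree <- network_degree(net)
  net
}

# Per-node neighbour counts (unweighted, from the edge pattern).
network_degree <- function(network) {
  deg <- integer(network$N)
  if (nrow(network$edges)) {
    t1 <- tabulate(network$edges$i, nbins = network$N)
    t2 <- tabulate(network$edges$j, nbins = network$N)
    deg <- t1 + t2
  }
  deg
}

#' @export
print.scn_network <- function(x, ...) {
  cat(sprintf(
    "<scn_network> N=%d (%d VL, %d DM), %d short + %d long edges, mean degree %.2f\n",
    x$N, sum(x$cells$region == "VL"), sum(x$cells$region == "DM"),
    sum(x$edges$class == "short"), sum(x$edges$class == "long"),
    mean(x$degree)))
  invisible(x)
}

#' Weighted adjacency matrix of an SCN network
#'
#' @param network an [build_network()] result.
#' @param weighted logical; use edge weights (`TRUE`) or the 0/1 pattern.
#' @return A symmetric sparse `Matrix::dgCMatrix`.
#' @export
adjacency_matrix <- function(network, weighted = TRUE) {
  e <- network$edges
  w <- if (weighted) e$weight else rep(1, nrow(e))
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i), x = c(w, w),
                       dims = c(network$N, network$N))
}

#' Rescale the weights of a random subset of edges
#'
#' Multiplies the weights of a seeded-random fraction of the edges of one
#' construction class by `factor`, leaving the edge pattern (and hence all
#' structural metrics) unchanged. This emulates synaptic-plasticity weakening
#' of long-range connections, e.g. reducing the coupling strength by 75% for
#' half of the long-range connections of a winter network.
#'
#' @param network an `scn_network`.
#' @param class edge class to select (`"short"` or `"long"`).
#' @param fraction fraction of that class to rescale, in `[0, 1]`.
#' @param factor nonnegative weight multiplier.
#' @param seed integer seed for the subset draw.
#' @return A new `scn_network` with updated weights.
#' @export
scale_edge_weights <- function(network, class = "long", fraction = 1,
                               factor = 1, seed = 1) {
  if (!class %in% c("short", "long"))
    stop_scn("unknown edge class '%s'", class)
  assert_scalar(fraction, "fraction", lower = 0, upper = 1)
  assert_scalar(factor, "factor", lower = 0)
  sel <- which(network$edges$class == class)
  n_take <- as.integer(round(fraction * length(sel)))
  if (n_take > 0) {
    take <- with_rng(seed, sample(sel, n_take))
    network$edges$weight[take] <- network$edges$weight[take] * factor
  }
  network
}
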