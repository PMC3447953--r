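# Independent brute-force oracles and hand-built fixtures used across tests.

# Build an scn_network directly from a cell table and edge list (bypasses the
# random constructors, for exactly controlled fixtures).
manual_network <- function(cells, edges) {
  net <- structure(list(cells = cells, edges = edges, N = nrow(cells),
                        config = NULL),
                   class = "scn_network")
  net$degree <- scnsim:::network_degree(net)
  net
}

# A path graph 1-2-3-...-n as an scn_network (all DM cells).
path_network <- function(n, weights = rep(1, n - 1)) {
  cells <- data.frame(id = seq_len(n), x = seq(0, 1, length.out = n), y = 0.5,
                      region = "DM", rhythmic = TRUE)
  edges <- data.frame(i = seq_len(n - 1), j = 2:n, weight = weights,
                      class = "short")
  manual_network(cells, edges)
}

# Random Erdos-Renyi pattern as an scn_network.
random_graph_network <- function(n, p, seed) {
  set.seed(seed)
  pr <- utils::combn(n, 2)
  take <- stats::runif(ncol(pr)) < p
  cells <- data.frame(id = seq_len(n), x = stats::runif(n),
                      y = stats::runif(n), region = "DM", rhythmic = TRUE)
  edges <- data.frame(i = pr[1, take], j = pr[2, take], weight = 1,
                      class = "short")
  manual_network(cells, edges)
}

# Brute-force all-pairs shortest paths by breadth-first search on an edge list.
bf_distances <- function(n, edges) {
  adj <- lapply(seq_len(n), function(i)
    c(edges$j[edges$i == i], edges$i[edges$j == i]))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- lev
      frontier <- nxt
    }
  }
  d
}

bf_efficiency <- function(net) {
  n <- net$N
  d <- bf_distances(n, net$edges)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

# Brute-force local clustering: enumerate links among each node's neighbours.
bf_clustering <- function(net) {
  n <- net$N
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(net$edges))) {
    A[net$edges$i[k], net$edges$j[k]] <- 1
    A[net$edges$j[k], net$edges$i[k]] <- 1
  }
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(ci)
}

with_rng_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Small ready-made simulation shared by several test files (memoized).
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

small_pop <- function(n, seed = 7, f = 1 / 3) {
  sample_poincare_population(n, f_nonrhythmic = f, seed = seed)
}

# Matched small summer/winter simulations (N = 120) used by the seasonal
# ordering tests; deltas rescaled by 600/N as in the size-extrapolation rule.
seasonal_runs <- function() {
  cached("seasonal", {
    N <- 120
    pop <- small_pop(N, seed = 5)
    sim <- sim_config(cycles_total = 30, cycles_transient = 15, seed = 5,
                      dt_out = 0.25)
    sched <- light_schedule(width = 12)
    run <- function(cfg) {
      net <- build_network(cfg)
      list(net = net, traj = simulate_network(net, pop, sched, sim))
    }
    list(summer = run(summer_config(N = N, seed = 5)),
         winter = run(winter_config(N = N, seed = 5)),
         pop = pop, sim = sim)
  })
}
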