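test_that("efficiency matches closed forms on canonical graphs", {
  # complete graph: all shortest paths are 1
  full <- random_graph_network(8, 1.1, seed = 1)
  expect_equal(efficiency(full), 1)
  # edgeless graph
  empty <- manual_network(data.frame(id = 1:5, x = 0, y = 0, region = "DM",
                                     rhythmic = TRUE),
                          data.frame(i = integer(0), j = integer(0),
                                     weight = numeric(0),
                                     class = character(0)))
  expect_equal(efficiency(empty), 0)
  # 3-node path: pairwise distances (1, 1, 2) -> E = (1 + 1 + 1/2) / 3 = 5/6
  expect_equal(efficiency(path_network(3)), 5 / 6)
})

test_that("clustering matches closed forms on canonical graphs", {
  triangle <- manual_network(
    data.frame(id = 1:3, x = 0, y = 0, region = "DM", rhythmic = TRUE),
    data.frame(i = c(1, 1, 2), j = c(2, 3, 3), weight = 1, class = "short"))
  expect_equal(clustering_coefficient(triangle), 1)
  star <- manual_network(
    data.frame(id = 1:5, x = 0, y = 0, region = "DM", rhythmic = TRUE),
    data.frame(i = 1, j = 2:5, weight = 1, class = "short"))
  expect_equal(clustering_coefficient(star), 0)
  # 4-cycle plus one diagonal, checked against the enumeration oracle
  sq <- manual_network(
    data.frame(id = 1:4, x = 0, y = 0, region = "DM", rhythmic = TRUE),
    data.frame(i = c(1, 2, 3, 1, 1), j = c(2, 3, 4, 4, 3), weight = 1,
               class = "short"))
  expect_equal(clustering_coefficient(sq), bf_clustering(sq))
})

test_that("efficiency and clustering agree with brute force on random graphs", {
  for (s in 1:12) {
    n <- sample(5:30, 1)
    net <- random_graph_network(n, runif(1, 0.05, 0.5), seed = 100 + s)
    expect_equal(efficiency(net), bf_efficiency(net), tolerance = 1e-12)
    expect_equal(clustering_coefficient(net), bf_clustering(net),
                 tolerance = 1e-12)
  }
})

test_that("the local-mean-field Laplacian has the defining structure", {
  pair <- path_network(2)
  expect_equal(laplacian(pair), matrix(c(1, -1, -1, 1), 2))
  net <- build_network(network_config(N = 80, delta = 0.05, seed = 3))
  L <- laplacian(net)
  conn <- net$degree > 0
  expect_equal(unname(rowSums(L)[conn]), rep(0, sum(conn)), tolerance = 1e-12)
  # regular symmetric-degree graph (a cycle): L symmetric
  cyc <- manual_network(
    data.frame(id = 1:6, x = 0, y = 0, region = "DM", rhythmic = TRUE),
    data.frame(i = c(1:5, 1), j = c(2:6, 6), weight = 1, class = "short"))
  expect_equal(laplacian(cyc), t(laplacian(cyc)))
  # for a symmetric Laplacian, singular values = |eigenvalues|
  sv <- svd(laplacian(cyc))$d
  ev <- abs(eigen(laplacian(cyc), only.values = TRUE)$values)
  expect_equal(sort(sv), sort(ev), tolerance = 1e-10)
})

test_that("near-zero singular counts detect components and prune isolates", {
  # one connected component after pruning -> only the trivial zero
  net <- path_network(6)
  sp <- near_zero_singular_count(net)
  expect_identical(sp$n_near_zero, 1L)
  expect_identical(sp$n_pruned, 0L)
  # two disjoint paths -> block structure -> two zeros
  two <- manual_network(
    data.frame(id = 1:6, x = 0, y = 0, region = "DM", rhythmic = TRUE),
    data.frame(i = c(1, 2, 4, 5), j = c(2, 3, 5, 6), weight = 1,
               class = "short"))
  expect_identical(near_zero_singular_count(two)$n_near_zero, 2L)
  # an isolated node is pruned, not counted
  iso <- manual_network(
    data.frame(id = 1:4, x = 0, y = 0, region = "DM", rhythmic = TRUE),
    data.frame(i = c(1, 2), j = c(2, 3), weight = 1, class = "short"))
  sp2 <- near_zero_singular_count(iso)
  expect_identical(sp2$n_pruned, 1L)
  expect_identical(sp2$n_near_zero, 1L)
})

test_that("winter networks lose the excess near-zero singular values", {
  count_for <- function(cfgf) {
    mean(vapply(1:8, function(s)
      near_zero_singular_count(build_network(cfgf(seed = s)))$n_near_zero,
      numeric(1)))
  }
  winter <- count_for(winter_config)
  summer <- count_for(summer_config)
  expect_gte(summer, winter)
  expect_gt(summer, 1)          # summer: communities beyond the trivial zero
  expect_lt(winter, 2)          # winter: essentially one synchronized block
})

test_that("small-world scan: E grows with delta and C*E peaks inside", {
  # small-world reasoning applies to the sparse regime; very dense wiring
  # behaves mean-field-like, so the scan stays below delta ~ 0.1
  cfg <- network_config(N = 150, seed = 2)
  grid <- c(0, 0.005, 0.02, 0.1)
  tab <- small_world_scan(cfg, grid, replicates = 8, seed = 3)
  expect_identical(tab$delta, grid)
  # paired-seed comparison: efficiency nondecreasing in delta in expectation
  expect_true(all(diff(tab$E) > -1e-6))
  expect_equal(tab$E[1], min(tab$E))
  # the small-world product has an interior maximum over the scanned range
  expect_true(which.max(tab$CE) > 1 && which.max(tab$CE) < length(grid))
  norm <- small_world_scan(cfg, grid, replicates = 3, seed = 3,
                           normalize = TRUE)
  expect_equal(range(norm$E), c(0, 1))
})
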