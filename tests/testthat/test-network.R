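test_that("cell placement fixes the VL/DM split and bands", {
  for (case in list(c(600, 200), c(1800, 600), c(3, 1))) {
    cells <- place_cells(network_config(N = case[1], seed = 1))
    expect_identical(sum(cells$region == "VL"), as.integer(case[2]))
    expect_true(all(cells$y[cells$region == "VL"] < 1 / 3))
    expect_true(all(cells$y[cells$region == "DM"] >= 1 / 3))
    expect_false(any(cells$rhythmic[cells$region == "VL"]))
  }
})

test_that("geometric graph hits the target mean degree on average", {
  # Monte-Carlo check of rho * pi * r^2 = k_mean (boundary effects tolerated)
  degs <- vapply(1:100, function(s) {
    cells <- place_cells(network_config(N = 600, seed = s))
    e <- connect_rgg(cells, k_mean = 6)
    2 * nrow(e) / sum(cells$region == "DM")
  }, numeric(1))
  expect_equal(mean(degs), 6, tolerance = 0.5)
  # no VL cell may carry short-range edges
  cells <- place_cells(network_config(N = 300, seed = 2))
  e <- connect_rgg(cells, 6)
  vl_ids <- cells$id[cells$region == "VL"]
  expect_false(any(c(e$i, e$j) %in% vl_ids))
  expect_warning(connect_rgg(cells, 0), "k_mean")
})

test_that("coincident cells connect for any positive radius", {
  cells <- data.frame(id = 1:2, x = c(0.4, 0.4), y = c(0.7, 0.7),
                      region = "DM", rhythmic = TRUE)
  e <- connect_rgg(cells, k_mean = 1e-6, f_vl = 1 / 3)
  expect_identical(nrow(e), 1L)
})

test_that("long-range wiring follows the Bernoulli pair model", {
  cells <- place_cells(network_config(N = 600, seed = 3))
  none <- add_long_range(cells, data.frame(), delta = 0, seed = 1)
  expect_identical(nrow(none), 0L)
  # delta = 1, intra_factor = 0: every VL-DM pair and nothing else
  all_inter <- add_long_range(cells, data.frame(), delta = 1,
                              intra_factor = 0, seed = 1)
  expect_identical(nrow(all_inter), 200L * 400L)
  expect_error(add_long_range(cells, data.frame(), delta = 2), "delta")
})

test_that("expected long-range counts match the binomial oracle", {
  # E[count] = delta * (n_vl*n_dm + intra * (C(n_vl,2) + C(n_dm,2))), minus
  # the (tiny) correction for skipped short-range pairs
  cfg <- network_config(N = 200, delta = 0.02, seed = 1)
  n_vl <- 67; n_dm <- 133
  counts <- vapply(1:100, function(s) {
    cells <- place_cells(network_config(N = 200, seed = s))
    nrow(add_long_range(cells, data.frame(), 0.02, 0.1, seed = s))
  }, numeric(1))
  expected <- 0.02 * (n_vl * n_dm + 0.1 * (choose(n_vl, 2) + choose(n_dm, 2)))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
  # doubling delta doubles the expectation
  counts2 <- vapply(1:100, function(s) {
    cells <- place_cells(network_config(N = 200, seed = s))
    nrow(add_long_range(cells, data.frame(), 0.04, 0.1, seed = s))
  }, numeric(1))
  expect_equal(mean(counts2) / mean(counts), 2, tolerance = 0.1)
})

test_that("build_network composes the stages reproducibly", {
  cfg <- network_config(N = 150, delta = 0.02, seed = 11)
  net <- build_network(cfg)
  expect_identical(sum(net$degree), 2L * nrow(net$edges))
  expect_true(all(net$edges$i < net$edges$j))       # no self/duplicate edges
  expect_false(any(duplicated(net$edges[, c("i", "j")])))
  expect_identical(net, build_network(cfg))         # bit-reproducible
  # delta = 0: VL cells are fully disconnected
  net0 <- build_network(network_config(N = 150, delta = 0, seed = 11))
  vl <- net0$cells$region == "VL"
  expect_true(all(net0$degree[vl] == 0))
})

test_that("edge-weight scaling changes weights but never the pattern", {
  net <- build_network(network_config(N = 150, delta = 0.05, seed = 4))
  same <- scale_edge_weights(net, "long", fraction = 0.5, factor = 1, seed = 1)
  expect_identical(same$edges, net$edges)
  off <- scale_edge_weights(net, "long", fraction = 1, factor = 0, seed = 1)
  expect_true(all(off$edges$weight[off$edges$class == "long"] == 0))
  expect_identical(off$edges[, c("i", "j", "class")],
                   net$edges[, c("i", "j", "class")])
  half <- scale_edge_weights(net, "long", fraction = 0.5, factor = 0.25,
                             seed = 1)
  wl <- half$edges$weight[half$edges$class == "long"]
  n_long <- sum(net$edges$class == "long")
  expect_identical(sum(wl == 0.25), as.integer(round(0.5 * n_long)))
  expect_error(scale_edge_weights(net, "diagonal", 1, 1), "unknown edge class")
})

test_that("GraphML and CSV round trips are lossless", {
  net <- build_network(network_config(N = 40, delta = 0.05, seed = 6))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "net.graphml")
  write_network_graphml(net, p)
  back <- read_network_graphml(p)
  expect_equal(back$cells, net$cells)
  expect_equal(back$edges, net$edges)
  expect_identical(back$degree, net$degree)
  write_network_csv(net, file.path(tmp, "net"))
  back2 <- read_network_csv(file.path(tmp, "net"))
  expect_equal(back2$cells, net$cells)
  expect_equal(back2$edges, net$edges)
})
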