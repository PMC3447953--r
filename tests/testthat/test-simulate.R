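test_that("the light schedule is an exactly periodic square wave", {
  sch <- light_schedule(width = 8, amplitude = 0.1, phase0 = 0)
  expect_identical(light_signal(1, sch), 0.1)
  expect_identical(light_signal(9, sch), 0)
  tt <- runif(200, 0, 240)
  expect_equal(light_signal(tt, sch), light_signal(tt + 24, sch))
  expect_error(light_schedule(width = 30), "width")
  p <- light_pulse(10, 4, 0.2)
  expect_equal(light_signal(c(9.9, 10, 13.9, 14), p), c(0, 0.2, 0.2, 0))
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(cycles_total = 10, cycles_transient = 10),
               "cycles_transient")
  expect_error(sim_config(rtol = 0), "tolerances")
  expect_error(sim_config(g = -1), "g must")
})

test_that("uncoupled cells keep their intrinsic periods", {
  n <- 8
  pop <- small_pop(n, seed = 21, f = 0)
  net <- suppressWarnings(          # k_mean = 0 deliberately: no edges at all
    build_network(network_config(N = n, delta = 0, k_mean = 0, seed = 1)))
  sim <- sim_config(g = 0, cycles_total = 16, cycles_transient = 6,
                    seed = 2, dt_out = 0.05)
  traj <- simulate_network(net, pop, NULL, sim)
  X <- activity(traj)
  post <- traj$times >= traj$transient_end
  for (i in seq_len(n)) {
    pk <- find_peaks(traj$times[post], X[post, i], min_gap = pop$tau[i] / 2)
    expect_equal(mean(diff(pk$time)), pop$tau[i], tolerance = 0.05)
  }
})

test_that("two identical coupled cells lock in phase from antiphase start", {
  cells <- data.frame(id = 1:2, x = c(0.4, 0.6), y = c(0.5, 0.5),
                      region = "DM", rhythmic = TRUE)
  net <- manual_network(cells, data.frame(i = 1, j = 2, weight = 1,
                                          class = "short"))
  pop <- data.frame(id = 1:2, A = 1, lam = 0.1, tau = 24, nu = 2,
                    rhythmic = TRUE)
  sim <- sim_config(g = 0.1, cycles_total = 40, cycles_transient = 10,
                    dt_out = 0.05, seed = 1)
  # near-antiphase start (exact antiphase is a symmetry-invariant manifold)
  traj <- simulate_network(net, pop, NULL, sim,
                           init_state = list(x = c(1, -0.85), y = c(0, 0.1)))
  X <- activity(traj)
  post <- traj$times >= max(traj$times) - 5 * 24
  pk1 <- find_peaks(traj$times[post], X[post, 1], min_gap = 12)
  pk2 <- find_peaks(traj$times[post], X[post, 2], min_gap = 12)
  n <- min(nrow(pk1), nrow(pk2))
  dphi <- abs(pk1$time[seq_len(n)] - pk2$time[seq_len(n)])
  expect_lt(min(dphi %% 24, 24 - dphi %% 24), 0.1)
})

test_that("coupling term equals g times the plain neighbour mean (3-cell path)", {
  net <- path_network(3)
  pop <- data.frame(id = 1:3, A = 1, lam = 0.05, tau = 24, nu = 0,
                    rhythmic = TRUE)
  g <- 0.3
  st <- list(x = c(0.5, -0.2, 1.1), y = c(0.1, 0.9, -0.4))
  # derivative through the network engine at t = 0: the first forward-Euler
  # step divided by the step size is exactly the initial derivative
  sim <- sim_config(g = g, cycles_total = 1, cycles_transient = 0,
                    dt_out = 1e-3, seed = 1, method = "euler")
  traj <- simulate_network(net, pop, NULL, sim, init_state = st)
  dx_num <- (activity(traj)[2, ] - activity(traj)[1, ]) / 1e-3
  # oracle: single-cell derivative + g * mean of neighbours' x
  own <- vapply(1:3, function(i) {
    poincare_derivatives(c(st$x[i], st$y[i]), poincare_params(1, 0.05, 24, 0))[1]
  }, numeric(1))
  nb_mean <- c(st$x[2], mean(st$x[c(1, 3)]), st$x[2])
  expect_equal(unname(dx_num), own + g * nb_mean, tolerance = 1e-6)
})

test_that("halving integrator tolerances leaves mean-field peaks unchanged", {
  run <- seasonal_runs()
  net <- run$winter$net
  sim1 <- sim_config(cycles_total = 20, cycles_transient = 10, seed = 5,
                     dt_out = 0.25)
  sim2 <- sim1; sim2$rtol <- sim1$rtol / 2; sim2$atol <- sim1$atol / 2
  sch <- light_schedule(width = 12)
  mf1 <- mean_field(simulate_network(net, run$pop, sch, sim1))
  mf2 <- mean_field(simulate_network(net, run$pop, sch, sim2))
  pk1 <- find_peaks(mf1$times, mf1$value, min_gap = 12)
  pk2 <- find_peaks(mf2$times, mf2$value, min_gap = 12)
  n <- min(nrow(pk1), nrow(pk2))
  expect_lt(max(abs(pk1$value[1:n] - pk2$value[1:n])), 1e-3)
})

test_that("post-transient statistics settle after just a few cycles", {
  run <- seasonal_runs()
  traj <- run$winter$traj
  sh_16 <- activity_width_height(mean_field(traj, c(16 * 24, max(traj$times))))
  sh_21 <- activity_width_height(mean_field(traj, c(21 * 24, max(traj$times))))
  expect_lt(abs(sh_16$w - sh_21$w) / sh_21$w, 0.02)
  expect_lt(abs(sh_16$h - sh_21$h) / sh_21$h, 0.02)
})

test_that("entrainment classification works and ignores the output stride", {
  # synthetic perfectly periodic mean field
  tt <- seq(0, 30 * 24, by = 0.1)
  synth <- list(times = tt, value = 1 + cos(2 * pi * tt / 24))
  expect_true(is_entrained(synth, 24))
  # free-running-like series with a different period is not entrained
  off <- list(times = tt, value = 1 + cos(2 * pi * tt / 25.4))
  expect_false(is_entrained(off, 24))
  expect_error(is_entrained(list(times = tt[tt < 100], value = tt[tt < 100]),
                            24), "at least")
  # real trajectory: stride-25 subsample gives the same classification
  run <- seasonal_runs()
  traj <- run$winter$traj
  full <- is_entrained(traj, 24)
  mf <- mean_field(traj)
  sub <- list(times = mf$times[seq(1, length(mf$times), 25)],
              value = mf$value[seq(1, length(mf$times), 25)])
  expect_identical(as.logical(is_entrained(sub, 24)), as.logical(full))
})

test_that("a single strongly forced oscillator locks to the schedule", {
  cells <- data.frame(id = 1, x = 0.5, y = 0.1, region = "VL",
                      rhythmic = TRUE)
  net <- manual_network(cells, data.frame(i = integer(0), j = integer(0),
                                          weight = numeric(0),
                                          class = character(0)))
  pop <- data.frame(id = 1, A = 1, lam = 0.1, tau = 25, nu = 2,
                    rhythmic = TRUE)
  sim <- sim_config(g = 0, cycles_total = 30, cycles_transient = 12,
                    dt_out = 0.1, seed = 3)
  traj <- simulate_network(net, pop, light_schedule(width = 12,
                                                    amplitude = 0.3), sim)
  expect_true(is_entrained(traj, 24))
})

test_that("free-running damped cell decays; uncoupled free run rejected inputs", {
  cells <- data.frame(id = 1, x = 0.5, y = 0.1, region = "VL",
                      rhythmic = FALSE)
  net <- manual_network(cells, data.frame(i = integer(0), j = integer(0),
                                          weight = numeric(0),
                                          class = character(0)))
  pop <- data.frame(id = 1, A = 0, lam = 0.5, tau = 24, nu = 2,
                    rhythmic = FALSE)
  sim <- sim_config(g = 0, cycles_total = 25, cycles_transient = 2,
                    dt_out = 0.1, seed = 3)
  traj <- free_run(net, pop, sim)
  x <- activity(traj)[, 1]
  # amplitude decays monotonically across cycles
  env <- vapply(split(x, floor(traj$times / 24)), function(v)
    diff(range(v)), numeric(1))
  expect_true(all(diff(env) < 1e-8))
})

test_that("nonrhythmic VL cells oscillate through coupling in darkness", {
  run <- seasonal_runs()
  net <- run$winter$net
  fr <- free_run(net, run$pop, run$sim, from = run$winter$traj)
  X <- activity(fr)[fr$times >= max(fr$times) - 5 * 24, , drop = FALSE]
  amp <- apply(X, 2, function(v) diff(range(v)))
  vl <- net$cells$region == "VL" & net$degree > 0
  dm <- net$cells$region == "DM"
  expect_gt(mean(amp[vl]), 0.1 * mean(amp[dm]))
})

test_that("the entrained phase distribution persists under free run", {
  run <- seasonal_runs()
  fr_sim <- run$sim
  fr_sim$cycles_total <- 10
  fr_sim$cycles_transient <- 0
  spread_ent <- peak_phase_distribution(run$winter$traj,
                                        reference = "meanfield_max")$spread_h
  fr <- free_run(run$winter$net, run$pop, fr_sim, from = run$winter$traj)
  spread_fr <- peak_phase_distribution(fr,
                                       reference = "meanfield_max")$spread_h
  expect_lt(abs(spread_fr - spread_ent) / spread_ent, 0.25)
})

test_that("topology switches re-stabilize quickly and broaden the mean field", {
  run <- seasonal_runs()
  # switching to an identical network: no transient at all
  same <- topology_switch_experiment(run$winter$net, run$winter$net, run$pop,
                                     sim_config(cycles_total = 24,
                                                cycles_transient = 10,
                                                seed = 5, dt_out = 0.25),
                                     switch_cycle = 18,
                                     schedule = light_schedule(width = 12))
  expect_identical(same$reentrain_cycles, 0L)
  swt <- topology_switch_experiment(run$winter$net, run$summer$net, run$pop,
                                    sim_config(cycles_total = 30,
                                               cycles_transient = 10,
                                               seed = 5, dt_out = 0.25),
                                    switch_cycle = 18,
                                    schedule = light_schedule(width = 12))
  # the mean field broadens after winter -> summer and settles within 10 cycles
  expect_gt(mean(utils::tail(swt$w_per_cycle, 4)), swt$w_reference)
  expect_lte(swt$reentrain_cycles, 10)
  expect_error(
    topology_switch_experiment(run$winter$net,
                               build_network(summer_config(N = 120, seed = 99)),
                               run$pop, switch_cycle = 18),
    "cell table")
})
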