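#' Simulation settings
#'
#' @param g coupling strength (1/h). The default reproduces the reported
#'   coupled regime of the network model: it is strong enough to synchronize
#'   the heterogeneous population and produces an approximately ten-fold
#'   expansion of single-cell activity amplitudes (see the methods vignette
#'   for the calibration).
#' @param cycles_total number of forcing cycles to integrate (default 40).
#' @param cycles_transient initial cycles flagged as transient and excluded
#'   from analyses (default 15).
#' @param dt_out output sampling step (h).
#' @param rtol,atol integrator tolerances.
#' @param ic_mean,ic_sd Poincare initial conditions: `x` and `y` drawn from
#'   Normal(`ic_mean[1]`, `ic_sd`) and Normal(`ic_mean[2]`, `ic_sd`).
#' @param seed integer seed for the initial-condition stream.
#' @param coupling_xy logical; couple through both Cartesian coordinates
#'   (default) or through `x` only (sensitivity switch).
#' @param method deSolve integration method.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(g = 0.2, cycles_total = 40, cycles_transient = 15,
                       dt_out = 0.1, rtol = 1e-6, atol = 1e-6,
                       ic_mean = c(1, 0), ic_sd = 0.2, seed = 1,
                       coupling_xy = TRUE, method = "lsoda") {
  assert_scalar(g, "g", lower = 0)
  assert_scalar(cycles_total, "cycles_total", lower = 1)
  assert_scalar(cycles_transient, "cycles_transient", lower = 0)
  if (cycles_transient >= cycles_total)
    stop_scn("cycles_transient (%s) must be < cycles_total (%s)",
             cycles_transient, cycles_total)
  assert_scalar(dt_out, "dt_out")
  if (dt_out <= 0) stop_scn("dt_out must be > 0")
  if (rtol <= 0 || atol <= 0) stop_scn("integrator tolerances must be > 0")
  assert_finite(ic_mean, "ic_mean")
  assert_scalar(ic_sd, "ic_sd", lower = 0)
  structure(list(g = g, cycles_total = cycles_total,
                 cycles_transient = cycles_transient, dt_out = dt_out,
                 rtol = rtol, atol = atol, ic_mean = ic_mean, ic_sd = ic_sd,
                 seed = as.integer(seed), coupling_xy = isTRUE(coupling_xy),
                 method = method),
            class = "sim_config")
}

# Infer the single-cell backend from the population columns.
infer_model <- function(params) {
  if (all(c("A", "lam", "tau") %in% names(params))) "poincare"
  else if (all(c("n", "v2", "s") %in% names(params))) "goodwin"
  else stop_scn("cannot infer model backend from parameter columns")
}

# Draw initial conditions for a population.
draw_initial_state <- function(model, N, sim) {
  with_rng(scn_subseed(sim$seed, "initial_conditions"), {
    if (model == "poincare") {
      list(x = stats::rnorm(N, sim$ic_mean[1], sim$ic_sd),
           y = stats::rnorm(N, sim$ic_mean[2], sim$ic_sd))
    } else {
      # positive starting concentrations scattered around typical orbit values
      list(u = abs(stats::rnorm(N, 0.5, 0.2)),
           p = abs(stats::rnorm(N, 0.5, 0.2)),
           z = abs(stats::rnorm(N, 1.5, 0.4)),
           V = abs(stats::rnorm(N, 0.5, 0.2)))
    }
  })
}

#' Integrate the coupled SCN network
#'
#' Integrates all cells of the network under local mean-field coupling and
#' optional photic forcing. For the Poincare backend, cell `i` receives
#' coupling terms `(g / k_i) * sum_j W_ij x_j` and `(g / k_i) * sum_j W_ij y_j`
#' added to `dx_i/dt` and `dy_i/dt` (cells with degree 0 receive no coupling),
#' and light is added to `dx_i/dt` for ventrolateral cells only. For the
#' Goodwin backend the neighbour neurotransmitter mean field
#' `F_i = (1 / k_i) * sum_j W_ij V_j` feeds the saturating transcription term
#' and light is added to `du_i/dt` of ventrolateral cells.
#'
#' @param network an [build_network()] result.
#' @param params population data.frame from [sample_poincare_population()] or
#'   [sample_goodwin_population()]; one row per cell.
#' @param schedule a [light_schedule()], [light_pulse()] or `NULL` (constant
#'   darkness).
#' @param sim a [sim_config()].
#' @param model `"poincare"` or `"goodwin"`; inferred from `params` when
#'   missing.
#' @param init_state optional named list of per-cell state vectors (as stored
#'   in a trajectory's `coords`) overriding the random initial conditions;
#'   used to continue from the end state of a previous run.
#' @param t0 start time (h); outputs are reported on `t0 + [0, horizon]`.
#' @return An object of class `scn_trajectory`: `times`, `coords` (list of
#'   time-by-cell matrices), `model`, `cycle_length`, `transient_end` (time;
#'   the transient window is flagged, not dropped), `schedule`, `sim`, and the
#'   generating `network`.
#' @export
simulate_network <- function(network, params, schedule = NULL,
                             sim = sim_config(), model = NULL,
                             init_state = NULL, t0 = 0) {
  stopifnot(inherits(network, "scn_network"))
  model <- model %||% infer_model(params)
  N <- network$N
  if (nrow(params) != N)
    stop_scn("params has %d rows but the network has %d cells",
             nrow(params), N)
  deg <- network$degree
  kinv <- ifelse(deg > 0, 1 / deg, 0)          # degree-0 cells: no coupling
  W <- adjacency_matrix(network, weighted = TRUE)
  vl <- as.numeric(network$cells$region == "VL")
  cycle <- if (inherits(schedule, "light_schedule")) schedule$period else 24
  times <- seq(0, sim$cycles_total * cycle, by = sim$dt_out)
  lf <- function(t) light_signal(t, schedule)

  if (model == "poincare") {
    A <- params$A; lam <- params$lam; nu <- params$nu
    om0 <- poincare_omega0(params$tau, nu)
    g <- sim$g
    cxy <- sim$coupling_xy
    rhs <- function(t, y, parms) {
      x <- y[1:N]; yy <- y[(N + 1):(2 * N)]
      r <- sqrt(x^2 + yy^2)
      cosphi <- ifelse(r > 0, x / r, 1)
      v <- om0 * (1 + nu * (1 + cosphi) / 2)^2
      radial <- lam * (A - r)
      cx <- g * kinv * as.numeric(W %*% x)
      cy <- if (cxy) g * kinv * as.numeric(W %*% yy) else 0
      L <- lf(t + t0) * vl
      list(c(radial * x - yy * v + cx + L,
             radial * yy + x * v + cy))
    }
    st <- init_state %||% draw_initial_state("poincare", N, sim)
    y0 <- c(st$x, st$y)
    coord_names <- c("x", "y")
  } else {
    base <- goodwin_params()               # shared Gonze-type constants
    pv <- list(v1 = base$v1, K1 = base$K1, n = params$n, v2 = params$v2,
               K2 = base$K2, k3 = base$k3, v4 = base$v4, K4 = base$K4,
               k5 = base$k5, v6 = base$v6, K6 = base$K6, k7 = base$k7,
               v8 = base$v8, K8 = base$K8, vc = base$vc, Kc = base$Kc,
               s = params$s)
    rhs <- function(t, y, parms) {
      u <- y[1:N]; p <- y[(N + 1):(2 * N)]
      z <- y[(2 * N + 1):(3 * N)]; V <- y[(3 * N + 1):(4 * N)]
      F <- kinv * as.numeric(W %*% V)
      d <- goodwin_deriv_vec(u, p, z, V, pv, F = F, light = lf(t + t0) * vl)
      list(c(d$du, d$dp, d$dz, d$dV))
    }
    st <- init_state %||% draw_initial_state("goodwin", N, sim)
    y0 <- c(st$u, st$p, st$z, st$V)
    coord_names <- c("u", "p", "z", "V")
  }

  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = sim$method,
                      rtol = sim$rtol, atol = sim$atol)
  if (attr(sol, "istate")[1] < 0)
    stop_scn("network integration failed near t = %.2f h",
             max(sol[, 1], na.rm = TRUE))
  coords <- stats::setNames(
    lapply(seq_along(coord_names), function(k) {
      m <- sol[, (1 + (k - 1) * N + 1):(1 + k * N), drop = FALSE]
      dimnames(m) <- NULL
      m
    }), coord_names)
  structure(list(times = t0 + times, coords = coords, model = model,
                 cycle_length = cycle,
                 transient_end = t0 + sim$cycles_transient * cycle,
                 schedule = schedule, sim = sim, params = params,
                 network = network),
            class = "scn_trajectory")
}

#' @export
print.scn_trajectory <- function(x, ...) {
  cat(sprintf(
    "<scn_trajectory> %s backend, %d cells, t = %.1f..%.1f h (transient to %.1f h)\n",
    x$model, ncol(x$coords[[1]]), min(x$times), max(x$times), x$transient_end))
  invisible(x)
}

#' Activity coordinate of a trajectory
#'
#' The model's continuous stand-in for electrical activity: the `x` coordinate
#' for the Poincare backend, the clock-gene mRNA `u` for the Goodwin backend.
#'
#' @param traj an `scn_trajectory`.
#' @return Numeric time-by-cell matrix.
#' @export
activity <- function(traj) {
  traj$coords[[if (traj$model == "poincare") "x" else "u"]]
}

# Final state of a trajectory as an init_state list.
end_state <- function(traj) {
  lapply(traj$coords, function(m) m[nrow(m), ])
}

#' Free-running (constant darkness) simulation
#'
#' Runs [simulate_network()] without photic forcing, optionally continuing
#' from the end state of a previous (typically entrained) trajectory so that
#' the persistence of the entrained phase distribution can be assessed.
#'
#' @param network,params,sim as in [simulate_network()].
#' @param from optional `scn_trajectory` whose final state seeds this run.
#' @param model backend override.
#' @return An `scn_trajectory`.
#' @export
free_run <- function(network, params, sim = sim_config(), from = NULL,
                     model = NULL) {
  init <- NULL
  t0 <- 0
  if (!is.null(from)) {
    stopifnot(inherits(from, "scn_trajectory"))
    init <- end_state(from)
    t0 <- max(from$times)
  }
  simulate_network(network, params, schedule = NULL, sim = sim,
                   model = model, init_state = init, t0 = t0)
}
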