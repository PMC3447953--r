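#' Test whether a trajectory is entrained to an external period
#'
#' The criterion is stated explicitly so entrainment maps are auditable: the
#' trajectory is entrained to `T_ext` iff, over the last `n_cycles`
#' post-transient cycles, (i) the mean inter-peak interval of the mean field
#' equals `T_ext` within `tol_period`, and (ii) the peak phase relative to
#' lights-on shows no secular drift: the slope of a linear fit of peak time
#' minus `cycle * T_ext` against cycle index stays below `tol_drift`.
#'
#' @param traj an `scn_trajectory`, or a list with `times` and `value`
#'   (a precomputed mean-field-like series).
#' @param T_ext external period (h).
#' @param tol_period tolerance on the mean inter-peak interval (h).
#' @param tol_drift tolerance on the secular drift (h per cycle).
#' @param n_cycles number of final cycles examined (>= 10 must be available).
#' @return Logical flag with attributes `period` (measured) and `drift`
#'   (h/cycle).
#' @export
is_entrained <- function(traj, T_ext, tol_period = 0.1, tol_drift = 0.05,
                         n_cycles = 10) {
  if (inherits(traj, "scn_trajectory")) {
    mf <- mean_field(traj)
    tt <- mf$times; xx <- mf$value
  } else {
    tt <- traj$times; xx <- traj$value
  }
  if (diff(range(tt)) < n_cycles * T_ext)
    stop_scn("trajectory must cover at least %d cycles of %g h after the transient",
             n_cycles, T_ext)
  pk <- find_peaks(tt, xx, min_gap = T_ext / 2)
  if (nrow(pk) < n_cycles + 1)
    return(structure(FALSE, period = NA_real_, drift = NA_real_))
  pk <- utils::tail(pk, n_cycles + 1)
  period <- mean(diff(pk$time))
  cyc <- seq_len(nrow(pk))
  resid <- pk$time - cyc * T_ext
  drift <- unname(stats::coef(stats::lm(resid ~ cyc))[2])
  structure(abs(period - T_ext) <= tol_period && abs(drift) <= tol_drift,
            period = period, drift = drift)
}

#' Arnold-tongue scan: entrainment region of the network
#'
#' For every combination of external period `T_ext` and forcing amplitude `b`,
#' the network is simulated under a square-wave schedule with photoperiod
#' `T_ext / 2` and classified with [is_entrained()]. One network realization
#' is used per condition; the seed is recorded in the result.
#'
#' @param network an `scn_network`.
#' @param params cell population data.frame.
#' @param T_grid,b_grid numeric grids of periods (h) and amplitudes.
#' @param sim a [sim_config()].
#' @param tol_period,tol_drift entrainment tolerances, see [is_entrained()].
#' @return An object of class `entrainment_map`: data.frame with columns
#'   `T_ext`, `b`, `entrained`, `period`, `drift`; attribute `seed`.
#' @export
entrainment_region <- function(network, params, T_grid, b_grid,
                               sim = sim_config(), tol_period = 0.1,
                               tol_drift = 0.05) {
  if (!all(is.finite(T_grid)) || !all(is.finite(b_grid)))
    stop_scn("grids must be finite")
  grid <- expand.grid(T_ext = T_grid, b = b_grid)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    T_ext <- grid$T_ext[k]; b <- grid$b[k]
    sched <- light_schedule(period = T_ext, width = T_ext / 2, amplitude = b)
    traj <- simulate_network(network, params, sched, sim)
    ent <- is_entrained(traj, T_ext, tol_period, tol_drift)
    data.frame(T_ext = T_ext, b = b, entrained = as.logical(ent),
               period = attr(ent, "period") %||% NA_real_,
               drift = attr(ent, "drift") %||% NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- sim$seed
  class(out) <- c("entrainment_map", class(out))
  out
}

#' Abrupt winter-to-summer topology switch
#'
#' Integrates the network with the winter adjacency up to `switch_cycle`
#' cycles, then continues from the same state with the summer adjacency, and
#' reports how many cycles the mean-field width `w` needs to re-stabilize
#' (relative change below `tol` per cycle). Both networks must share the
#' same cell table.
#'
#' @param net_winter,net_summer `scn_network`s over identical cells.
#' @param params cell population data.frame.
#' @param sim a [sim_config()]; `cycles_total` covers both phases.
#' @param switch_cycle cycle index at which the adjacency is swapped.
#' @param schedule photic forcing (applied throughout).
#' @param tol relative per-cycle change of `w` below which the mean field
#'   counts as re-stabilized.
#' @return List with `trajectory` (post-switch), `pre` (pre-switch
#'   trajectory), `w_per_cycle` (post-switch), and `reentrain_cycles`.
#' @export
topology_switch_experiment <- function(net_winter, net_summer, params,
                                       sim = sim_config(),
                                       switch_cycle = 20,
                                       schedule = light_schedule(width = 12),
                                       tol = 0.05) {
  if (!isTRUE(all.equal(net_winter$cells, net_summer$cells)))
    stop_scn("both networks must share the same cell table")
  if (switch_cycle >= sim$cycles_total)
    stop_scn("switch_cycle must be < cycles_total")
  sim1 <- sim
  sim1$cycles_total <- switch_cycle
  sim1$cycles_transient <- min(sim$cycles_transient, switch_cycle - 1)
  pre <- simulate_network(net_winter, params, schedule, sim1)
  sim2 <- sim
  sim2$cycles_total <- sim$cycles_total - switch_cycle
  sim2$cycles_transient <- 0
  post <- simulate_network(net_summer, params, schedule, sim2,
                           init_state = end_state(pre), t0 = max(pre$times))
  # per-cycle mean-field width after the switch (including cycle 0 = last
  # pre-switch cycle as the reference)
  cyc <- post$cycle_length
  w_ref <- activity_width_height(
    mean_field(pre, window = c(max(pre$times) - 3 * cyc, max(pre$times))))$w
  mfp <- mean_field(post, window = range(post$times))
  n_post <- floor(diff(range(mfp$times)) / cyc)
  w_cycles <- vapply(seq_len(n_post), function(k) {
    win <- max(pre$times) + c(k - 1, k) * cyc
    x <- mfp$value[mfp$times >= win[1] & mfp$times <= win[2]]
    h <- max(x) - min(x)
    sum(x > min(x) + h / 2) * stats::median(diff(mfp$times))
  }, numeric(1))
  w_seq <- c(w_ref, w_cycles)
  rel <- abs(diff(w_seq)) / pmax(w_seq[-length(w_seq)], 1e-12)
  stable <- which(rel < tol)
  reentrain <- if (length(stable)) stable[1] - 1L else NA_integer_
  list(trajectory = post, pre = pre, w_per_cycle = w_cycles,
       w_reference = w_ref, reentrain_cycles = reentrain)
}
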