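# Phase response curves: finite light pulses on the network, and adjoint
# infinitesimal PRCs of single cells.

#' Phase response curve of the SCN network to a finite light pulse
#'
#' Protocol: the network is first entrained to a 24 h schedule, which anchors
#' circadian time (CT0 = clock time of the mean-field maximum under
#' entrainment). From the entrained end state, a free-running control and,
#' per circadian time on the grid, a pulsed run (one square pulse of
#' `pulse_duration` hours and amplitude `pulse_amplitude` applied to all
#' ventrolateral cells) are integrated from the identical state, so the pulse
#' effect is isolated by common random numbers. The asymptotic shift of the
#' mean-field maximum versus the control is reported in hours in `(-12, 12]`,
#' phase advances positive.
#'
#' @param network an `scn_network`.
#' @param params cell population data.frame.
#' @param sim a [sim_config()] used for the entrainment stage.
#' @param ct_grid circadian times of pulse onset, in `[0, 24)`.
#' @param pulse_duration pulse length (h, default 4).
#' @param pulse_amplitude pulse strength (model units).
#' @param entrain_schedule the anchoring schedule (24 h period).
#' @param free_cycles length of the free-running control/pulse runs (cycles).
#' @return An object of class `scn_prc`: data.frame with columns `ct` and
#'   `dphi` (h), plus attributes `pulse_duration`, `pulse_amplitude`, `ct0`.
#' @export
measure_prc <- function(network, params, sim = sim_config(),
                        ct_grid = seq(0, 22, by = 2), pulse_duration = 4,
                        pulse_amplitude = 0.6,
                        entrain_schedule = light_schedule(width = 12,
                                                          amplitude = 0.6),
                        free_cycles = 15) {
  stopifnot(inherits(entrain_schedule, "light_schedule"))
  ent <- simulate_network(network, params, entrain_schedule, sim)
  mf_ent <- mean_field(ent)
  pk <- find_peaks(mf_ent$times, mf_ent$value, min_gap = 12)
  if (nrow(pk) < 3) stop_scn("entrained mean field has no stable rhythm")
  ct0 <- circular_median(pk$time %% 24, 24)  # clock time of CT0 (mf maximum)
  s0 <- end_state(ent)
  t_end <- max(ent$times)

  sim_free <- sim
  sim_free$cycles_total <- free_cycles
  sim_free$cycles_transient <- min(sim$cycles_transient, free_cycles - 10)
  run_free <- function(forcing) {
    simulate_network(network, params, forcing, sim_free,
                     init_state = s0, t0 = t_end)
  }
  control <- run_free(NULL)
  mf_c <- mean_field(control, window = range(control$times))
  pk_c <- find_peaks(mf_c$times, mf_c$value, min_gap = 12)
  if (nrow(pk_c) < 5) stop_scn("free-running reference rhythm is unstable")

  shift_of <- function(ct) {
    # pulse onset in the second free-running cycle at the requested CT
    base <- t_end + 24
    onset <- base + ((ct - ((base - ct0) %% 24)) %% 24)
    pulsed <- run_free(light_pulse(onset, pulse_duration, pulse_amplitude))
    mf_p <- mean_field(pulsed, window = range(pulsed$times))
    pk_p <- find_peaks(mf_p$times, mf_p$value, min_gap = 12)
    n <- min(nrow(pk_c), nrow(pk_p))
    if (n < 3) return(NA_real_)
    # asymptotic shift: control minus pulsed peak times (advance > 0),
    # averaged over the last peaks, wrapped to (-12, 12]
    d <- utils::tail(pk_c$time, 3) - utils::tail(pk_p$time[seq_len(n)], 3)
    d <- mean(((d + 12) %% 24) - 12)
    -(((-d + 12) %% 24) - 12)   # map +/-12 boundary to +12
  }
  dphi <- vapply(ct_grid, shift_of, numeric(1))
  structure(data.frame(ct = ct_grid, dphi = dphi),
            class = c("scn_prc", "data.frame"),
            pulse_duration = pulse_duration,
            pulse_amplitude = pulse_amplitude, ct0 = ct0)
}

# --- adjoint iPRC ----------------------------------------------------------

# Single-cell RHS factory returning f(y) and the model dimension.
single_cell_rhs <- function(params) {
  if (inherits(params, "poincare_params")) {
    list(f = function(y) {
      d <- poincare_deriv_vec(y[1], y[2], params$A, params$lam,
                              params$tau, params$nu)
      c(d$dx, d$dy)
    }, dim = 2L, act = 1L)
  } else if (inherits(params, "goodwin_params")) {
    list(f = function(y) {
      d <- goodwin_deriv_vec(y[1], y[2], y[3], y[4], params)
      c(d$du, d$dp, d$dz, d$dV)
    }, dim = 4L, act = 1L)
  } else stop_scn("params must be poincare_params or goodwin_params")
}

# Numerical Jacobian of f at y (central differences).
num_jacobian <- function(f, y, h = 1e-6) {
  m <- length(y)
  J <- matrix(0, m, m)
  for (j in seq_len(m)) {
    hp <- h * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + hp
    ym <- y; ym[j] <- ym[j] - hp
    J[, j] <- (f(yp) - f(ym)) / (2 * hp)
  }
  J
}

#' Infinitesimal phase response curve by the adjoint method
#'
#' Finds the stable limit cycle of a single uncoupled cell, then solves the
#' adjoint variational system `dz/dt = -J(t)' z` backward in time around the
#' cycle until periodic convergence, with the standard normalization
#' `z(t) . f(x0(t)) = 1` (phase measured in time units, so `z` has units of
#' hours of phase shift per unit state perturbation per hour of pulse). The
#' returned curve samples the sensitivity of the phase to perturbations of
#' each state coordinate over one period, on a circadian-time grid anchored
#' at the activity maximum (CT of the peak = 0).
#'
#' @param params a [poincare_params()] or [goodwin_params()] object with a
#'   self-sustained rhythm.
#' @param n_samples samples per period.
#' @param n_periods_adjoint backward integration length (periods) used to
#'   converge onto the periodic adjoint solution.
#' @param settle_cycles forward integration length used to relax onto the
#'   limit cycle before sampling it.
#' @return An object of class `scn_iprc`: data.frame with columns `ct`,
#'   `time`, one sensitivity column per state coordinate (`z_x`, `z_y` or
#'   `z_u`, ...), and attribute `period`.
#' @export
compute_iprc <- function(params, n_samples = 480, n_periods_adjoint = 10,
                         settle_cycles = 30) {
  sc <- single_cell_rhs(params)
  if (inherits(params, "poincare_params") && params$A <= 0)
    stop_scn("cell is damped (A = 0): no stable limit cycle")
  rhs <- function(t, y, p) list(sc$f(y))
  y0 <- if (sc$dim == 2L) c(params$A, 0) else c(0.1, 0.1, 2, 0.1)
  relax <- deSolve::lsoda(y0, seq(0, settle_cycles * 24, by = 0.05),
                          rhs, NULL, rtol = 1e-10, atol = 1e-10)
  xact <- relax[, sc$act + 1L]
  tt <- relax[, 1L]
  post <- tt >= 0.5 * max(tt)
  pk <- find_peaks(tt[post], xact[post], min_gap = 6)
  if (nrow(pk) < 3) stop_scn("no stable limit cycle found")
  period <- mean(diff(pk$time))
  # one period of the cycle starting at an activity peak
  t_anchor <- pk$time[nrow(pk) - 1L]
  tgrid <- seq(0, period, length.out = n_samples + 1L)
  y_anchor <- relax[which.min(abs(tt - t_anchor)), -1L]
  cyc <- deSolve::lsoda(y_anchor, tgrid, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  if (max(abs(cyc[nrow(cyc), -1L] - cyc[1L, -1L])) > 1e-3)
    warning("limit cycle not closed to 1e-3; monodromy may be inaccurate")
  states <- cyc[, -1L, drop = FALSE]
  # periodic interpolants of the cycle states
  interp <- lapply(seq_len(sc$dim), function(k) {
    v <- states[, k]; v[length(v)] <- v[1L]
    stats::splinefun(tgrid, v, method = "periodic")
  })
  state_at <- function(t) {
    tm <- t %% period
    vapply(interp, function(fn) fn(tm), numeric(1))
  }
  # adjoint system backward in time: w(s) = z(T_tot - s)
  T_tot <- n_periods_adjoint * period
  adj <- function(s, w, p) {
    J <- num_jacobian(sc$f, state_at(T_tot - s))
    list(as.numeric(t(J) %*% w))
  }
  w0 <- sc$f(state_at(0))               # seed with a generic vector
  w0 <- w0 / sum(w0 * w0)
  sol <- deSolve::lsoda(w0, seq(0, T_tot, by = period / n_samples),
                        adj, NULL, rtol = 1e-10, atol = 1e-12)
  # last full period of the backward run, mapped to forward time
  ns <- n_samples
  last <- sol[(nrow(sol) - ns):nrow(sol), -1L, drop = FALSE]
  z <- last[rev(seq_len(ns + 1L)), , drop = FALSE]  # z(t) on tgrid
  # pointwise renormalization z . f = 1
  for (i in seq_len(nrow(z))) {
    fi <- sc$f(states[i, ])
    z[i, ] <- z[i, ] / sum(z[i, ] * fi)
  }
  coord <- if (sc$dim == 2L) c("x", "y") else c("u", "p", "z", "V")
  out <- data.frame(ct = tgrid / period * 24, time = tgrid)
  for (k in seq_len(sc$dim)) out[[paste0("z_", coord[k])]] <- z[, k]
  structure(out, class = c("scn_iprc", "data.frame"), period = period)
}

#' Predict the phase shift of a short weak pulse from an iPRC
#'
#' Linear prediction `dphi = amplitude * integral of z_x over the pulse
#' window`, used to cross-check the adjoint curve against direct simulation.
#'
#' @param iprc an [compute_iprc()] result.
#' @param ct circadian time of pulse onset.
#' @param duration pulse length (h).
#' @param amplitude pulse strength.
#' @param coord perturbed coordinate (default the activity coordinate).
#' @return Predicted shift in hours (advance > 0).
#' @export
iprc_predict_shift <- function(iprc, ct, duration, amplitude,
                               coord = NULL) {
  period <- attr(iprc, "period")
  coord <- coord %||% grep("^z_", names(iprc), value = TRUE)[1]
  zfun <- stats::splinefun(iprc$time,
                           {v <- iprc[[coord]]; v[length(v)] <- v[1]; v},
                           method = "periodic")
  t0 <- ct / 24 * period
  stats::integrate(function(s) amplitude * zfun((t0 + s) %% period),
                   0, duration, subdivisions = 400L)$value
}
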