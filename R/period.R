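#' Measure the inherent period of a single uncoupled cell
#'
#' Integrates one cell in constant darkness without coupling, discards an
#' initial transient, and returns the mean inter-peak interval of the activity
#' coordinate (`x` for the Poincare backend, clock-gene mRNA `u` for the
#' Goodwin backend). If the oscillation amplitude decays below
#' `amplitude_floor` times its initial value the cell is classified as damped:
#' the function then returns `NA` with attribute `damped = TRUE`, or, when
#' `ringing = TRUE`, the inter-peak interval of the decaying (ringing)
#' oscillation, which is the relevant inherent period for damped cells.
#'
#' @param params a [poincare_params()] or [goodwin_params()] object.
#' @param model_kind `"poincare"` or `"goodwin"`; inferred from the class of
#'   `params` when missing.
#' @param cycles number of nominal 24 h cycles to integrate.
#' @param dt output sampling step (h).
#' @param amplitude_floor relative amplitude below which the cell is
#'   classified as damped.
#' @param ringing logical; report the damped ringing period instead of `NA`
#'   for damped cells.
#' @return Period in hours (possibly `NA`), with attribute `damped`.
#' @export
#' @examples
#' intrinsic_period(poincare_params(A = 1, lam = 0.1, tau = 25))
intrinsic_period <- function(params, model_kind = NULL, cycles = 12,
                             dt = 0.05, amplitude_floor = 1e-3,
                             ringing = FALSE) {
  model_kind <- model_kind %||%
    if (inherits(params, "goodwin_params")) "goodwin" else "poincare"
  if (model_kind == "poincare") {
    # self-sustained cells start exactly on the limit cycle (r = A), so the
    # measurement is free of the slow radial transient of weak oscillators
    y0 <- c(x = if (params$A > 0) params$A else 1, y = 0)
    rhs <- function(t, y, p) {
      d <- poincare_deriv_vec(y[1], y[2], params$A, params$lam,
                              params$tau, params$nu)
      list(c(d$dx, d$dy))
    }
    act <- 1L
  } else {
    y0 <- c(u = 0.1, p = 0.1, z = 2, V = 0.1)
    rhs <- function(t, y, p) {
      d <- goodwin_deriv_vec(y[1], y[2], y[3], y[4], params)
      list(c(d$du, d$dp, d$dz, d$dV))
    }
    act <- 1L
  }
  times <- seq(0, cycles * 24, by = dt)
  sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-8, atol = 1e-8)
  if (attr(sol, "istate")[1] < 0)
    stop_scn("single-cell integration failed (%s backend)", model_kind)
  x <- sol[, act + 1L]
  tt <- sol[, 1L]
  # amplitude of the last quarter versus the first quarter of the run
  q <- length(x) %/% 4
  e <- length(x) %/% 8
  amp_late <- diff(range(x[(length(x) - q):length(x)]))
  amp_early <- diff(range(x[seq_len(q)]))
  amp_8a <- diff(range(x[(length(x) - 2 * e):(length(x) - e)]))
  amp_8b <- diff(range(x[(length(x) - e):length(x)]))
  # damped: fully decayed, or still shrinking without settling (covers the
  # algebraic 1/t decay of the A = 0 Poincare cell)
  damped <- amp_late < amplitude_floor * max(amp_early, 1) ||
    (amp_late < 0.6 * amp_early && amp_8b < 0.97 * amp_8a)
  if (damped && !ringing)
    return(structure(NA_real_, damped = TRUE))
  if (damped) {
    # inherent period of a damped cell: ringing frequency of the linearization
    # at the stable equilibrium, 2*pi / Im(lambda)
    f <- function(y) {
      d <- rhs(0, y, NULL)[[1]]
      d
    }
    y_eq <- sol[nrow(sol), -1L]
    for (it in 1:20) {                    # Newton refinement to the fixed point
      fv <- f(y_eq)
      if (max(abs(fv)) < 1e-12) break
      J <- num_jacobian(f, y_eq)
      step <- tryCatch(solve(J, fv), error = function(e) NULL)
      if (is.null(step)) break
      y_eq <- y_eq - step
    }
    J <- num_jacobian(f, y_eq)
    im <- max(abs(Im(eigen(J, only.values = TRUE)$values)))
    if (im > 1e-8 && max(abs(f(y_eq))) < 1e-8)
      return(structure(2 * pi / im, damped = TRUE))
    # fallback: early decaying peaks
    pk <- find_peaks(tt, x, min_gap = 6)
    pk <- pk[pk$value - min(x) > 0.05 * amp_early, , drop = FALSE]
    if (nrow(pk) < 2L)
      stop_scn("cannot measure ringing period: fewer than two usable peaks")
    return(structure(mean(diff(pk$time)), damped = TRUE))
  }
  post <- tt >= 0.3 * max(tt)   # discard the settling transient
  pk <- find_peaks(tt[post], x[post], min_gap = 6)
  if (nrow(pk) < 3L)
    stop_scn("cannot measure period: fewer than three post-transient peaks")
  structure(mean(diff(pk$time)), damped = FALSE)
}
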