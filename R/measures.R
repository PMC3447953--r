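#' Mean-field activity of the SCN
#'
#' Arithmetic mean of the activity coordinate over all cells at each output
#' time, shifted so that its minimum over the analysis window is exactly zero
#' (the "positive quadrant" convention for population electrical activity).
#'
#' @param traj an `scn_trajectory`.
#' @param window time window `c(from, to)`; defaults to the post-transient
#'   part of the trajectory.
#' @return An object of class `scn_meanfield`: list with `times`, `value`
#'   (min 0), and `cycle_length`.
#' @export
mean_field <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "scn_trajectory"))
  window <- window %||% c(traj$transient_end, max(traj$times))
  keep <- traj$times >= window[1] & traj$times <= window[2]
  if (!any(keep)) stop_scn("empty analysis window [%g, %g]",
                           window[1], window[2])
  mf <- rowMeans(activity(traj)[keep, , drop = FALSE])
  structure(list(times = traj$times[keep], value = mf - min(mf),
                 cycle_length = traj$cycle_length),
            class = "scn_meanfield")
}

#' Width and amplitude of the mean-field activity peak
#'
#' Splits the mean-field series into consecutive cycles and computes, per
#' cycle, the amplitude `h = max - min` and the width `w`: the total time the
#' signal exceeds `min + h/2` (possibly split super-threshold intervals within
#' one cycle are summed, which keeps the measure robust for bimodal peaks).
#' Cycle means and standard deviations are reported.
#'
#' @param mf an [mean_field()] result (or any list with `times`, `value`).
#' @param cycle_length cycle length (h); defaults to the series' own.
#' @param h_floor amplitude below which a cycle's width is undefined and
#'   flagged (`NA`).
#' @return An object of class `activity_shape`: list with the cycle-averaged
#'   `w` and `h`, their SDs, and the per-cycle table.
#' @export
#' @examples
#' tt <- seq(0, 72, by = 0.01)
#' mf <- list(times = tt, value = 1 + cos(2 * pi * tt / 24), cycle_length = 24)
#' activity_width_height(mf)$w  # 12 h for a pure cosine
activity_width_height <- function(mf, cycle_length = NULL, h_floor = 1e-8) {
  cycle_length <- cycle_length %||% mf$cycle_length %||% 24
  tt <- mf$times
  xx <- mf$value
  if (diff(range(tt)) < 3 * cycle_length)
    stop_scn("need at least 3 full cycles to estimate the activity shape")
  dt <- stats::median(diff(tt))
  idx <- floor((tt - tt[1]) / cycle_length)
  per <- lapply(split(seq_along(tt), idx), function(k) {
    if (length(k) < 0.9 * cycle_length / dt) return(NULL)
    x <- xx[k]
    h <- max(x) - min(x)
    if (h < h_floor) return(data.frame(h = h, w = NA_real_))
    lvl <- min(x) + h / 2
    data.frame(h = h, w = sum(x > lvl) * dt)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || !nrow(per))
    stop_scn("no complete cycles in the analysis window")
  structure(list(w = mean(per$w), h = mean(per$h),
                 w_sd = stats::sd(per$w), h_sd = stats::sd(per$h),
                 per_cycle = per, flat = anyNA(per$w)),
            class = "activity_shape")
}

#' @export
print.activity_shape <- function(x, ...) {
  cat(sprintf("<activity_shape> w = %.2f +/- %.2f h, h = %.3g +/- %.2g (%d cycles)\n",
              x$w, x$w_sd %||% NA, x$h, x$h_sd %||% NA, nrow(x$per_cycle)))
  invisible(x)
}

#' Pairwise correlation matrix of single-cell activities
#'
#' Pearson correlation of the activity series of every cell pair, computed on
#' every `stride`-th recorded point of the post-transient window (the
#' subsampling convention used for correlation analyses of the integrated
#' series). Cells with zero variance over the window (e.g. fully silent
#' cells) are flagged and excluded from the average off-diagonal coefficient.
#'
#' @param traj an `scn_trajectory`.
#' @param stride subsampling stride in output samples (default 25).
#' @param window analysis window; defaults to post-transient.
#' @return An object of class `scn_correlation`: list with the `matrix`
#'   (`NA` rows for degenerate cells), `rho_bar` (mean over valid `i != j`
#'   pairs, signed), `stride`, and `excluded` (ids of degenerate cells).
#' @export
correlation_matrix <- function(traj, stride = 25, window = NULL) {
  stopifnot(inherits(traj, "scn_trajectory"))
  window <- window %||% c(traj$transient_end, max(traj$times))
  keep <- which(traj$times >= window[1] & traj$times <= window[2])
  if (length(keep) < 2 * stride)
    stop_scn("analysis window too short for stride %d", stride)
  rows <- keep[seq(1L, length(keep), by = stride)]
  X <- activity(traj)[rows, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  degenerate <- unname(which(sds == 0 | !is.finite(sds)))
  rho <- suppressWarnings(stats::cor(X))
  dimnames(rho) <- NULL
  rho[degenerate, ] <- NA_real_
  rho[, degenerate] <- NA_real_
  off <- rho[upper.tri(rho)]
  structure(list(matrix = rho, rho_bar = mean(off, na.rm = TRUE),
                 stride = stride, excluded = degenerate),
            class = "scn_correlation")
}

#' @export
print.scn_correlation <- function(x, ...) {
  cat(sprintf("<scn_correlation> %d cells, rho_bar = %.3f (stride %d, %d excluded)\n",
              nrow(x$matrix), x$rho_bar, x$stride, length(x$excluded)))
  invisible(x)
}

#' Distribution of single-cell activity peak phases
#'
#' For every cell, detects post-transient activity peaks (local maxima with a
#' refractory window of half a cycle and parabolic refinement) and reports the
#' median peak time modulo the cycle, relative to a reference: lights-on of
#' the schedule, or the mean-field maximum. The scalar spread is the circular
#' (angular) deviation `sqrt(2 (1 - R))` of the peak phases, reported both in
#' radians and hours; it approaches `sqrt(2)` rad for a uniform phase spread.
#'
#' @param traj an `scn_trajectory`.
#' @param reference `"lights_on"` (default if a schedule is present) or
#'   `"meanfield_max"`.
#' @param min_amplitude peak-to-trough amplitude below which a cell is deemed
#'   peakless and excluded (counted in `n_peakless`).
#' @return List with `peak_time` (per cell, h in `[0, cycle)`, `NA` for
#'   peakless cells), `spread_h`, `spread_rad`, `mean_R`, and `n_peakless`.
#' @export
peak_phase_distribution <- function(traj, reference = NULL,
                                    min_amplitude = 1e-4) {
  stopifnot(inherits(traj, "scn_trajectory"))
  reference <- reference %||%
    if (inherits(traj$schedule, "light_schedule")) "lights_on" else "meanfield_max"
  cyc <- traj$cycle_length
  keep <- traj$times >= traj$transient_end
  tt <- traj$times[keep]
  X <- activity(traj)[keep, , drop = FALSE]
  ref0 <- switch(reference,
    lights_on = if (inherits(traj$schedule, "light_schedule"))
      traj$schedule$phase0 else 0,
    meanfield_max = {
      mf <- rowMeans(X)
      pk <- find_peaks(tt, mf, min_gap = cyc / 2)
      if (!nrow(pk)) stop_scn("mean field has no detectable peaks")
      stats::median(pk$time %% cyc)
    },
    stop_scn("unknown reference '%s'", reference))
  peak_time <- apply(X, 2, function(x) {
    if (max(x) - min(x) < min_amplitude) return(NA_real_)
    pk <- find_peaks(tt, x, min_gap = cyc / 2)
    if (!nrow(pk)) return(NA_real_)
    circular_median((pk$time - ref0) %% cyc, cyc)
  })
  ok <- !is.na(peak_time)
  if (!any(ok)) stop_scn("no cell has detectable peaks")
  cs <- circular_spread(peak_time[ok], period = cyc)
  list(peak_time = peak_time, spread_h = cs$spread,
       spread_rad = cs$spread_rad, mean_R = cs$R,
       mean_peak_time = cs$mean_time, n_peakless = sum(!ok),
       reference = reference)
}
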