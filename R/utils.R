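# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_scn <- function(...) stop(sprintf(...), call. = FALSE)

assert_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_scn("%s must be finite numeric, got: %s", what,
             paste(utils::head(x, 3), collapse = ", "))
  invisible(x)
}

assert_scalar <- function(x, what, lower = -Inf, upper = Inf) {
  assert_finite(x, what)
  if (length(x) != 1L) stop_scn("%s must be a single value", what)
  if (x < lower || x > upper)
    stop_scn("%s must lie in [%s, %s], got %s", what, lower, upper, x)
  invisible(x)
}

#' Derive a reproducible sub-seed for a named random stream
#'
#' One root seed per experiment is split deterministically into independent
#' streams (parameters, geometry, long-range links, initial conditions, ...)
#' so that each stage is independently reproducible.
#'
#' @param seed integer root seed.
#' @param stream character stream label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
scn_subseed <- function(seed, stream) {
  assert_scalar(seed, "seed")
  h <- 0
  for (ch in utf8ToInt(as.character(stream)))
    h <- (h * 131 + ch) %% 2147483563
  as.integer((abs(seed) * 48271 + h) %% 2147483563)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so library code never clobbers user RNG state.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Locate local maxima of a sampled signal
#'
#' Peaks are local maxima on the sampling grid separated by at least
#' `min_gap`; when two candidates fall closer than `min_gap` the larger one is
#' kept. Peak times are refined by fitting a parabola through the three samples
#' around each maximum.
#'
#' @param times numeric vector of sample times (uniform grid).
#' @param x numeric signal sampled at `times`.
#' @param min_gap minimum separation between successive peaks, in time units.
#' @param refine logical; parabolic sub-grid refinement of peak times.
#' @return data.frame with columns `time` and `value`, one row per peak.
#' @export
find_peaks <- function(times, x, min_gap = 12, refine = TRUE) {
  n <- length(x)
  if (n < 3L) return(data.frame(time = numeric(0), value = numeric(0)))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) return(data.frame(time = numeric(0), value = numeric(0)))
  # enforce refractory gap, keeping the larger of any close pair
  keep <- integer(0)
  for (i in idx) {
    if (length(keep) && times[i] - times[keep[length(keep)]] < min_gap) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  tt <- times[keep]
  vv <- x[keep]
  if (refine) {
    dt <- times[2] - times[1]
    interior <- keep > 1L & keep < n
    km <- keep[interior]
    denom <- x[km - 1L] - 2 * x[km] + x[km + 1L]
    off <- ifelse(abs(denom) > 0, 0.5 * (x[km - 1L] - x[km + 1L]) / denom, 0)
    off[abs(off) > 1] <- 0
    tt[interior] <- times[km] + off * dt
    vv[interior] <- x[km] - 0.25 * (x[km - 1L] - x[km + 1L]) * off
  }
  data.frame(time = tt, value = vv)
}

# Wrap-aware median of times modulo `period`: center on the circular mean,
# take the ordinary median of the centered deviations, map back.
circular_median <- function(times, period = 24) {
  ang <- 2 * pi * (times %% period) / period
  cm <- atan2(mean(sin(ang)), mean(cos(ang))) * period / (2 * pi)
  dev <- ((times - cm + period / 2) %% period) - period / 2
  (cm + stats::median(dev)) %% period
}

# Circular statistics on times modulo `period` (hours).
circular_spread <- function(times, period = 24) {
  ang <- 2 * pi * (times %% period) / period
  R <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  # angular deviation sqrt(2(1 - R)): bounded, sqrt(2) for a uniform spread
  list(R = R,
       spread = sqrt(2 * (1 - R)) * period / (2 * pi),
       spread_rad = sqrt(2 * (1 - R)),
       mean_time = (atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)) *
         period / (2 * pi))
}
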