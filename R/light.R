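#' Square-wave photic forcing
#'
#' Light is a 24 h square wave of adjustable width (the photoperiod) and
#' amplitude, applied only to the ventrolateral cells: the signal equals
#' `amplitude` while `(t - phase0) mod period < width` and 0 otherwise.
#' Presets: a long summer photoperiod is 16 h, a short winter photoperiod 8 h.
#'
#' @param period forcing period T (h).
#' @param width photoperiod `sigma_L` in `[0, period]` (h).
#' @param amplitude forcing strength b (model units).
#' @param phase0 clock time of lights-on (h).
#' @return An object of class `light_schedule`.
#' @export
#' @examples
#' ls <- light_schedule(width = 8, amplitude = 0.1)
#' light_signal(c(1, 9, 25), ls)
light_schedule <- function(period = 24, width = 12, amplitude = 0.6,
                           phase0 = 0) {
  assert_scalar(period, "period")
  if (period <= 0) stop_scn("period must be > 0")
  assert_scalar(width, "width")
  if (width < 0 || width > period)
    stop_scn("width must lie in [0, period] = [0, %s]", period)
  assert_scalar(amplitude, "amplitude", lower = 0)
  assert_scalar(phase0, "phase0")
  structure(list(period = period, width = width, amplitude = amplitude,
                 phase0 = phase0),
            class = "light_schedule")
}

#' One-off square light pulse
#'
#' Used by the phase-response-curve protocol: a single pulse of given onset,
#' duration and amplitude on an otherwise free-running background.
#'
#' @param onset pulse start time (h, simulation time).
#' @param duration pulse length (h).
#' @param amplitude pulse strength (model units).
#' @return An object of class `light_pulse`.
#' @export
light_pulse <- function(onset, duration = 4, amplitude = 0.1) {
  assert_scalar(onset, "onset")
  assert_scalar(duration, "duration", lower = 0)
  assert_scalar(amplitude, "amplitude", lower = 0)
  structure(list(onset = onset, duration = duration, amplitude = amplitude),
            class = "light_pulse")
}

#' Evaluate a light input at given times
#'
#' @param t numeric vector of times (h).
#' @param schedule a [light_schedule()], [light_pulse()], or `NULL` (constant
#'   darkness).
#' @return Numeric vector of light intensities.
#' @export
light_signal <- function(t, schedule) {
  assert_finite(t, "t")
  UseMethod("light_signal", schedule)
}

#' @export
light_signal.NULL <- function(t, schedule) rep(0, length(t))

#' @export
light_signal.light_schedule <- function(t, schedule) {
  ifelse(((t - schedule$phase0) %% schedule$period) < schedule$width,
         schedule$amplitude, 0)
}

#' @export
light_signal.light_pulse <- function(t, schedule) {
  ifelse(t >= schedule$onset & t < schedule$onset + schedule$duration,
         schedule$amplitude, 0)
}

#' Seasonal photoperiod presets
#'
#' @param amplitude forcing strength b (model units).
#' @return A [light_schedule()] with a 16 h (summer) or 8 h (winter)
#'   photoperiod.
#' @export
summer_photoperiod <- function(amplitude = 0.6)
  light_schedule(width = 16, amplitude = amplitude)

#' @rdname summer_photoperiod
#' @export
winter_photoperiod <- function(amplitude = 0.6)
  light_schedule(width = 8, amplitude = amplitude)
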