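#' Deterministic fixture waveforms
#'
#' Sampled test signals at solver resolution, used to exercise the
#' controller operations (pressure sensing, delays, filters) in isolation.
#'
#' @param kind `"constant"`, `"pulse"`, `"step"` or `"ramp"`
#' @param duration signal length (s)
#' @param dt sample interval (s)
#' @param value constant value (`constant`)
#' @param low,high diastolic/systolic values and `bpm` the rate (`pulse`)
#' @param from,to,at step from `from` to `to` at time `at` (`step`);
#'   `ramp` rises from `from` with `slope` per second
#' @param bpm pulse rate (beats per minute)
#' @param slope ramp slope (units/s)
#' @return numeric vector of `round(duration/dt)` samples, first sample at
#'   `t = dt`
#' @export
#' @examples
#' w <- generate_fixture_waveform("pulse", duration = 3, dt = 1e-3,
#'                                low = 80, high = 120, bpm = 69)
#' max(w)  # 120
generate_fixture_waveform <- function(kind = c("constant", "pulse", "step",
                                               "ramp"),
                                      duration, dt = 1e-3, value = 100,
                                      low = 80, high = 120, bpm = 69,
                                      from = 100, to = 150, at = duration / 2,
                                      slope = 1) {
  kind <- match.arg(kind)
  t <- seq_len(round(duration / dt)) * dt
  switch(kind,
    constant = rep(value, length(t)),
    pulse = low + (high - low) * 0.5 * (1 - cos(2 * pi * t * bpm / 60)),
    step = ifelse(t < at, from, to),
    ramp = from + slope * t)
}
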