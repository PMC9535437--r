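#' Tubuloglomerular feedback parameters
#'
#' The macula densa senses the glomerular filtration rate (the GL-to-TU
#' connector flow) with a transport delay `delta3`, and drives the afferent
#' resistance through a clamped linear activation around the operating point.
#'
#' @param op_gfr operating point (ml/min): GFR at which activation is zero
#' @param th_gfr,sa_gfr threshold and saturation (ml/min); activation is
#'   clamped to `[th_gfr - op_gfr, sa_gfr - op_gfr]`
#' @param delta3 sensing delay (s)
#' @param tau3,tau4 constriction/dilation time constants (s)
#' @param gain `g_TGF`, in (mmHg·s/L)/(ml/min): resistance contribution per
#'   unit of filtered GFR deviation
#' @param sensing `"instantaneous"` (pulsatile GL→TU flow, the default) or
#'   `"beat_averaged"`
#' @return a `tgf_params` list
#' @export
tgf_params <- function(op_gfr = 149, th_gfr = 144, sa_gfr = 333,
                       delta3 = 18, tau3 = 15, tau4 = 33, gain = 200,
                       sensing = c("instantaneous", "beat_averaged")) {
  sensing <- match.arg(sensing)
  stopifnot(th_gfr < op_gfr, op_gfr < sa_gfr, delta3 > 0, tau3 > 0, tau4 > 0)
  list(op_gfr = op_gfr, th_gfr = th_gfr, sa_gfr = sa_gfr, delta3 = delta3,
       tau3 = tau3, tau4 = tau4, gain = gain, sensing = sensing)
}

#' Delayed GFR signal
#'
#' Returns the GFR `delta3` seconds ago (nearest sample).  During warm-up
#' (insufficient history) the earliest available sample is returned, which
#' equals the initial GFR for buffers pre-filled at start.
#'
#' @param history sampled GFR (ml/min), oldest first, sampled at `dt`
#' @param delta3 delay (s)
#' @param dt sample interval (s)
#' @return GFR (ml/min) at `t - delta3`
#' @export
delayed_gfr <- function(history, delta3, dt) {
  n <- length(history)
  a3 <- round(delta3 / dt)
  history[max(1L, n - a3)]
}

#' TGF activation
#'
#' Clamped linear activation: the delayed GFR is clamped to
#' `[th_gfr, sa_gfr]` and the operating point subtracted.  Piecewise linear,
#' continuous and non-decreasing in the sensed GFR.
#'
#' @param gfr_delayed delayed GFR (ml/min)
#' @param params a [tgf_params()]
#' @return activation (ml/min of GFR deviation)
#' @export
tgf_activation <- function(gfr_delayed, params) {
  pmin(pmax(gfr_delayed, params$th_gfr), params$sa_gfr) - params$op_gfr
}

#' One TGF update step
#'
#' First-order relaxation of the (pre-gain) TGF state toward the activation,
#' with the constriction constant `tau3` when activation is positive and the
#' dilation constant `tau4` otherwise.
#'
#' @param dr_tgf current state (ml/min of GFR deviation)
#' @param a_tgf activation (ml/min)
#' @param dt step (s)
#' @param params a [tgf_params()]
#' @return updated state
#' @export
tgf_update <- function(dr_tgf, a_tgf, dt, params) {
  stopifnot(dt > 0)
  tau <- if (a_tgf > 0) params$tau3 else params$tau4
  dr_tgf + dt * (a_tgf - dr_tgf) / tau
}
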