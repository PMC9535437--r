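#' Myogenic response parameters
#'
#' Constants of the myogenic controller.  `p0` and `p1` bound the pressure
#' band over which the response modulates conductance, `q0` is the desired
#' renal blood flow, and `k` the relative fractional change in flow over the
#' band.  `delta1`/`delta2` are the constriction/dilation onset delays of the
#' pressure-sensing window, `tau1`/`tau2` the constriction/dilation time
#' constants.  Downstream resistances are the fixed renal connectors used to
#' isolate the afferent share of the target resistance.
#'
#' @param p0,p1 pressure band (mmHg); `p0 < p1`
#' @param q0 desired renal blood flow (L/s)
#' @param k dimensionless slope factor
#' @param delta1,delta2 sensing-window delays (s); `delta1 < delta2`
#' @param tau1,tau2 constriction/dilation time constants (s)
#' @param gain controller gain `g_MR`
#' @param r_base baseline afferent resistance (mmHg·s/L)
#' @param r_gl_vr,r_gl_tu,r_tu_vr,r_vr_vc downstream resistances (mmHg·s/L)
#' @param floor_frac afferent resistance floor, as a fraction of `r_base`
#' @param tau_convention `"physiological"` (default: tau1 when the target
#'   exceeds the current resistance, i.e. constriction) or `"literal"`
#'   (the printed inequality direction)
#' @return an `mr_params` list
#' @export
mr_params <- function(p0 = 80, p1 = 180, q0 = 0.018, k = 0.5,
                      delta1 = 0.3, delta2 = 1.2, tau1 = 4, tau2 = 5.3,
                      gain = 1, r_base, r_gl_vr, r_gl_tu, r_tu_vr, r_vr_vc,
                      floor_frac = 0.05,
                      tau_convention = c("physiological", "literal")) {
  tau_convention <- match.arg(tau_convention)
  stopifnot(p0 < p1, q0 > 0, k >= 0, delta1 < delta2, tau1 > 0, tau2 > 0,
            r_base > 0, floor_frac > 0)
  list(p0 = p0, p1 = p1, q0 = q0, k = k, delta1 = delta1, delta2 = delta2,
       tau1 = tau1, tau2 = tau2, gain = gain, r_base = r_base,
       r_gl_vr = r_gl_vr, r_gl_tu = r_gl_tu, r_tu_vr = r_tu_vr,
       r_vr_vc = r_vr_vc, floor_frac = floor_frac,
       tau_convention = tau_convention)
}

#' Sensed renal arterial pressure
#'
#' The myogenic sensor reads the maximum of the renal-artery pressure over
#' the window `[t - delta2, t - delta1]` — effectively the systolic pressure,
#' to which the myogenic response is most sensitive.  `delta1` gives the
#' onset delay of constriction after a pressure rise, `delta2` the onset
#' delay of dilation after a fall.
#'
#' @param history sampled pressure (mmHg), oldest first, sampled at `dt`
#' @param delta1,delta2 window delays (s)
#' @param t current time (s); the last sample of `history` is at time `t`
#' @param dt sample interval (s)
#' @return maximum pressure over the closed window (mmHg)
#' @export
sensed_pressure <- function(history, delta1, delta2, t, dt) {
  n <- length(history)
  a1 <- round(delta1 / dt)
  a2 <- round(delta2 / dt)
  if (n < a2 + 1)
    stop("insufficient history: need ", a2 + 1, " samples, have ", n)
  idx <- (n - a2):(n - a1)
  max(history[idx])
}

#' Target conductance of the renal vascular bed
#'
#' Piecewise map from sensed systolic renal pressure to the conductance that
#' would hold renal flow on the autoregulatory curve: flow `q0` at `p0`,
#' rising with relative slope `k` across `[p0, p1]`, constant outside the
#' band.  The caval pressure enters so the conductance applies to the full
#' renal pressure gradient.  Continuous at both breakpoints.
#'
#' @param p_ar sensed renal arterial pressure (mmHg)
#' @param p_vc caval (venous) pressure (mmHg)
#' @param params an [mr_params()]
#' @return target conductance (L/(s·mmHg))
#' @export
target_conductance <- function(p_ar, p_vc, params) {
  if (any(p_ar <= p_vc))
    stop("target_conductance: p_ar must exceed p_vc")
  with(params, {
    ifelse(p_ar < p0,
           q0 / (p0 - p_vc),
    ifelse(p_ar <= p1,
           q0 * (1 + k * (p_ar - p0) / p0) / (p_ar - p_vc),
           q0 * (1 + k * (p1 - p0) / p0) / (p1 - p_vc)))
  })
}

#' Afferent share of the target resistance
#'
#' The target conductance describes the whole renal path (AR to VC), but only
#' the afferent arteriole is actuated.  Subtracting the fixed downstream
#' network — efferent `GL_VR` in parallel with the tubular chain
#' `GL_TU + TU_VR`, in series with `VR_VC` — leaves the afferent target:
#' \deqn{R_T = c_T^{-1} -
#'   \left[\frac{1}{R_{GL\_VR}} + \frac{1}{R_{GL\_TU}+R_{TU\_VR}}\right]^{-1}
#'   - R_{VR\_VC}}
#' Non-positive results are clamped to the resistance floor with a warning.
#'
#' @param c_t target conductance (L/(s·mmHg))
#' @param params an [mr_params()]
#' @return afferent target resistance (mmHg·s/L)
#' @export
afferent_target_resistance <- function(c_t, params) {
  stopifnot(all(c_t > 0))
  r_down <- downstream_resistance(params)
  r_t <- 1 / c_t - r_down
  floor_r <- params$floor_frac * params$r_base
  if (any(r_t < floor_r)) {
    warning("afferent target resistance at or below floor; clamped to ",
            signif(floor_r, 4), " mmHg*s/L")
    r_t <- pmax(r_t, floor_r)
  }
  r_t
}

#' Lumped resistance downstream of the afferent arteriole
#' @param params an [mr_params()]
#' @return resistance (mmHg·s/L)
#' @export
downstream_resistance <- function(params) {
  with(params,
       1 / (1 / r_gl_vr + 1 / (r_gl_tu + r_tu_vr)) + r_vr_vc)
}

#' One myogenic update step
#'
#' First-order relaxation of the myogenic resistance contribution toward
#' `ΔR = R_T − R_base`, with the constriction constant `tau1` when the
#' target exceeds the current afferent resistance and the dilation constant
#' `tau2` otherwise (the `physiological` convention; `literal` flips the
#' comparison).
#'
#' @param dr_mr current contribution (mmHg·s/L)
#' @param r_t afferent target resistance (mmHg·s/L)
#' @param r_current current afferent resistance (mmHg·s/L)
#' @param dt step (s)
#' @param params an [mr_params()]
#' @return updated contribution (mmHg·s/L)
#' @export
mr_update <- function(dr_mr, r_t, r_current, dt, params) {
  stopifnot(dt > 0)
  d_r <- r_t - params$r_base
  constrict <- if (params$tau_convention == "literal") r_current > r_t
               else r_t > r_current
  tau <- if (constrict) params$tau1 else params$tau2
  dr_mr + dt * (d_r - dr_mr) / tau
}
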