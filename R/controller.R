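#' Controller mode
#'
#' The three run modes: `"none"` (uncontrolled), `"mr"` (myogenic response
#' only, the TGF-independent preparation) and `"mr+tgf"` (intact
#' autoregulation).
#'
#' @param mode character
#' @return list with logical `mr_active`, `tgf_active`
#' @export
controller_mode <- function(mode = c("none", "mr", "mr+tgf", "tgf")) {
  mode <- match.arg(mode)
  list(mode = mode,
       mr_active = mode %in% c("mr", "mr+tgf"),
       tgf_active = mode %in% c("tgf", "mr+tgf"))
}

#' Combined afferent resistance
#'
#' \deqn{R_{AR\_GL}(t) = R_{base} + dR_{MR}(t)\,g_{MR} + dR_{TGF}(t)\,g_{TGF}}
#' with inactive controllers contributing zero, floored at
#' `floor_frac * r_base` (a warning is issued when the floor engages).
#'
#' @param r_base baseline afferent resistance (mmHg·s/L)
#' @param dr_mr,dr_tgf controller states
#' @param g_mr,g_tgf gains
#' @param mode a [controller_mode()]
#' @param floor_frac resistance floor fraction of `r_base`
#' @return afferent resistance (mmHg·s/L)
#' @export
combined_resistance <- function(r_base, dr_mr, dr_tgf, g_mr, g_tgf,
                                mode = controller_mode("mr+tgf"),
                                floor_frac = 0.05) {
  stopifnot(r_base > 0)
  r <- r_base +
    (if (mode$mr_active) g_mr * dr_mr else 0) +
    (if (mode$tgf_active) g_tgf * dr_tgf else 0)
  floor_r <- floor_frac * r_base
  if (any(r < floor_r)) {
    warning("afferent resistance floored at ", signif(floor_r, 4),
            " mmHg*s/L")
    r <- pmax(r, floor_r)
  }
  r
}

#' Default autoregulation block
#'
#' MR and TGF parameter defaults with the controller switched off
#' (`mode = "none"`).  `r_base` and the downstream resistances of the MR
#' block are filled in from the calibrated model at simulation time when
#' left `NULL`.
#'
#' @param mode run mode
#' @return autoregulation parameter block
#' @export
default_autoregulation <- function(mode = "none") {
  list(mode = mode,
       mr = list(p0 = 80, p1 = 180, q0 = 0.018, k = 0.5,
                 delta1 = 0.3, delta2 = 1.2, tau1 = 4, tau2 = 5.3,
                 gain = 1, r_base = NULL, floor_frac = 0.05,
                 tau_convention = "physiological"),
       tgf = list(op_gfr = 149, th_gfr = 144, sa_gfr = 333,
                  delta3 = 18, tau3 = 15, tau4 = 33, gain = 200,
                  gain_units = "(mmHg*s/L)/(ml/min)",
                  sensing = "instantaneous"))
}

# Resolve the autoregulation block of a model into the flat control list the
# simulation cores consume.  r_base defaults to the model's current AR_GL
# resistance; downstream resistances are read from the model.
resolve_controller <- function(model, mode = NULL, state = NULL) {
  au <- model$autoregulation
  md <- controller_mode(mode %||% au$mode)
  dt <- model$dt
  kn <- vapply(model$connectors, `[[`, "", "name")
  if (!("AR_GL" %in% kn)) {
    if (md$mr_active || md$tgf_active)
      stop("model has no afferent connector 'AR_GL'; controllers unavailable")
    # inert controller stub for non-renal networks
    return(list(mr_active = FALSE, tgf_active = FALSE, afferent = 0L,
                ar_comp = 0L, vc_comp = 0L, gfr_conn = 0L,
                p0 = 80, p1 = 180, q0 = 0.018, k = 0.5, tau1 = 4, tau2 = 5.3,
                g_mr = 1, r_base = 1, floor_frac = 0.05, tau_literal = FALSE,
                r_gl_vr = 1, r_gl_tu = 1, r_tu_vr = 1, r_vr_vc = 1,
                op_gfr = 149, th_gfr = 144, sa_gfr = 333, tau3 = 15,
                tau4 = 33, g_tgf = 0, a1 = 0L, a2 = 0L, a3 = 0L,
                gfr_avg_steps = 0L, dr_mr = 0, dr_tgf = 0, p_buf = 0,
                gfr_buf = 0, p_head = 0L, g_head = 0L, r_aff = 1,
                warm = FALSE))
  }
  mr <- au$mr
  tgf <- au$tgf
  r_base <- mr$r_base %||% get_resistance(model, "AR_GL")
  a1 <- as.integer(round(mr$delta1 / dt))
  a2 <- as.integer(round(mr$delta2 / dt))
  a3 <- as.integer(round(tgf$delta3 / dt))
  gavg <- if (identical(tgf$sensing, "beat_averaged"))
    as.integer(round((60 / model$heart_rate) / dt)) else 0L
  if (is.null(state)) {
    state <- list(dr_mr = 0, dr_tgf = 0,
                  p_buf = numeric(a2 + 1),
                  gfr_buf = numeric(a3 + max(gavg, 1L)),
                  p_head = 0L, g_head = 0L, r_aff = r_base, warm = TRUE)
  }
  list(mr_active = md$mr_active, tgf_active = md$tgf_active,
       afferent = conn_index(model, "AR_GL") - 1L,
       ar_comp = comp_index(model, "AR") - 1L,
       vc_comp = comp_index(model, "VC") - 1L,
       gfr_conn = conn_index(model, "GL_TU") - 1L,
       p0 = mr$p0, p1 = mr$p1, q0 = mr$q0, k = mr$k,
       tau1 = mr$tau1, tau2 = mr$tau2, g_mr = mr$gain,
       r_base = r_base, floor_frac = mr$floor_frac,
       tau_literal = identical(mr$tau_convention, "literal"),
       r_gl_vr = get_resistance(model, "GL_VR"),
       r_gl_tu = get_resistance(model, "GL_TU"),
       r_tu_vr = get_resistance(model, "TU_VR"),
       r_vr_vc = get_resistance(model, "VR_VC"),
       op_gfr = tgf$op_gfr, th_gfr = tgf$th_gfr, sa_gfr = tgf$sa_gfr,
       tau3 = tgf$tau3, tau4 = tgf$tau4, g_tgf = tgf$gain,
       a1 = a1, a2 = a2, a3 = a3, gfr_avg_steps = gavg,
       dr_mr = state$dr_mr, dr_tgf = state$dr_tgf,
       p_buf = state$p_buf, gfr_buf = state$gfr_buf,
       p_head = as.integer(state$p_head), g_head = as.integer(state$g_head),
       r_aff = state$r_aff %||% r_base,
       warm = isTRUE(state$warm))
}

#' MR parameter view of a model's autoregulation block
#'
#' Convenience accessor building an [mr_params()] with `r_base` and the
#' downstream resistances resolved from the model's (calibrated) connectors.
#'
#' @param model a `hemo_model`
#' @return an `mr_params` list
#' @export
model_mr_params <- function(model) {
  mr <- model$autoregulation$mr
  mr_params(p0 = mr$p0, p1 = mr$p1, q0 = mr$q0, k = mr$k,
            delta1 = mr$delta1, delta2 = mr$delta2,
            tau1 = mr$tau1, tau2 = mr$tau2, gain = mr$gain,
            r_base = mr$r_base %||% get_resistance(model, "AR_GL"),
            r_gl_vr = get_resistance(model, "GL_VR"),
            r_gl_tu = get_resistance(model, "GL_TU"),
            r_tu_vr = get_resistance(model, "TU_VR"),
            r_vr_vc = get_resistance(model, "VR_VC"),
            floor_frac = mr$floor_frac,
            tau_convention = mr$tau_convention)
}

#' TGF parameter view of a model's autoregulation block
#' @param model a `hemo_model`
#' @return a `tgf_params` list
#' @export
model_tgf_params <- function(model) {
  p <- model$autoregulation$tgf
  tgf_params(op_gfr = p$op_gfr, th_gfr = p$th_gfr, sa_gfr = p$sa_gfr,
             delta3 = p$delta3, tau3 = p$tau3, tau4 = p$tau4,
             gain = p$gain, sensing = p$sensing)
}
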