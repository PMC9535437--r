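#' Double-Hill activation waveform for a time-varying elastance chamber
#'
#' Normalised activation \eqn{a(t) \in [0, 1]} over one cardiac cycle,
#' the product of a rising Hill term and a decaying Hill term:
#' \deqn{h(u) = \frac{(u/\alpha_1)^{n_1}}{1 + (u/\alpha_1)^{n_1}}
#'             \cdot \frac{1}{1 + (u/\alpha_2)^{n_2}}, \qquad
#'       a(u) = h(u) / \max_u h(u)}
#' with \eqn{u} the time since chamber activation onset (the cycle time
#' shifted by `shift_frac` of the period, for atrial timing).  The chamber
#' elastance is then \eqn{E(t) = E_d + a(t)\,(E_{es} - E_d)}.
#'
#' @param t times (s), any length; evaluated modulo the period
#' @param period cardiac cycle length (s)
#' @param alpha1_frac,n1 rise-time fraction of the period and rise exponent
#' @param alpha2_frac,n2 decay-time fraction of the period and decay exponent
#' @param shift_frac activation onset as a fraction of the period
#'   (0 for ventricles; atria use a late-cycle onset so the atrial kick
#'   precedes ventricular systole)
#' @return activation values in `[0, 1]`
#' @export
#' @examples
#' a <- elastance_activation(seq(0, 0.87, by = 0.001), period = 0.87)
#' range(a)
elastance_activation <- function(t, period, alpha1_frac = 0.303, n1 = 1.32,
                                 alpha2_frac = 0.508, n2 = 21.9,
                                 shift_frac = 0) {
  stopifnot(period > 0, alpha1_frac > 0, alpha2_frac > 0, n1 > 0, n2 > 0)
  u <- (t - shift_frac * period) %% period
  h <- function(u) {
    x1 <- (u / (alpha1_frac * period))^n1
    x2 <- (u / (alpha2_frac * period))^n2
    (x1 / (1 + x1)) * (1 / (1 + x2))
  }
  # normalise on a fine grid of the cycle (clamp the residual grid error)
  grid <- seq(0, period, length.out = 8192L)
  pmin(h(u) / max(h(grid)), 1)
}

#' Chamber elastance over the cycle
#'
#' @param t times (s)
#' @param profile list with fields `ees`, `ed` (mmHg/L) and optionally the
#'   activation shape parameters accepted by [elastance_activation()]
#' @param period cardiac cycle length (s)
#' @return elastance (mmHg/L), bounded by `[ed, ees]`
#' @export
chamber_elastance <- function(t, profile, period) {
  stopifnot(profile$ees > 0, profile$ed > 0, profile$ees >= profile$ed)
  a <- elastance_activation(
    t, period,
    alpha1_frac = profile$alpha1_frac %||% 0.303,
    n1 = profile$n1 %||% 1.32,
    alpha2_frac = profile$alpha2_frac %||% 0.508,
    n2 = profile$n2 %||% 21.9,
    shift_frac = profile$shift_frac %||% 0)
  profile$ed + a * (profile$ees - profile$ed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
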