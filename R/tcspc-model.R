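#' Two-component incomplete-decay model
#'
#' Expected fluorescence decay under pulsed excitation when the lifetimes
#' are not short compared with the laser repetition period, so each
#' histogram also contains photons excited by earlier pulses. Summing the
#' mono-exponential decay over all preceding pulses gives the closed form
#'
#'   f(t) = sum_i a_i * exp(-t / tau_i) / (1 - exp(-T / tau_i)),  t in [0, T)
#'
#' with `T` the repetition period. Offset (dark counts) and scatter are
#' fixed at zero; they are not part of the model.
#'
#' @param t_axis Times at which to evaluate, ps, in `[0, rep_period)`.
#' @param a1,a2 Component amplitudes (counts at the scale of one pulse).
#' @param t1,t2 Component lifetimes, ps, strictly positive.
#' @param rep_period Laser repetition period, ps.
#' @return Expected counts at `t_axis`.
#' @examples
#' tt <- seq(0, 12400, by = 48.8)
#' f <- model_incomplete_biexp(tt, a1 = 0.6, a2 = 0.4,
#'                             t1 = 700, t2 = 1750, rep_period = 12500)
#' @export
model_incomplete_biexp <- function(t_axis, a1, a2, t1, t2, rep_period) {
  if (!is.finite(t1) || !is.finite(t2) || t1 <= 0 || t2 <= 0)
    stop("lifetimes must be strictly positive", call. = FALSE)
  if (rep_period <= max(t_axis))
    stop("rep_period must exceed the largest time in t_axis", call. = FALSE)
  a1 * exp(-t_axis / t1) / (1 - exp(-rep_period / t1)) +
    a2 * exp(-t_axis / t2) / (1 - exp(-rep_period / t2))
}

#' Shift a decay curve by a (fractional) number of channels
#'
#' Translates the curve along the channel axis by linear interpolation,
#' wrapping periodically across the repetition window -- the natural
#' boundary condition for the incomplete model, whose decay is periodic in
#' the laser period. Positive shifts move the curve towards later channels.
#'
#' @param curve Numeric vector of per-channel values.
#' @param shift Shift in channels; may be fractional; `|shift| < n/4`.
#' @return Shifted curve, same length.
#' @export
apply_shift <- function(curve, shift) {
  n <- length(curve)
  stopifnot(n >= 2L, is.finite(shift))
  if (abs(shift) >= n / 4)
    stop("|shift| must be below a quarter of the channel count", call. = FALSE)
  if (shift == 0) return(curve)
  pos <- (seq_len(n) - 1 - shift) %% n      # source position, 0-based
  lo <- floor(pos)
  frac <- pos - lo
  i0 <- (lo %% n) + 1L
  i1 <- ((lo + 1) %% n) + 1L
  (1 - frac) * curve[i0] + frac * curve[i1]
}

#' Amplitude-weighted mean lifetime
#'
#' `Tm = a1% * t1 + a2% * t2`, the standard mean-lifetime summary of a
#' bi-exponential fit. The amplitude fractions must sum to 1.
#'
#' @param a1_pct,a2_pct Relative amplitude fractions (sum to 1).
#' @param t1,t2 Component lifetimes, ps.
#' @return Mean lifetime, ps. Vectorized.
#' @export
compute_tm <- function(a1_pct, t1, a2_pct, t2) {
  if (any(abs(a1_pct + a2_pct - 1) > 1e-6))
    stop("amplitude fractions must sum to 1", call. = FALSE)
  a1_pct * t1 + a2_pct * t2
}

#' FRET efficiency from mean lifetimes
#'
#' FRET shortens the donor lifetime, so given the donor's mean lifetime
#' without FRET (`tm_ref`, measured with the non-binding sensor variant)
#' the efficiency is `E = 1 - tm / tm_ref`. Values of `tm` above `tm_ref`
#' yield negative efficiencies; these are retained (not clamped) and
#' flagged in the `"flagged_negative"` attribute.
#'
#' @param tm Mean lifetime(s) of the FRET sample, ps.
#' @param tm_ref Reference (no-FRET) mean lifetime, ps, > 0.
#' @return Efficiency fraction(s); attribute `flagged_negative` marks
#'   entries with `tm > tm_ref`.
#' @examples
#' fret_efficiency(1283, 1745)  # about 0.265
#' @export
fret_efficiency <- function(tm, tm_ref) {
  if (!is.finite(tm_ref) || tm_ref <= 0)
    stop("tm_ref must be strictly positive", call. = FALSE)
  e <- 1 - tm / tm_ref
  attr(e, "flagged_negative") <- tm > tm_ref
  e
}

#' Relative change in FRET efficiency, percent
#'
#' `(1 - E_treated / E_control) * 100`: the percent reduction of FRET
#' efficiency in a treated condition relative to a control.
#'
#' @param e_treated,e_control Efficiencies; `e_control` must be non-zero.
#' @return Percent reduction (positive when treatment lowers efficiency).
#' @export
relative_efficiency_change <- function(e_treated, e_control) {
  if (any(e_control == 0))
    stop("control efficiency must be non-zero", call. = FALSE)
  (1 - as.numeric(e_treated) / as.numeric(e_control)) * 100
}
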