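#' ATP biosensor model
#'
#' Describes a genetically encoded FRET-based ATP sensor: an ATP-binding
#' domain sandwiched between a donor and an acceptor fluorophore. ATP binding
#' pulls the fluorophores together and switches the donor from its unquenched
#' lifetime `tau_free` to the shorter FRET-quenched lifetime `tau_fret`.
#' A binding-incompetent variant (`binding_competent = FALSE`) models the
#' mutant reference sensor that shows no detectable ATP binding and therefore
#' reports the donor lifetime without FRET.
#'
#' The dose-response mapping from ATP concentration to bound fraction is a
#' Hill curve. Published characterization of the real sensor does not pin
#' this shape down; the defaults (`kd` 3.3 mM, `hill_n` 2) are stated
#' generator conventions, not literature claims, and every check compares
#' against generator ground truth rather than published constants.
#'
#' @param kd Half-saturation ATP concentration (mM).
#' @param hill_n Hill coefficient (dimensionless, > 0).
#' @param tau_free Donor lifetime without FRET (ps).
#' @param tau_fret Donor lifetime in the FRET (ATP-bound) state (ps);
#'   must be shorter than `tau_free`.
#' @param binding_competent If `FALSE` the sensor never binds ATP and the
#'   bound fraction is 0 at all concentrations.
#' @return An object of class `sensor_model`.
#' @examples
#' s <- sensor_model()
#' atp_to_bound_fraction(3.3, s)  # 0.5 at kd
#' @export
sensor_model <- function(kd = 3.3, hill_n = 2, tau_free = 1750,
                         tau_fret = 700, binding_competent = TRUE) {
  stopifnot(kd > 0, hill_n > 0, tau_fret > 0)
  if (tau_fret >= tau_free)
    stop("tau_fret must be strictly smaller than tau_free", call. = FALSE)
  stop_if_not_flag(binding_competent, "binding_competent")
  structure(
    list(kd = kd, hill_n = hill_n, tau_free = tau_free, tau_fret = tau_fret,
         binding_competent = binding_competent),
    class = "sensor_model"
  )
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf(
    "<sensor_model> kd = %g mM, n = %g, tau_free = %g ps, tau_fret = %g ps, %s\n",
    x$kd, x$hill_n, x$tau_free, x$tau_fret,
    if (x$binding_competent) "binding-competent" else "non-binding reference"))
  invisible(x)
}

#' Bound fraction of the sensor at a given ATP concentration
#'
#' Hill curve `atp^n / (kd^n + atp^n)` for a binding-competent sensor;
#' identically 0 for the non-binding reference variant. Vectorized over
#' `atp`.
#'
#' @param atp ATP concentration(s), mM, non-negative.
#' @param sensor A [sensor_model()].
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
atp_to_bound_fraction <- function(atp, sensor) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (any(!is.finite(atp)) || any(atp < 0))
    stop("atp must be finite and non-negative", call. = FALSE)
  if (!sensor$binding_competent) return(rep(0, length(atp)))
  an <- atp^sensor$hill_n
  an / (sensor$kd^sensor$hill_n + an)
}

#' Expected amplitude-weighted mean lifetime for a bound fraction
#'
#' With a fraction `f` of sensors in the FRET state, the amplitude-weighted
#' mean donor lifetime is `f * tau_fret + (1 - f) * tau_free`.
#'
#' @param bound_fraction Fraction(s) in `[0, 1]`.
#' @param sensor A [sensor_model()].
#' @return Expected mean lifetime(s), ps.
#' @export
expected_tm <- function(bound_fraction, sensor) {
  stopifnot(inherits(sensor, "sensor_model"),
            all(bound_fraction >= 0), all(bound_fraction <= 1))
  bound_fraction * sensor$tau_fret + (1 - bound_fraction) * sensor$tau_free
}
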