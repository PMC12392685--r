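#' Derive a phasor calibration from a known-lifetime reference
#'
#' The instrument response and electronic delays rotate and demodulate
#' every measured phasor by the same complex factor. Measuring a
#' reference of known mono-exponential lifetime (e.g. a coumarin
#' solution) determines that factor: the correction is the rotation
#' `delta_phi = phi_theory - phi_meas` and scale
#' `mod_factor = m_theory / m_meas` that move the reference's aggregate
#' (intensity-weighted) phasor onto its closed-form position
#' [mono_exp_phasor()]. Applied to any field acquired under the same
#' response, it cancels the IRF exactly.
#'
#' @param reference An uncalibrated `phasor_field` of the reference.
#' @param tau_ref The reference's known lifetime in ns (> 0).
#' @return A `phasor_calibration` with `delta_phi` (rad), `mod_factor`,
#'   `tau_ref` and `omega`.
#' @export
calibration_from_reference <- function(reference, tau_ref) {
  stopifnot(inherits(reference, "phasor_field"), tau_ref > 0)
  if (reference$calibrated) {
    stop("reference field is already calibrated", call. = FALSE)
  }
  agg <- aggregate_phasor(reference)
  m_meas <- sqrt(agg$g^2 + agg$s^2)
  if (m_meas < 1e-12) {
    stop("reference aggregate phasor has ~zero modulus; signal unusable",
         call. = FALSE)
  }
  th <- mono_exp_phasor(tau_ref, reference$omega)
  structure(
    list(delta_phi = atan2(th$s, th$g) - atan2(agg$s, agg$g),
         mod_factor = sqrt(th$g^2 + th$s^2) / m_meas,
         tau_ref = tau_ref, omega = reference$omega),
    class = "phasor_calibration"
  )
}

#' @export
print.phasor_calibration <- function(x, ...) {
  cat(sprintf(
    "<phasor_calibration> delta_phi = %+.5f rad, mod_factor = %.5f (tau_ref = %g ns)\n",
    x$delta_phi, x$mod_factor, x$tau_ref))
  invisible(x)
}

#' Apply a phasor calibration to a field
#'
#' Rotates every valid phasor by `delta_phi` and scales its modulus by
#' `mod_factor` about the origin. The field and correction must share the
#' same angular frequency.
#'
#' @param field A `phasor_field`.
#' @param corr A `phasor_calibration` from [calibration_from_reference()].
#' @return The calibrated `phasor_field` (`calibrated = TRUE`).
#' @export
apply_calibration <- function(field, corr) {
  stopifnot(inherits(field, "phasor_field"),
            inherits(corr, "phasor_calibration"))
  if (abs(field$omega - corr$omega) > 1e-9 * corr$omega) {
    stop(sprintf("omega mismatch: field %.9g vs calibration %.9g rad/ns",
                 field$omega, corr$omega), call. = FALSE)
  }
  cphi <- cos(corr$delta_phi); sphi <- sin(corr$delta_phi)
  g <- corr$mod_factor * (field$g * cphi - field$s * sphi)
  s <- corr$mod_factor * (field$g * sphi + field$s * cphi)
  field$g <- g
  field$s <- s
  field$calibrated <- TRUE
  field
}
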