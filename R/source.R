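## The photon source: wavelength and fluence (photons per area) at the
## interaction point.

#' X-ray photon source
#'
#' Defines the pulse that illuminates the sample: photon energy (or
#' wavelength — give exactly one), pulse energy, focus size and transverse
#' profile. The fluence this source delivers on axis is the \eqn{I_0} of
#' the photon-counting detector model.
#'
#' @param photon_energy Photon energy in eV; alternative to `wavelength`.
#' @param wavelength Wavelength in m; alternative to `photon_energy`.
#' @param pulse_energy Pulse energy in J.
#' @param focus_diameter Focus diameter in m. For the flat-top profile this
#'   is the top-hat diameter; for the Gaussian profile it is the FWHM.
#' @param profile `"flat-top"` (default) or `"gaussian"`.
#' @param pulse_energy_jitter_sigma Optional per-shot normal jitter of the
#'   pulse energy, J (truncated at 0).
#' @return Object of class `fxi_source`.
#' @export
#' @examples
#' photon_source(photon_energy = 1000, pulse_energy = 1e-3,
#'               focus_diameter = 1e-6)
photon_source <- function(photon_energy = NULL, wavelength = NULL,
                          pulse_energy, focus_diameter,
                          profile = c("flat-top", "gaussian"),
                          pulse_energy_jitter_sigma = 0) {
  profile <- match.arg(profile)
  if (is.null(photon_energy) == is.null(wavelength)) {
    stop("specify exactly one of photon_energy or wavelength")
  }
  if (is.null(photon_energy)) photon_energy <- energy_from_wavelength(wavelength)
  wavelength <- wavelength_from_energy(photon_energy)
  stopifnot(pulse_energy > 0, focus_diameter > 0,
            pulse_energy_jitter_sigma >= 0)
  structure(list(photon_energy = photon_energy, wavelength = wavelength,
                 pulse_energy = pulse_energy,
                 focus_diameter = focus_diameter, profile = profile,
                 pulse_energy_jitter_sigma = pulse_energy_jitter_sigma),
            class = "fxi_source")
}

#' @export
print.fxi_source <- function(x, ...) {
  cat(sprintf("<fxi_source> %.4g eV (%.4g nm), %.3g J/pulse, %.3g um %s focus\n",
              x$photon_energy, x$wavelength * 1e9, x$pulse_energy,
              x$focus_diameter * 1e6, x$profile))
  invisible(x)
}

#' Photons per pulse
#'
#' @param src An `fxi_source`.
#' @param pulse_energy Override of the pulse energy in J (for jittered
#'   shots); defaults to the source's nominal value.
#' @return Expected photon count per pulse.
#' @export
photons_per_pulse <- function(src, pulse_energy = src$pulse_energy) {
  stopifnot(inherits(src, "fxi_source"))
  pulse_energy / (src$photon_energy * .const$e)
}

#' Fluence at a transverse position in the focus
#'
#' Photons per unit area delivered by one pulse at transverse offset
#' `position` from the beam axis. The flat-top profile is
#' \eqn{N/(\pi (d/2)^2)} inside the focus diameter and 0 outside; the
#' Gaussian profile is a 2-D Gaussian with FWHM equal to the focus diameter,
#' integrating to the photon count N over the plane.
#'
#' @param src An `fxi_source`.
#' @param position Length-2 transverse offset (m), or an n x 2 matrix.
#' @param pulse_energy Optional per-shot pulse energy override, J.
#' @return Fluence in photons/m^2 (vector if `position` is a matrix).
#' @export
#' @examples
#' src <- photon_source(photon_energy = 1000, pulse_energy = 1e-3,
#'                      focus_diameter = 1e-6)
#' fluence_at(src, c(0, 0))
fluence_at <- function(src, position = c(0, 0),
                       pulse_energy = src$pulse_energy) {
  stopifnot(inherits(src, "fxi_source"))
  if (!is.matrix(position)) position <- matrix(position, ncol = 2)
  stopifnot(ncol(position) == 2)
  n_photons <- photons_per_pulse(src, pulse_energy)
  r2 <- rowSums(position^2)
  if (src$profile == "flat-top") {
    peak <- n_photons / (pi * (src$focus_diameter / 2)^2)
    out <- ifelse(r2 <= (src$focus_diameter / 2)^2, peak, 0)
  } else {
    sigma <- src$focus_diameter / (2 * sqrt(2 * log(2)))
    out <- n_photons / (2 * pi * sigma^2) * exp(-r2 / (2 * sigma^2))
  }
  unname(out)
}
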