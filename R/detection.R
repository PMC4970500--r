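## From |F(q)|^2 to photon counts: solid angle, polarization, expected
## intensity, Poisson sampling, masks/saturation, and the real-space
## projection utility.

## CXI-convention pixel mask bits
MASK_INVALID <- 1L         # bit 0
MASK_SATURATED <- 256L     # bit 8

#' Solid angle of a detector pixel
#'
#' For a flat detector the solid angle subtended by a pixel at angle
#' \eqn{\theta'} off the detector normal is
#' \eqn{\Delta\Omega = (s^2/D^2)\cos^3\theta'} (projected pixel area times
#' inverse-square distance).
#'
#' @param det An `fxi_detector`.
#' @param pixel Optional 1-based flattened pixel index (x fast); default all.
#' @return Solid angle(s) in steradian.
#' @export
#' @examples
#' d <- detector_geometry(1, 1, 75e-6, 0.74, center_x = 0, center_y = 0)
#' solid_angle(d)  # on-axis pixel
solid_angle <- function(det, pixel = NULL) {
  stopifnot(inherits(det, "fxi_detector"))
  i <- rep(seq_len(det$nx) - 1, times = det$ny)
  j <- rep(seq_len(det$ny) - 1, each = det$nx)
  px <- (i - det$center_x) * det$pixel_size
  py <- (j - det$center_y) * det$pixel_size
  D <- det$detector_distance
  costheta <- D / sqrt(px^2 + py^2 + D^2)
  omega <- (det$pixel_size^2 / D^2) * costheta^3
  if (is.null(pixel)) omega else omega[pixel]
}

#' Polarization factor
#'
#' The fraction of Thomson-scattered intensity surviving at full scattering
#' angle \eqn{\theta} and azimuth \eqn{\phi}: for a linearly polarized beam
#' \eqn{P = 1 - \sin^2\theta\cos^2\phi} (horizontal polarization axis) or
#' \eqn{1 - \sin^2\theta\sin^2\phi} (vertical); for unpolarized light
#' \eqn{P = (1 + \cos^2\theta)/2}; `"ignore"` returns 1.
#'
#' @param theta Full scattering angle(s), rad.
#' @param phi Azimuth(s), rad.
#' @param mode `"horizontal"`, `"vertical"`, `"unpolarized"` or `"ignore"`.
#' @return Dimensionless factor(s) in \[0, 1\].
#' @export
polarization_factor <- function(theta, phi,
                                mode = c("ignore", "horizontal", "vertical",
                                         "unpolarized")) {
  mode <- match.arg(mode)
  switch(mode,
    ignore = rep(1, length(theta)),
    horizontal = 1 - sin(theta)^2 * cos(phi)^2,
    vertical = 1 - sin(theta)^2 * sin(phi)^2,
    unpolarized = (1 + cos(theta)^2) / 2)
}

.intensity_pattern <- function(expected, sampled, mask, meta) {
  structure(list(expected = expected, sampled = sampled, mask = mask,
                 meta = meta),
            class = "fxi_intensity")
}

#' @export
print.fxi_intensity <- function(x, ...) {
  cat(sprintf("<fxi_intensity> %d x %d pixels, total expected %.4g photons%s\n",
              ncol(x$expected), nrow(x$expected), sum(x$expected),
              if (!is.null(x$sampled)) ", Poisson-sampled" else ""))
  invisible(x)
}

#' Expected photon counts per pixel
#'
#' The photon-counting detector model
#' \deqn{I_{pix} = I_0 \,\Delta\Omega\, P\, |F(q)|^2 \, \epsilon}
#' with \eqn{I_0} the on-axis fluence (photons/m^2), \eqn{\Delta\Omega}
#' the pixel solid angle, \eqn{P} the polarization factor and \eqn{\epsilon}
#' the scalar quantum efficiency. Since \eqn{|F|^2} has units m^2, the
#' result is a dimensionless expected count.
#'
#' @param amp An `fxi_amplitude`.
#' @param det An `fxi_detector` (shape must match the amplitude's q map).
#' @param src An `fxi_source` with the same wavelength as the q map.
#' @param pol_mode Polarization mode, see [polarization_factor()].
#' @param pulse_energy Optional per-shot pulse energy override, J.
#' @return An `fxi_intensity` with the `expected` matrix filled.
#' @export
expected_intensity <- function(amp, det, src, pol_mode = "ignore",
                               pulse_energy = NULL) {
  stopifnot(inherits(amp, "fxi_amplitude"), inherits(det, "fxi_detector"),
            inherits(src, "fxi_source"))
  if (abs(amp$qmap$wavelength - src$wavelength) >
      1e-9 * src$wavelength) {
    stop("wavelength mismatch between amplitude pattern and source")
  }
  if (amp$qmap$nx != det$nx || amp$qmap$ny != det$ny) {
    stop("detector shape does not match the amplitude's q map")
  }
  if (is.null(pulse_energy)) pulse_energy <- src$pulse_energy
  i0 <- fluence_at(src, c(0, 0), pulse_energy)
  omega <- solid_angle(det)
  P <- polarization_factor(amp$qmap$theta, amp$qmap$phi, pol_mode)
  I <- i0 * omega * P * Mod(amp$F)^2 * det$quantum_efficiency
  expected <- matrix(I, nrow = det$ny, ncol = det$nx, byrow = TRUE)
  .intensity_pattern(expected, NULL, det$mask,
                     list(wavelength = src$wavelength,
                          distance = det$detector_distance,
                          fluence = i0, pol_mode = pol_mode))
}

#' Apply Poisson shot noise
#'
#' Photon counting inevitably suffers from shot noise: each pixel's sampled
#' count is an independent Poisson draw with the expected count as mean.
#' Optional Gaussian read noise (in photon units) is added after the
#' Poisson draw, rounded, and floored at zero.
#'
#' @param i An `fxi_intensity` with expected counts.
#' @param rng_seed Optional integer seed for reproducibility.
#' @param read_noise_sigma Std. dev. of additive detector read noise,
#'   photons; 0 disables it.
#' @return The `fxi_intensity` with the `sampled` integer matrix filled.
#' @export
apply_poisson <- function(i, rng_seed = NULL, read_noise_sigma = 0) {
  stopifnot(inherits(i, "fxi_intensity"), all(is.finite(i$expected)))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  counts <- stats::rpois(length(i$expected), i$expected)
  if (read_noise_sigma > 0) {
    counts <- pmax(0, round(counts + stats::rnorm(length(counts), 0,
                                                  read_noise_sigma)))
  }
  i$sampled <- matrix(as.integer(counts), nrow = nrow(i$expected))
  i
}

#' Apply detector mask and saturation
#'
#' Pixels above the detector's saturation level are clipped to it and
#' flagged with the CXI saturation bit (bit 8); the detector's mask bits
#' (bit 0 = invalid) are propagated. Values under the mask are preserved,
#' only flagged.
#'
#' @param i An `fxi_intensity`.
#' @param det An `fxi_detector`.
#' @return The `fxi_intensity` with mask updated and values clipped.
#' @export
apply_mask_and_saturation <- function(i, det) {
  stopifnot(inherits(i, "fxi_intensity"), inherits(det, "fxi_detector"))
  mask <- det$mask
  if (is.finite(det$saturation_level)) {
    for (field in c("expected", "sampled")) {
      if (is.null(i[[field]])) next
      over <- i[[field]] > det$saturation_level
      if (any(over)) {
        i[[field]][over] <- if (field == "sampled")
          as.integer(det$saturation_level) else det$saturation_level
        mask[over] <- bitwOr(mask[over], MASK_SATURATED)
      }
    }
  }
  i$mask <- mask
  i
}

#' Real-space projection image from far-field amplitudes
#'
#' In the small-angle regime the Ewald-sphere curvature is negligible and
#' the detector samples an (almost) flat 2-D slice of reciprocal space, so
#' a 2-D inverse DFT of F over the detector grid yields the complex
#' projection of the scattering potential along the beam. The real-space
#' pixel size is \eqn{2\pi/(N \Delta q)} per axis.
#'
#' @param amp An `fxi_amplitude` computed on a detector q map.
#' @return List with `image` (complex ny x nx matrix, zero frequency at the
#'   array centre), `pixel_size` (length-2, m) and `warning_flag` (set when
#'   the maximum scattering angle exceeds ~5 degrees and the flat-grid
#'   assumption degrades).
#' @export
projection_image <- function(amp) {
  stopifnot(inherits(amp, "fxi_amplitude"))
  qm <- amp$qmap
  warn <- NULL
  if (max(qm$theta) > 5 * pi / 180) {
    warn <- sprintf("max scattering angle %.2f deg exceeds the small-angle regime",
                    max(qm$theta) * 180 / pi)
  }
  Fg <- matrix(amp$F, nrow = qm$ny, ncol = qm$nx, byrow = TRUE)
  ## q spacing of the flat grid approximation (transverse components)
  qx <- matrix(qm$q[, 1], nrow = qm$ny, byrow = TRUE)
  qy <- matrix(qm$q[, 2], nrow = qm$ny, byrow = TRUE)
  dqx <- qx[1, 2] - qx[1, 1]
  dqy <- qy[2, 1] - qy[1, 1]
  nx <- qm$nx; ny <- qm$ny
  ## shift so that the q = 0 sample sits at matrix element (1,1) for fft;
  ## the grid q = dq * (index - 1 - c), so multiply by the appropriate
  ## phase ramp to recentre the image afterwards
  cx <- -qx[1, 1] / dqx   # fractional index of q_x = 0 (0-based)
  cy <- -qy[1, 1] / dqy
  ## inverse DFT: f(x_m) = sum_k F_k exp(+i q_k x_m); with q_k = dq (k - c)
  ## and x_m = dx (m - n/2), dx = 2pi/(n dq)
  kx <- seq_len(nx) - 1; ky <- seq_len(ny) - 1
  mx <- seq_len(nx) - 1 - floor(nx / 2)
  my <- seq_len(ny) - 1 - floor(ny / 2)
  ## f(x_m) = sum_k F_k exp(+i q_k x_m) with q = dq (k - c) and
  ## x = dx (m - n/2), dx = 2pi/(n dq): a small dense separable transform
  ## (detector rasters are at most a few hundred pixels per axis)
  Ax <- exp(2i * pi * ((kx - cx) %o% mx) / nx)  # nx x nx
  Ay <- exp(2i * pi * ((ky - cy) %o% my) / ny)  # ny x ny
  img <- t(Ay) %*% Fg %*% Ax / (nx * ny)
  pixel <- c(2 * pi / (ny * abs(dqy)), 2 * pi / (nx * abs(dqx)))
  list(image = img, pixel_size = pixel, warning_flag = warn)
}
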