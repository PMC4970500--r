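## Small pattern-analysis utilities: radial averaging, central speckle
## size, and scattering-weighted particle size.

#' Azimuthally averaged radial profile
#'
#' Averages a detector-shaped matrix over rings of constant pixel radius
#' around a centre.
#'
#' @param m Numeric matrix (`ny` x `nx`).
#' @param center_x,center_y Centre in 0-based pixel units.
#' @return Data frame with `radius` (pixels) and `value`.
#' @export
radial_average <- function(m, center_x = (ncol(m) - 1) / 2,
                           center_y = (nrow(m) - 1) / 2) {
  r <- sqrt(outer((seq_len(nrow(m)) - 1 - center_y)^2,
                  (seq_len(ncol(m)) - 1 - center_x)^2, "+"))
  br <- floor(r + 0.5)
  v <- tapply(as.numeric(m), as.numeric(br), mean)
  data.frame(radius = as.numeric(names(v)), value = as.numeric(v))
}

#' Central speckle size of a diffraction pattern
#'
#' Measures the full width at half maximum of the azimuthally averaged
#' central lobe of an intensity pattern, in scattering-vector units. For a
#' compact particle of effective diameter \eqn{D} the central speckle is
#' the transform of the particle support and its FWHM is close to
#' \eqn{2\pi/D} (for a uniform ball it is \eqn{3.63/R \approx 1.16 \times
#' 2\pi/D}).
#'
#' @param intensity `ny` x `nx` intensity matrix.
#' @param dq Pixel spacing in q, 1/m (transverse, small-angle).
#' @param center_x,center_y Beam centre in 0-based pixel units.
#' @return Speckle FWHM in 1/m.
#' @export
central_speckle_size <- function(intensity, dq,
                                 center_x = (ncol(intensity) - 1) / 2,
                                 center_y = (nrow(intensity) - 1) / 2) {
  prof <- radial_average(intensity, center_x, center_y)$value
  prof <- prof / prof[1]
  below <- which(prof < 0.5)
  if (length(below) == 0) stop("central lobe wider than the detector")
  i <- below[1]
  ## linear interpolation between the bracketing ring radii
  x <- (i - 2) + (prof[i - 1] - 0.5) / (prof[i - 1] - prof[i])
  2 * x * dq
}

#' Scattering-weighted effective particle diameter
#'
#' The Guinier-style size measure \eqn{D_{eff} = 2\sqrt{(5/3)}\,R_g} with
#' \eqn{R_g} the (weighted) radius of gyration; exact for a uniform ball,
#' where it returns the ball diameter.
#'
#' @param positions n x 3 matrix of positions, m.
#' @param weights Optional non-negative weights (e.g. electron counts).
#' @return Effective diameter in m.
#' @export
guinier_diameter <- function(positions, weights = NULL) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 3)
  if (is.null(weights)) weights <- rep(1, nrow(positions))
  stopifnot(length(weights) == nrow(positions), all(weights >= 0))
  ctr <- colSums(positions * weights) / sum(weights)
  rg2 <- sum(weights * rowSums(sweep(positions, 2, ctr)^2)) / sum(weights)
  2 * sqrt(5 / 3 * rg2)
}
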