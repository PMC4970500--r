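## Rotations, detector layout, and the map from detector pixels to
## scattering vectors q on the Ewald sphere.

## ---- rotations -------------------------------------------------------------
## Internal representation: unit quaternion c(w, x, y, z). Rotations act
## actively on column vectors; composition r1 %*% r2 means "apply r2 first".

.quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("zero quaternion")
  q / n
}

#' Rotation from a quaternion
#'
#' @param q Numeric length-4 vector `(w, x, y, z)`; normalised internally.
#' @return Object of class `fxi_rotation` (a unit quaternion).
#' @export
rotation_from_quaternion <- function(q) {
  stopifnot(is.numeric(q), length(q) == 4, all(is.finite(q)))
  structure(.quat_normalize(as.numeric(q)), class = "fxi_rotation")
}

#' Identity rotation
#' @return An `fxi_rotation`.
#' @export
rotation_identity <- function() rotation_from_quaternion(c(1, 0, 0, 0))

## quaternion for a rotation by `angle` about principal axis "x"/"y"/"z"
.quat_axis <- function(axis, angle) {
  v <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
              stop("axis must be one of x, y, z"))
  c(cos(angle / 2), sin(angle / 2) * v)
}

.quat_mul <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

#' Rotation from extrinsic Euler angles
#'
#' The three rotations are applied about the FIXED laboratory axes named in
#' `order`, first letter first: `order = "xyz"` with angles `(a, b, c)`
#' means rotate about lab x by `a`, then lab y by `b`, then lab z by `c`.
#' All 12 three-letter orders with no two adjacent equal axes are accepted.
#'
#' @param angles Numeric length-3, radians.
#' @param order Three-letter axis order string, e.g. `"zyz"` or `"xyz"`.
#' @return An `fxi_rotation`.
#' @export
#' @examples
#' rotation_from_euler(c(0, 0, pi/2), "xyz")
rotation_from_euler <- function(angles, order = "zyz") {
  stopifnot(is.numeric(angles), length(angles) == 3)
  ax <- strsplit(tolower(order), "")[[1]]
  if (length(ax) != 3 || !all(ax %in% c("x", "y", "z")) ||
      ax[1] == ax[2] || ax[2] == ax[3]) {
    stop("order must be one of the 12 valid Euler axis orders, got '",
         order, "'")
  }
  ## extrinsic: later rotations multiply from the left
  q <- .quat_axis(ax[1], angles[1])
  q <- .quat_mul(.quat_axis(ax[2], angles[2]), q)
  q <- .quat_mul(.quat_axis(ax[3], angles[3]), q)
  rotation_from_quaternion(q)
}

#' Rotation from a 3x3 matrix
#'
#' @param m Orthonormal 3x3 matrix with determinant +1.
#' @return An `fxi_rotation`.
#' @export
rotation_from_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 3))
  if (max(abs(crossprod(m) - diag(3))) > 1e-8 || det(m) < 0) {
    stop("matrix is not a proper rotation (orthonormal, det +1)")
  }
  tr <- sum(diag(m))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (m[3, 2] - m[2, 3]) / s, (m[1, 3] - m[3, 1]) / s,
           (m[2, 1] - m[1, 2]) / s)
  } else {
    i <- which.max(diag(m))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(m[i, i] - m[j, j] - m[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (m[k, j] - m[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (m[j, i] + m[i, j]) / s
    q[k + 1] <- (m[k, i] + m[i, k]) / s
  }
  rotation_from_quaternion(q)
}

#' Rotation matrix of a rotation
#'
#' @param r An `fxi_rotation`.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(r) {
  stopifnot(inherits(r, "fxi_rotation"))
  w <- r[1]; x <- r[2]; y <- r[3]; z <- r[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Compose two rotations
#'
#' `rotation_compose(r1, r2)` applies `r2` first, then `r1`.
#'
#' @param r1,r2 `fxi_rotation` objects.
#' @return An `fxi_rotation`.
#' @export
rotation_compose <- function(r1, r2) {
  rotation_from_quaternion(.quat_mul(unclass(r1), unclass(r2)))
}

#' Inverse rotation
#' @param r An `fxi_rotation`.
#' @return An `fxi_rotation`.
#' @export
rotation_inverse <- function(r) {
  rotation_from_quaternion(c(r[1], -r[2:4]))
}

#' Apply a rotation to 3-vectors
#'
#' @param r An `fxi_rotation`.
#' @param v Length-3 vector or n x 3 matrix of row vectors.
#' @return Rotated vector(s), same shape as `v`.
#' @export
apply_rotation <- function(r, v) {
  m <- rotation_matrix(r)
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 3)
    v %*% t(m)
  } else {
    stopifnot(length(v) == 3)
    drop(m %*% v)
  }
}

#' Uniform random rotations
#'
#' Samples rotations uniformly over SO(3) by normalising 4-D standard
#' Gaussian quaternions.
#'
#' @param n Number of rotations.
#' @return List of `fxi_rotation` objects (an `fxi_rotation` if `n == 1`).
#' @export
random_rotation <- function(n = 1) {
  out <- lapply(seq_len(n), function(i)
    rotation_from_quaternion(stats::rnorm(4)))
  if (n == 1) out[[1]] else out
}

#' @export
print.fxi_rotation <- function(x, ...) {
  cat(sprintf("<fxi_rotation> quaternion (w,x,y,z) = (%.4f, %.4f, %.4f, %.4f)\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

## ---- detector --------------------------------------------------------------

#' Pixel-array detector geometry
#'
#' Describes a flat detector orthogonal to the nominal beam axis. The lab
#' frame has z along the beam, x the fast pixel axis, y the slow axis;
#' pixel indices are 0-based and the beam centre may be fractional.
#'
#' @param nx,ny Pixel counts (>= 1).
#' @param pixel_size Pixel edge length in m.
#' @param detector_distance Distance from interaction point along the beam, m.
#' @param center_x,center_y Beam centre in pixel units; defaults to the
#'   detector midpoint `(n-1)/2`.
#' @param mask Optional integer matrix (`ny` x `nx`) of per-pixel mask bits
#'   (CXI convention: bit 0 = invalid); default all zero.
#' @param saturation_level Saturation threshold in photons (`Inf` = none).
#' @param quantum_efficiency Scalar in (0, 1].
#' @return Object of class `fxi_detector`.
#' @export
#' @examples
#' detector_geometry(64, 64, 75e-6, 0.74)
detector_geometry <- function(nx, ny, pixel_size, detector_distance,
                              center_x = (nx - 1) / 2,
                              center_y = (ny - 1) / 2,
                              mask = NULL,
                              saturation_level = Inf,
                              quantum_efficiency = 1) {
  stopifnot(nx >= 1, ny >= 1, pixel_size > 0, detector_distance > 0,
            quantum_efficiency > 0, quantum_efficiency <= 1)
  if (is.null(mask)) mask <- matrix(0L, nrow = ny, ncol = nx)
  stopifnot(is.matrix(mask), nrow(mask) == ny, ncol(mask) == nx)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size,
                 detector_distance = detector_distance,
                 center_x = center_x, center_y = center_y,
                 mask = mask, saturation_level = saturation_level,
                 quantum_efficiency = quantum_efficiency),
            class = "fxi_detector")
}

#' @export
print.fxi_detector <- function(x, ...) {
  cat(sprintf("<fxi_detector> %d x %d pixels, %.3g um pitch, D = %.3g m\n",
              x$nx, x$ny, x$pixel_size * 1e6, x$detector_distance))
  invisible(x)
}

## ---- q map -----------------------------------------------------------------

#' Scattering-vector map of a detector
#'
#' Maps every pixel centre to its scattering vector on the Ewald sphere:
#' for pixel position \eqn{p = ((i - c_x)s, (j - c_y)s, D)} in the lab frame
#' with unit direction \eqn{\hat s = p/|p|},
#' \deqn{q = \frac{2\pi}{\lambda}(\hat s - \hat z'),}
#' where \eqn{\hat z'} is the (possibly tilted) incident beam direction.
#' The convention includes the \eqn{2\pi} factor, so
#' \eqn{|q| = (4\pi/\lambda)\sin(\theta/2)} and full-period resolution is
#' \eqn{2\pi/|q|}.
#'
#' @param det An `fxi_detector`.
#' @param wavelength Wavelength in m.
#' @param beam_tilt Length-2 tilt angles (rad) of the incident beam about
#'   the lab x and y axes; the detector stays fixed.
#' @return Object of class `fxi_qmap`: fields `q` (npix x 3 matrix, pixel
#'   x index fast), `theta`, `phi`, `nx`, `ny`, `wavelength`.
#' @export
#' @examples
#' qmap_from_detector(detector_geometry(8, 8, 75e-6, 0.74), 1.24e-9)
qmap_from_detector <- function(det, wavelength, beam_tilt = c(0, 0)) {
  stopifnot(inherits(det, "fxi_detector"), wavelength > 0,
            length(beam_tilt) == 2, all(abs(beam_tilt) < 0.1))
  k <- 2 * pi / wavelength
  i <- rep(seq_len(det$nx) - 1, times = det$ny)   # fast axis
  j <- rep(seq_len(det$ny) - 1, each = det$nx)
  px <- (i - det$center_x) * det$pixel_size
  py <- (j - det$center_y) * det$pixel_size
  pz <- det$detector_distance
  norm <- sqrt(px^2 + py^2 + pz^2)
  s <- cbind(px, py, pz) / norm
  ## incident direction: z rotated by small tilts about x then y
  tilt <- rotation_compose(rotation_from_euler(c(0, beam_tilt[2], 0), "xyz"),
                           rotation_from_euler(c(beam_tilt[1], 0, 0), "xyz"))
  z0 <- apply_rotation(tilt, c(0, 0, 1))
  q <- k * sweep(s, 2, z0, "-")
  costheta <- pmin(1, pmax(-1, s %*% z0))
  theta <- acos(drop(costheta))
  phi <- atan2(py, px)
  structure(list(q = unname(q), theta = theta, phi = phi,
                 nx = det$nx, ny = det$ny, wavelength = wavelength,
                 beam_direction = z0),
            class = "fxi_qmap")
}

#' Build a q map from explicit scattering vectors
#'
#' Utility for evaluating amplitudes on arbitrary q points (for example a
#' radial line) rather than a detector raster.
#'
#' @param q n x 3 matrix of scattering vectors, 1/m.
#' @param wavelength Wavelength in m.
#' @return An `fxi_qmap` with `nx = n`, `ny = 1`.
#' @export
qmap_manual <- function(q, wavelength) {
  if (!is.matrix(q)) q <- matrix(q, ncol = 3)
  stopifnot(ncol(q) == 3, wavelength > 0)
  k <- 2 * pi / wavelength
  qn <- sqrt(rowSums(q^2))
  theta <- 2 * asin(pmin(1, qn / (2 * k)))
  structure(list(q = unname(q), theta = theta, phi = atan2(q[, 2], q[, 1]),
                 nx = nrow(q), ny = 1L, wavelength = wavelength,
                 beam_direction = c(0, 0, 1)),
            class = "fxi_qmap")
}

#' Full-period resolution at a pixel
#'
#' @param qmap An `fxi_qmap`.
#' @param pixel Pixel index (1-based, into the flattened pixel order), or
#'   omitted for all pixels.
#' @return Resolution \eqn{d = 2\pi/|q|} in m (`Inf` at the exact centre).
#' @export
resolution_at_pixel <- function(qmap, pixel = NULL) {
  stopifnot(inherits(qmap, "fxi_qmap"))
  qn <- sqrt(rowSums(qmap$q^2))
  d <- ifelse(qn > 0, 2 * pi / qn, Inf)
  if (is.null(pixel)) d else d[pixel]
}
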