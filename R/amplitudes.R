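## Far-field complex scattering amplitudes F(q) at the QMap points for each
## particle model, coherent superposition of multiple particles, and a
## literal brute-force DFT oracle.

.amplitude_pattern <- function(F, qmap, provenance, warning_flag = NULL) {
  structure(list(F = F, qmap = qmap, provenance = provenance,
                 warning_flag = warning_flag),
            class = "fxi_amplitude")
}

#' @export
print.fxi_amplitude <- function(x, ...) {
  cat(sprintf("<fxi_amplitude> %d pixels (%d x %d), model: %s, max|F| = %.3g m\n",
              length(x$F), x$qmap$nx, x$qmap$ny, x$provenance,
              max(Mod(x$F))))
  if (!is.null(x$warning_flag)) cat("  warning: ", x$warning_flag, "\n")
  invisible(x)
}

## rotate q into the particle frame: a particle rotated by R has
## F_R(q) = F(R^-1 q)
.q_particle_frame <- function(qmap, orientation) {
  if (is.null(orientation)) return(qmap$q)
  apply_rotation(rotation_inverse(orientation), qmap$q)
}

#' Brute-force nonuniform DFT (testing oracle)
#'
#' The literal double loop \eqn{F(q_i) = \sum_j w_j \exp(-i q_i \cdot r_j)},
#' written in plain R with no algebraic shortcuts. It is the independent
#' oracle every fast amplitude path is checked against; keep instances small
#' (\eqn{\le 10^5} point-pixel products recommended).
#'
#' @param points n x 3 matrix of point positions, m.
#' @param weights Length-n complex weights.
#' @param qmap An `fxi_qmap`.
#' @return An `fxi_amplitude`.
#' @export
brute_force_dft <- function(points, weights, qmap) {
  stopifnot(inherits(qmap, "fxi_qmap"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  stopifnot(nrow(points) == length(weights))
  F <- complex(length.out = nrow(qmap$q))
  for (i in seq_along(F)) {
    acc <- 0 + 0i
    for (j in seq_len(nrow(points))) {
      acc <- acc + weights[j] *
        exp(-1i * sum(qmap$q[i, ] * points[j, ]))
    }
    F[i] <- acc
  }
  .amplitude_pattern(F, qmap, "brute_force_dft")
}

## fast path: dense exact evaluation in C++
.nudft <- function(points, weights, q) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  .nudft_cpp(q, points, as.complex(weights))
}

#' Scattering amplitude of an atomic model
#'
#' \deqn{F(q) = r_0 \sum_a f_a(\lambda) \sum_{i \in a}
#'       \exp(-i q \cdot R r_i)}
#' with \eqn{R} the particle orientation and \eqn{f_a} the complex atomic
#' scattering factor of species \eqn{a}. Orientation is applied by rotating
#' `q` into the particle frame, so coordinates are never resampled.
#'
#' @param p An `fxi_atoms` particle.
#' @param qmap An `fxi_qmap`.
#' @param photon_energy Photon energy in eV.
#' @return An `fxi_amplitude` (units: m, scattering length).
#' @export
amplitude_atoms <- function(p, qmap, photon_energy) {
  stopifnot(inherits(p, "fxi_atoms"), inherits(qmap, "fxi_qmap"))
  qp <- .q_particle_frame(qmap, p$orientation)
  F <- complex(length.out = nrow(qp))
  for (z in unique(p$elements)) {
    f <- atomic_scattering_factor(z, photon_energy)
    sel <- p$elements == z
    F <- F + f * .nudft(p$positions[sel, , drop = FALSE],
                        rep(1 + 0i, sum(sel)), qp)
  }
  .amplitude_pattern(.const$r0 * F, qmap,
                     sprintf("atoms (n = %d)", length(p$elements)))
}

#' Scattering amplitude of a voxelized map
#'
#' \deqn{F(q) = \frac{k^2}{2\pi}\,\Delta x^3 \sum_j \bar n_j
#'       \exp(-i q \cdot R x_j)}
#' where \eqn{\bar n = 1 - n} is the complemented refractive index of each
#' voxel and \eqn{k = 2\pi/\lambda}. The per-voxel weight
#' \eqn{(k^2/2\pi)\Delta x^3 \bar n} equals \eqn{r_0} times the effective
#' electron content of the voxel, which makes this model consistent with
#' [amplitude_atoms()] and [amplitude_sphere()].
#'
#' @param p An `fxi_map` particle.
#' @param qmap An `fxi_qmap`.
#' @param wavelength Wavelength in m.
#' @return An `fxi_amplitude`. If the grid is too coarse for the largest
#'   requested `|q|` (`dx > pi / q_max`), the pattern carries a
#'   `warning_flag`.
#' @export
amplitude_map <- function(p, qmap, wavelength) {
  stopifnot(inherits(p, "fxi_map"), inherits(qmap, "fxi_qmap"))
  nbar <- map_nbar(p, wavelength)
  n <- dim(p$values)[1]
  k <- 2 * pi / wavelength
  qp <- .q_particle_frame(qmap, p$orientation)
  qmax <- sqrt(max(rowSums(qp^2)))
  warn <- NULL
  if (p$dx > pi / qmax) {
    warn <- sprintf("grid too coarse: dx = %.3g m exceeds pi/q_max = %.3g m",
                    p$dx, pi / qmax)
  }
  ## voxel centre coordinates relative to the map centre; drop empty voxels
  idx <- seq_len(n) - (n + 1) / 2
  nz <- which(nbar != 0)
  if (length(nz) == 0) {
    return(.amplitude_pattern(complex(length.out = nrow(qp)), qmap,
                              "map (empty)", warn))
  }
  ijk <- arrayInd(nz, dim(p$values))
  pts <- cbind(idx[ijk[, 1]], idx[ijk[, 2]], idx[ijk[, 3]]) * p$dx
  w <- (k^2 / (2 * pi)) * p$dx^3 * nbar[nz]
  F <- .nudft(pts, w, qp)
  .amplitude_pattern(F, qmap, sprintf("map (%d^3 voxels)", n), warn)
}

## the uniform-sphere shape factor 3(sin u - u cos u)/u^3, with the
## analytic q -> 0 limit
.sphere_shape_factor <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  out[small] <- 1 - u[small]^2 / 10       # Taylor expansion
  us <- u[!small]
  out[!small] <- 3 * (sin(us) - us * cos(us)) / us^3
  out
}

#' Scattering amplitude of a uniform sphere (analytic)
#'
#' \deqn{F(q) = s_{tot}\, \frac{3[\sin(qR) - qR\cos(qR)]}{(qR)^3}}
#' with \eqn{R = d/2} and total scattering length
#' \eqn{s_{tot} = (k^2/2\pi)\,\bar n\,(4/3)\pi R^3}.
#'
#' @param p An `fxi_sphere` particle.
#' @param qmap An `fxi_qmap`.
#' @param wavelength Wavelength in m.
#' @return An `fxi_amplitude`.
#' @export
amplitude_sphere <- function(p, qmap, wavelength) {
  stopifnot(inherits(p, "fxi_sphere"), inherits(qmap, "fxi_qmap"))
  k <- 2 * pi / wavelength
  nbar <- .nbar(p$material, energy_from_wavelength(wavelength))
  R <- p$diameter / 2
  s_tot <- (k^2 / (2 * pi)) * nbar * (4 / 3) * pi * R^3
  qn <- sqrt(rowSums(qmap$q^2))
  F <- s_tot * .sphere_shape_factor(qn * R)
  .amplitude_pattern(F, qmap, sprintf("sphere (d = %.3g nm)", p$diameter * 1e9))
}

#' Scattering amplitude of a uniform spheroid (analytic)
#'
#' The classic ellipsoid reduction of the sphere solution:
#' \eqn{F(q) = s_{tot}\, 3[\sin u - u\cos u]/u^3} with
#' \eqn{u = |q| R_{eff}(\psi)}, \eqn{R_{eff}^2 = a^2\sin^2\psi +
#' c^2\cos^2\psi}, and \eqn{\psi} the angle between \eqn{q} and the rotated
#' symmetry axis.
#'
#' @param p An `fxi_spheroid` particle.
#' @param qmap An `fxi_qmap`.
#' @param wavelength Wavelength in m.
#' @return An `fxi_amplitude`.
#' @export
amplitude_spheroid <- function(p, qmap, wavelength) {
  stopifnot(inherits(p, "fxi_spheroid"), inherits(qmap, "fxi_qmap"))
  k <- 2 * pi / wavelength
  nbar <- .nbar(p$material, energy_from_wavelength(wavelength))
  ax <- spheroid_semiaxes(p)
  a <- ax[1]; c_ <- ax[3]
  s_tot <- (k^2 / (2 * pi)) * nbar * (4 / 3) * pi * a^2 * c_
  axis <- apply_rotation(p$orientation, c(0, 0, 1))
  qn <- sqrt(rowSums(qmap$q^2))
  cospsi <- numeric(length(qn))
  pos <- qn > 0
  cospsi[pos] <- (qmap$q[pos, , drop = FALSE] %*% axis) / qn[pos]
  cospsi <- pmin(1, pmax(-1, cospsi))
  reff <- sqrt(a^2 * (1 - cospsi^2) + c_^2 * cospsi^2)
  F <- s_tot * .sphere_shape_factor(qn * reff)
  .amplitude_pattern(F, qmap,
                     sprintf("spheroid (d = %.3g nm, c/a = %.3g)",
                             p$diameter * 1e9, p$flattening))
}

#' Scattering amplitude of any particle model
#'
#' Generic dispatcher over the four particle models.
#'
#' @param p An `fxi_particle`.
#' @param qmap An `fxi_qmap`.
#' @param photon_energy Photon energy in eV.
#' @return An `fxi_amplitude`.
#' @export
amplitude <- function(p, qmap, photon_energy) {
  wl <- wavelength_from_energy(photon_energy)
  if (inherits(p, "fxi_sphere"))   return(amplitude_sphere(p, qmap, wl))
  if (inherits(p, "fxi_spheroid")) return(amplitude_spheroid(p, qmap, wl))
  if (inherits(p, "fxi_map"))      return(amplitude_map(p, qmap, wl))
  if (inherits(p, "fxi_atoms"))    return(amplitude_atoms(p, qmap, photon_energy))
  stop("unknown particle model")
}

#' Coherent superposition of particle amplitudes
#'
#' \deqn{F_{tot}(q) = \sum_j F_j(q)\, e^{-i q \cdot \Delta r_j}\, w_j}
#' where \eqn{\Delta r_j} is particle j's position and
#' \eqn{w_j = \sqrt{I(x_j, y_j) / I_{ref}}} weights each particle by the
#' illumination at its transverse position relative to the reference
#' (on-axis) fluence.
#'
#' @param patterns List of `fxi_amplitude` objects sharing one `fxi_qmap`.
#' @param positions List (or n x 3 matrix) of particle positions, m.
#' @param src Optional `fxi_source` for illumination weighting; `NULL`
#'   gives every particle unit weight.
#' @param pulse_energy Optional per-shot pulse energy override, J.
#' @return An `fxi_amplitude`.
#' @export
superpose <- function(patterns, positions = NULL, src = NULL,
                      pulse_energy = NULL) {
  stopifnot(length(patterns) >= 1,
            all(vapply(patterns, inherits, logical(1), "fxi_amplitude")))
  qmap <- patterns[[1]]$qmap
  for (p in patterns) {
    if (!isTRUE(all.equal(p$qmap$q, qmap$q))) {
      stop("all patterns must share the same q map")
    }
  }
  if (is.null(positions)) {
    positions <- matrix(0, nrow = length(patterns), ncol = 3)
  }
  if (is.list(positions)) positions <- do.call(rbind, positions)
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 3)
  stopifnot(nrow(positions) == length(patterns))
  if (!is.null(src)) {
    if (is.null(pulse_energy)) pulse_energy <- src$pulse_energy
    iref <- fluence_at(src, c(0, 0), pulse_energy)
    wgt <- sqrt(fluence_at(src, positions[, 1:2, drop = FALSE],
                           pulse_energy) / iref)
  } else {
    wgt <- rep(1, length(patterns))
  }
  F <- complex(length.out = nrow(qmap$q))
  for (j in seq_along(patterns)) {
    phase <- exp(-1i * drop(qmap$q %*% positions[j, ]))
    F <- F + patterns[[j]]$F * phase * wgt[j]
  }
  .amplitude_pattern(F, qmap,
                     sprintf("superposition of %d", length(patterns)))
}

#' Intensity |F|^2 of an amplitude pattern as a matrix
#'
#' @param amp An `fxi_amplitude`.
#' @return `ny` x `nx` numeric matrix of \eqn{|F|^2} (m^2).
#' @export
amplitude_intensity_matrix <- function(amp) {
  stopifnot(inherits(amp, "fxi_amplitude"))
  matrix(Mod(amp$F)^2, nrow = amp$qmap$ny, ncol = amp$qmap$nx, byrow = TRUE)
}
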