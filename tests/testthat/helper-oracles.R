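## Shared independent oracles and small utilities for the test suite.
## Everything here is deliberately written in the most literal way possible
## so it can serve as a reference against the package's optimized paths.

## normalized root-mean-square error between two numeric/complex vectors,
## relative to the RMS of the reference
nrmse <- function(x, ref) {
  sqrt(mean(Mod(x - ref)^2)) / sqrt(mean(Mod(ref)^2))
}

## rotation matrix about an arbitrary axis (Rodrigues formula), written
## independently of the package's quaternion path
axis_rot <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## the icosahedral rotation group (60 proper rotations) for the icosahedron
## with vertices at cyclic permutations of (0, +-1, +-phi): generated by a
## 2*pi/5 rotation about a vertex axis and a pi rotation about z, closed
## under multiplication by breadth-first search
icosa_rotation_group <- function() {
  phi <- (1 + sqrt(5)) / 2
  g1 <- axis_rot(c(0, 1, phi), 2 * pi / 5)
  g2 <- axis_rot(c(0, 0, 1), pi)
  key <- function(m) paste(round(m, 8), collapse = ",")
  seen <- new.env(parent = emptyenv())
  queue <- list(diag(3))
  assign(key(diag(3)), diag(3), envir = seen)
  while (length(queue) > 0) {
    m <- queue[[1]]; queue <- queue[-1]
    for (g in list(g1, g2)) {
      nm <- g %*% m
      k <- key(nm)
      if (!exists(k, envir = seen)) {
        assign(k, nm, envir = seen)
        queue <- c(queue, list(nm))
      }
    }
  }
  as.list(seen)
}

## analytic sphere form factor shape 3[sin(u) - u cos(u)]/u^3, written
## directly (no Taylor switch; oracle use only at moderate u)
sphere_shape_oracle <- function(u) 3 * (sin(u) - u * cos(u)) / u^3

## a deterministic qmap on a radial line lying exactly on the Ewald sphere:
## transverse magnitude qt along x, qz = k(cos(theta') - 1)
radial_qline <- function(qt, wavelength) {
  k <- 2 * pi / wavelength
  qmap_manual(cbind(qt, 0, k * (sqrt(pmax(1 - (qt / k)^2, 0)) - 1)),
              wavelength)
}
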