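## The four particle models and the per-shot stochastic ensemble.

#' Uniform sphere particle
#'
#' @param diameter Sphere diameter in m.
#' @param material An `fxi_material`, built-in material name, or an
#'   `fxi_refractive_index` giving the medium directly.
#' @return Object of classes `fxi_sphere`, `fxi_particle`.
#' @export
#' @examples
#' particle_sphere(1e-8, "water")
particle_sphere <- function(diameter, material = "water") {
  stopifnot(diameter > 0)
  if (!inherits(material, "fxi_refractive_index")) {
    material <- .resolve_material(material)
  }
  structure(list(diameter = diameter, material = material),
            class = c("fxi_sphere", "fxi_particle"))
}

#' Uniform spheroid particle
#'
#' The spheroid is parameterised by the diameter of the equal-volume sphere
#' and a flattening ratio `c/a` of the symmetry semi-axis `c` over the
#' equatorial semi-axis `a`; the volume is preserved at every flattening.
#'
#' @param diameter Diameter of the equal-volume sphere, m.
#' @param flattening Ratio c/a (> 0); 1 is a sphere, < 1 oblate, > 1 prolate.
#' @param material As in [particle_sphere()].
#' @param orientation An `fxi_rotation` for the symmetry axis (which is the
#'   lab z axis in the unrotated frame).
#' @return Object of classes `fxi_spheroid`, `fxi_particle`.
#' @export
particle_spheroid <- function(diameter, flattening = 1, material = "water",
                              orientation = rotation_identity()) {
  stopifnot(diameter > 0, flattening > 0)
  if (!inherits(material, "fxi_refractive_index")) {
    material <- .resolve_material(material)
  }
  structure(list(diameter = diameter, flattening = flattening,
                 material = material, orientation = orientation),
            class = c("fxi_spheroid", "fxi_particle"))
}

#' Semi-axes of a spheroid
#'
#' Returns `(a, a, c)` with `c/a = flattening` and
#' \eqn{(4/3)\pi a^2 c = (4/3)\pi (d/2)^3} (volume-preserving).
#'
#' @param p An `fxi_spheroid`.
#' @return Numeric length-3 `(a, a, c)` in m.
#' @export
spheroid_semiaxes <- function(p) {
  stopifnot(inherits(p, "fxi_spheroid"))
  r <- p$diameter / 2
  a <- r * p$flattening^(-1 / 3)
  c_ <- r * p$flattening^(2 / 3)
  c(a, a, c_)
}

#' Voxelized particle map
#'
#' A sample described on a cubic Cartesian grid. Voxel values can be
#' complex refractive indices, electron densities (1/m^3), or atom number
#' densities (1/m^3, split among the material's species by their relative
#' abundances).
#'
#' @param values Cubic 3-D numeric or complex array (n x n x n).
#' @param dx Voxel spacing in m.
#' @param kind `"refractive_index"`, `"electron_density"` or
#'   `"atom_density"`.
#' @param material Required for `kind = "atom_density"`: the medium whose
#'   composition distributes the atom density over species.
#' @param orientation An `fxi_rotation`.
#' @return Object of classes `fxi_map`, `fxi_particle`.
#' @export
particle_map <- function(values, dx,
                         kind = c("refractive_index", "electron_density",
                                  "atom_density"),
                         material = NULL,
                         orientation = rotation_identity()) {
  kind <- match.arg(kind)
  d <- dim(values)
  if (length(d) != 3 || length(unique(d)) != 1) {
    stop("map values must be a cubic n x n x n array")
  }
  stopifnot(dx > 0)
  if (kind == "atom_density") {
    if (is.null(material)) stop("atom_density maps need a material")
    material <- .resolve_material(material)
  }
  if (kind == "electron_density" && any(Re(values) < 0)) {
    stop("electron densities must be non-negative")
  }
  structure(list(values = values, dx = dx, kind = kind,
                 material = material, orientation = orientation),
            class = c("fxi_map", "fxi_particle"))
}

## convert map voxel values to the complemented refractive index
## nbar = 1 - n = delta + i*beta at the given wavelength
map_nbar <- function(p, wavelength) {
  stopifnot(inherits(p, "fxi_map"))
  switch(p$kind,
    refractive_index = 1 - p$values,
    electron_density =
      .const$r0 * wavelength^2 * Re(p$values) / (2 * pi) + 0i,
    atom_density = {
      E <- energy_from_wavelength(wavelength)
      w <- p$material$composition / sum(p$material$composition)
      f <- vapply(names(w), function(sym)
        atomic_scattering_factor(sym, E), complex(1))
      fbar <- sum(w * f)  # mean scattering factor per atom
      .const$r0 * wavelength^2 / (2 * pi) * p$values * fbar
    })
}

#' Atomic-coordinate particle
#'
#' @param positions n x 3 matrix of atom positions in m.
#' @param elements Length-n vector of atomic numbers or element symbols.
#' @param orientation An `fxi_rotation`.
#' @return Object of classes `fxi_atoms`, `fxi_particle`.
#' @export
particle_atoms <- function(positions, elements,
                           orientation = rotation_identity()) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 3)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  z <- if (is.character(elements)) element_number(elements) else as.integer(elements)
  if (length(z) != nrow(positions)) {
    stop("positions and elements must have equal length")
  }
  structure(list(positions = unname(positions), elements = z,
                 orientation = orientation),
            class = c("fxi_atoms", "fxi_particle"))
}

#' @export
print.fxi_particle <- function(x, ...) {
  desc <- switch(class(x)[1],
    fxi_sphere   = sprintf("sphere d = %.3g nm", x$diameter * 1e9),
    fxi_spheroid = sprintf("spheroid d = %.3g nm, c/a = %.3g",
                           x$diameter * 1e9, x$flattening),
    fxi_map      = sprintf("map %d^3 voxels, dx = %.3g nm (%s)",
                           dim(x$values)[1], x$dx * 1e9, x$kind),
    fxi_atoms    = sprintf("%d atoms", length(x$elements)))
  cat("<fxi_particle> ", desc, "\n", sep = "")
  invisible(x)
}

## ---- geometric voxelization ------------------------------------------------

## fractional sub-voxel coverage of a signed distance d (positive inside),
## linear ramp of one voxel width
.edge_coverage <- function(d, dx) pmin(1, pmax(0, 0.5 + d / dx))

## vertices of a regular icosahedron (edge length 2): (0, +-1, +-phi) cyclic
.icosa_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    cbind(0, c(-1, -1, 1, 1), c(-phi, phi, -phi, phi)),
    cbind(c(-1, -1, 1, 1), c(-phi, phi, -phi, phi), 0),
    cbind(c(-phi, phi, -phi, phi), 0, c(-1, -1, 1, 1)))
  unname(v)
}

## unit face normals of the regular icosahedron, derived from its vertex
## set: each face is a triangle of mutually adjacent (distance-2) vertices
.icosa_face_normals <- function() {
  v <- .icosa_vertices()
  d <- as.matrix(stats::dist(v))
  adj <- abs(d - 2) < 1e-9
  normals <- list()
  nv <- nrow(v)
  for (i in 1:(nv - 2)) for (j in (i + 1):(nv - 1)) for (k in (j + 1):nv) {
    if (adj[i, j] && adj[j, k] && adj[i, k]) {
      ctr <- colSums(v[c(i, j, k), ]) / 3
      normals[[length(normals) + 1]] <- ctr / sqrt(sum(ctr^2))
    }
  }
  do.call(rbind, normals)
}

#' Voxelize a geometric shape into a particle map
#'
#' Builds an atom-density map of a uniformly filled sphere, spheroid or
#' regular icosahedron of the given material. Sizes are specified by the
#' diameter of the equal-volume sphere, so all three shapes of the same
#' `diameter` enclose the same volume. Surface voxels get fractional
#' occupancy from the local signed distance to the surface (a one-voxel
#' linear ramp), which suppresses hard-edge ringing in the discrete Fourier
#' transform; set `antialias = FALSE` for a binary map.
#'
#' @param shape `"sphere"`, `"spheroid"` or `"icosahedron"`.
#' @param diameter Equal-volume-sphere diameter, m.
#' @param dx Voxel spacing, m; must resolve the shape (>= 8 voxels across).
#' @param material Medium filling the shape.
#' @param flattening For `"spheroid"`: ratio c/a.
#' @param orientation An `fxi_rotation` applied to the shape before
#'   voxelization (the grid itself is axis-aligned).
#' @param antialias Fractional edge coverage (default) vs hard 0/1 edges.
#' @param pad Number of empty voxels padded on each side.
#' @return An `fxi_map` particle of kind `"atom_density"`.
#' @export
#' @examples
#' m <- map_from_geometry("sphere", 3.2e-8, 1e-9, "water")
map_from_geometry <- function(shape = c("sphere", "spheroid", "icosahedron"),
                              diameter, dx, material = "water",
                              flattening = 1,
                              orientation = rotation_identity(),
                              antialias = TRUE, pad = 2) {
  shape <- match.arg(shape)
  stopifnot(diameter > 0, dx > 0, flattening > 0)
  if (diameter / dx < 8) {
    stop("grid too coarse: need at least 8 voxels across the shape")
  }
  material <- .resolve_material(material)
  r <- diameter / 2
  ## grid large enough for the rotated shape: max extent is the
  ## circumradius of the shape
  rmax <- switch(shape,
    sphere = r,
    spheroid = r * max(flattening^(-1 / 3), flattening^(2 / 3)),
    icosahedron = {
      a_edge <- (pi * diameter^3 / 6 / ((5 / 12) * (3 + sqrt(5))))^(1 / 3)
      a_edge / 4 * sqrt(10 + 2 * sqrt(5))  # circumradius
    })
  n <- 2 * ceiling(rmax / dx) + 1 + 2 * pad
  idx <- seq_len(n) - (n + 1) / 2
  x <- idx * dx
  g <- expand.grid(x = x, y = x, z = x)
  pts <- as.matrix(g)
  ## rotate grid points back instead of rotating the shape forward
  pts <- apply_rotation(rotation_inverse(orientation), pts)
  d_signed <- switch(shape,
    sphere = r - sqrt(rowSums(pts^2)),
    spheroid = {
      ax <- r * flattening^(-1 / 3); cz <- r * flattening^(2 / 3)
      u <- sqrt((pts[, 1] / ax)^2 + (pts[, 2] / ax)^2 + (pts[, 3] / cz)^2)
      grad <- sqrt((pts[, 1] / ax^2)^2 + (pts[, 2] / ax^2)^2 +
                     (pts[, 3] / cz^2)^2)
      ifelse(u > 0, (1 - u) / pmax(grad / pmax(u, 1e-300), 1e-300), ax)
    },
    icosahedron = {
      a_edge <- (pi * diameter^3 / 6 / ((5 / 12) * (3 + sqrt(5))))^(1 / 3)
      r_in <- a_edge * sqrt(3) / 12 * (3 + sqrt(5))
      nm <- .icosa_face_normals()
      r_in - apply(pts %*% t(nm), 1, max)
    })
  occ <- if (antialias) .edge_coverage(d_signed, dx) else as.numeric(d_signed >= 0)
  values <- array(occ, dim = c(n, n, n))
  ## total atom number density of the material
  rho_atoms <- sum(.atom_densities(material))
  particle_map(values * rho_atoms, dx, kind = "atom_density",
               material = material, orientation = rotation_identity())
}

## ---- stochastic per-shot ensemble ------------------------------------------

#' Particle species for stochastic shots
#'
#' Describes how instances of a template particle arrive in the beam:
#' Poisson arrival numbers, size and shape jitter, and position and
#' orientation distributions.
#'
#' @param template An `fxi_particle` used as the prototype.
#' @param arrival_rate Expected particles per shot (Poisson mean); ignored
#'   when `count` is given.
#' @param count Fixed (deterministic) number of instances per shot;
#'   `NULL` (default) for Poisson arrivals.
#' @param diameter_sigma Normal jitter of the diameter, m (spheres and
#'   spheroids only; draws are resampled until positive).
#' @param flattening_range Length-2 range for uniform flattening draws
#'   (spheroids only); `NULL` keeps the template's value.
#' @param position `"fixed"`, `"uniform-in-focus"` or `"normal"`.
#' @param position_value Fixed transverse position (m, length 2) for
#'   `position = "fixed"`.
#' @param position_sigma Std. dev. (m) for `position = "normal"`.
#' @param orientation `"fixed"` (template's) or `"uniform-random"`.
#' @param label Species label recorded in the ground truth.
#' @return Object of class `fxi_species`.
#' @export
#' @examples
#' species_spec(particle_sphere(8e-9, "water"), arrival_rate = 0.2,
#'              orientation = "uniform-random")
species_spec <- function(template, arrival_rate = 1, count = NULL,
                         diameter_sigma = 0, flattening_range = NULL,
                         position = c("fixed", "uniform-in-focus", "normal"),
                         position_value = c(0, 0), position_sigma = 0,
                         orientation = c("fixed", "uniform-random"),
                         label = class(template)[1]) {
  stopifnot(inherits(template, "fxi_particle"),
            arrival_rate >= 0, diameter_sigma >= 0)
  position <- match.arg(position)
  orientation <- match.arg(orientation)
  if (!is.null(flattening_range)) {
    stopifnot(length(flattening_range) == 2, all(flattening_range > 0),
              flattening_range[1] <= flattening_range[2])
  }
  if (!is.null(count)) stopifnot(count >= 0, count == round(count))
  structure(list(template = template, arrival_rate = arrival_rate,
                 count = count, diameter_sigma = diameter_sigma,
                 flattening_range = flattening_range,
                 position = position, position_value = position_value,
                 position_sigma = position_sigma,
                 orientation = orientation, label = label),
            class = "fxi_species")
}

.sample_truncated_normal <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
}

## uniform point in a disc of the given diameter
.sample_disc <- function(diameter) {
  r <- diameter / 2 * sqrt(stats::runif(1))
  a <- stats::runif(1, 0, 2 * pi)
  c(r * cos(a), r * sin(a))
}

#' Sample the particle ensemble of one shot
#'
#' Draws, for each species, a Poisson-distributed (or fixed) number of
#' particle instances with independently sampled sizes, flattenings,
#' positions and orientations. Orientations are uniform over SO(3)
#' (normalised 4-D Gaussian quaternions).
#'
#' @param species A single `fxi_species` or a list of them.
#' @param rng_seed Optional integer seed for reproducibility.
#' @param focus_diameter Focus diameter (m) used by the
#'   `"uniform-in-focus"` position distribution.
#' @return List of particle instances; each instance is a list with fields
#'   `particle` (all randomness resolved), `position` (3-vector, m) and
#'   `label`.
#' @export
sample_shot_ensemble <- function(species, rng_seed = NULL,
                                 focus_diameter = 1e-6) {
  if (inherits(species, "fxi_species")) species <- list(species)
  stopifnot(all(vapply(species, inherits, logical(1), "fxi_species")))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  out <- list()
  for (sp in species) {
    n <- if (!is.null(sp$count)) sp$count else stats::rpois(1, sp$arrival_rate)
    for (i in seq_len(n)) {
      p <- sp$template
      if (inherits(p, c("fxi_sphere", "fxi_spheroid")) && sp$diameter_sigma > 0) {
        p$diameter <- .sample_truncated_normal(p$diameter, sp$diameter_sigma)
      }
      if (inherits(p, "fxi_spheroid") && !is.null(sp$flattening_range)) {
        p$flattening <- stats::runif(1, sp$flattening_range[1],
                                     sp$flattening_range[2])
      }
      if (sp$orientation == "uniform-random" && !inherits(p, "fxi_sphere")) {
        p$orientation <- random_rotation(1)
      }
      pos <- switch(sp$position,
        fixed = c(sp$position_value, 0),
        `uniform-in-focus` = c(.sample_disc(focus_diameter), 0),
        normal = c(stats::rnorm(2, 0, sp$position_sigma), 0))
      out[[length(out) + 1]] <- structure(
        list(particle = p, position = pos, label = sp$label),
        class = "fxi_particle_instance")
    }
  }
  out
}
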