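## Element scattering factors, optical media, and the conversions between
## electron density, atom density and complex refractive index.

## cache for parsed scattering-factor tables, filled lazily
.scatfact_env <- new.env(parent = emptyenv())

.scatfact_table <- function(z) {
  key <- as.character(z)
  if (!is.null(.scatfact_env[[key]])) return(.scatfact_env[[key]])
  sym <- tolower(element_symbol(z))
  path <- system.file("extdata", "scatfact", paste0(sym, ".nff"),
                      package = "fxisim")
  if (!nzchar(path) || !file.exists(path)) {
    stop("no scattering-factor table bundled for element ", element_symbol(z),
         " (Z = ", z, ")")
  }
  tab <- utils::read.table(path, header = FALSE, skip = 2,
                           col.names = c("energy", "f1", "f2"))
  stopifnot(all(diff(tab$energy) > 0), all(is.finite(tab$f1)),
            all(is.finite(tab$f2)))
  .scatfact_env[[key]] <- tab
  tab
}

#' Photon wavelength from photon energy
#'
#' Converts photon energy in electronvolts to wavelength in metres via
#' \eqn{\lambda = hc/E}.
#'
#' @param photon_energy Photon energy in eV (positive).
#' @return Wavelength in m.
#' @seealso [energy_from_wavelength()]
#' @export
#' @examples
#' wavelength_from_energy(1000)  # ~1.24 nm
wavelength_from_energy <- function(photon_energy) {
  if (any(!is.finite(photon_energy)) || any(photon_energy <= 0)) {
    stop("photon_energy must be positive and finite")
  }
  .const$h * .const$c / (photon_energy * .const$e)
}

#' Photon energy from wavelength
#'
#' Inverse of [wavelength_from_energy()]: \eqn{E = hc/\lambda} in eV.
#'
#' @param wavelength Wavelength in m (positive).
#' @return Photon energy in eV.
#' @export
energy_from_wavelength <- function(wavelength) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    stop("wavelength must be positive and finite")
  }
  .const$h * .const$c / (wavelength * .const$e)
}

#' Complex atomic scattering factor
#'
#' Returns the forward-scattering atomic scattering factor
#' \eqn{f = f_1 + i f_2} of an element at a photon energy, linearly
#' interpolated in energy from the bundled tables (computed from
#' Cromer-Liberman anomalous-dispersion theory with \eqn{f_1 = Z + f'}).
#' The same value is used at all scattering angles; this forward-scattering
#' approximation is valid when the resolution of the measurement is well
#' below atomic length scales, which holds for the nanometre-scale targets
#' this simulator addresses.
#'
#' @param element Atomic number Z or element symbol.
#' @param photon_energy Photon energy in eV; must lie inside the tabulated
#'   range (no extrapolation is ever performed).
#' @return Complex scattering factor (vectorised over `photon_energy`).
#' @export
#' @examples
#' atomic_scattering_factor("C", 1000)
atomic_scattering_factor <- function(element, photon_energy) {
  z <- if (is.character(element)) element_number(element) else as.integer(element)
  tab <- .scatfact_table(z)
  rng <- range(tab$energy)
  if (any(photon_energy < rng[1] | photon_energy > rng[2])) {
    stop(sprintf("photon energy outside tabulated range [%.0f, %.0f] eV for Z = %d",
                 rng[1], rng[2], z))
  }
  f1 <- stats::approx(tab$energy, tab$f1, xout = photon_energy)$y
  f2 <- stats::approx(tab$energy, tab$f2, xout = photon_energy)$y
  complex(real = f1, imaginary = f2)
}

#' Define an optical medium
#'
#' A material is a mass density plus a relative stoichiometric composition.
#' Abundances are relative weights, not counts: `{H: 2, O: 1}` and
#' `{H: 4, O: 2}` describe the same medium.
#'
#' @param name Material name.
#' @param mass_density Mass density in kg/m^3 (positive).
#' @param composition Named numeric vector mapping element symbols to
#'   relative abundances (all >= 0, at least one > 0).
#' @return Object of class `fxi_material`.
#' @export
#' @examples
#' material("water", 1000, c(H = 2, O = 1))
material <- function(name, mass_density, composition) {
  stopifnot(is.numeric(mass_density), length(mass_density) == 1,
            is.finite(mass_density), mass_density > 0)
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named vector of element abundances")
  }
  if (any(composition < 0) || all(composition == 0)) {
    stop("abundances must be >= 0 with at least one > 0")
  }
  element_number(names(composition))  # validates symbols
  structure(list(name = as.character(name),
                 mass_density = mass_density,
                 composition = composition[composition > 0]),
            class = "fxi_material")
}

#' @export
print.fxi_material <- function(x, ...) {
  cat(sprintf("<fxi_material> %s, %.3g g/cm^3, composition: %s\n",
              x$name, x$mass_density / 1000,
              paste(sprintf("%s:%g", names(x$composition), x$composition),
                    collapse = " ")))
  invisible(x)
}

#' Built-in optical media
#'
#' A selection of media commonly used to model FXI samples: water, protein,
#' DNA, lipid, a generic cell, and a virus-like particle. Mass densities are
#' literature values for the bulk media; atomic compositions are the
#' stoichiometries in common use for X-ray optical modelling of biological
#' matter. They are starting points, not hard truths — construct your own
#' [material()] to override.
#'
#' @return Named list of `fxi_material` objects.
#' @export
#' @examples
#' builtin_materials()$protein
builtin_materials <- function() {
  list(
    water   = material("water",   1000, c(H = 2, O = 1)),
    protein = material("protein", 1350, c(H = 86, C = 52, N = 13, O = 22, S = 3)),
    dna     = material("dna",     1700, c(H = 11, C = 10, N = 4, O = 6, P = 1)),
    lipid   = material("lipid",   1000, c(H = 69, C = 36, O = 6)),
    cell    = material("cell",    1000, c(H = 23, C = 3, N = 1, O = 10,
                                          P = 0.39, S = 0.03)),
    virus   = material("virus",   1340, c(H = 72.43, C = 47.52, N = 13.55,
                                          O = 17.17, P = 1.11, S = 0.7))
  )
}

.resolve_material <- function(m) {
  if (inherits(m, "fxi_material")) return(m)
  if (is.character(m) && length(m) == 1) {
    mats <- builtin_materials()
    if (!m %in% names(mats)) {
      stop("unknown built-in material '", m, "'; available: ",
           paste(names(mats), collapse = ", "))
    }
    return(mats[[m]])
  }
  stop("material must be an fxi_material or the name of a built-in one")
}

## number density of each atomic species, 1/m^3
.atom_densities <- function(mat) {
  z <- element_number(names(mat$composition))
  A <- .atomic_weight_of_z(z)                      # g/mol
  w <- mat$composition
  molar_mass <- sum(w * A)                         # g per "formula unit" mole
  if (molar_mass <= 0) stop("material has zero molar mass")
  ## formula units per m^3: density [g/m^3] / molar mass * N_A
  n_formula <- mat$mass_density * 1000 / molar_mass * .const$N_A
  stats::setNames(n_formula * w, names(w))
}

#' Electron density of a material
#'
#' \eqn{\rho_e = \rho_m N_A (\sum_i w_i Z_i) / (\sum_i w_i A_i)} with
#' stoichiometric weights \eqn{w_i}.
#'
#' @param mat An `fxi_material` or built-in material name.
#' @return Electron number density in 1/m^3.
#' @export
#' @examples
#' electron_density("water")  # ~3.34e29
electron_density <- function(mat) {
  mat <- .resolve_material(mat)
  rho_a <- .atom_densities(mat)
  z <- element_number(names(rho_a))
  sum(rho_a * z)
}

.refractive_index <- function(n) {
  delta <- 1 - Re(n)
  beta <- -Im(n)
  if (abs(1 - n) >= 1e-2) {
    stop("refractive index violates the X-ray sanity bound |1 - n| < 1e-2")
  }
  if (beta < 0) stop("negative absorption index beta")
  structure(list(n = n, delta = delta, beta = beta),
            class = "fxi_refractive_index")
}

#' @export
print.fxi_refractive_index <- function(x, ...) {
  cat(sprintf("<fxi_refractive_index> n = 1 - %.4e - %.4ei (delta, beta)\n",
              x$delta, x$beta))
  invisible(x)
}

#' Refractive index from atomic composition
#'
#' Computes the complex X-ray refractive index of a material from its
#' per-species atom densities and complex scattering factors:
#' \deqn{n = 1 - \frac{r_0 \lambda^2}{2\pi} \sum_a \rho_a f_a(\lambda)}
#' with \eqn{r_0} the Thomson scattering length and \eqn{\rho_a} the number
#' density of species \eqn{a}. With the sign convention
#' \eqn{n = 1 - \delta - i\beta}, absorption gives \eqn{\beta \ge 0}.
#'
#' @param mat An `fxi_material` or built-in material name.
#' @param photon_energy Photon energy in eV.
#' @return Object of class `fxi_refractive_index` with fields `n` (complex),
#'   `delta` (\eqn{1 - \mathrm{Re}\,n}) and `beta` (\eqn{-\mathrm{Im}\,n}).
#' @export
#' @examples
#' refractive_index_from_atom_density("water", 1000)
refractive_index_from_atom_density <- function(mat, photon_energy) {
  mat <- .resolve_material(mat)
  lambda <- wavelength_from_energy(photon_energy)
  rho_a <- .atom_densities(mat)
  f <- vapply(names(rho_a), function(sym)
    atomic_scattering_factor(sym, photon_energy), complex(1))
  nbar <- .const$r0 * lambda^2 / (2 * pi) * sum(rho_a * f)
  .refractive_index(1 - nbar)
}

#' Refractive index from electron density
#'
#' \eqn{\mathrm{Re}(n) = 1 - r_0 \lambda^2 \rho_e / (2\pi)}. An electron
#' density carries no absorption information, so \eqn{\beta = 0}; this is
#' the high-energy limit \eqn{f \to Z} of
#' [refractive_index_from_atom_density()].
#'
#' @param rho_e Electron number density in 1/m^3 (non-negative).
#' @param wavelength Wavelength in m.
#' @return Object of class `fxi_refractive_index`.
#' @export
refractive_index_from_electron_density <- function(rho_e, wavelength) {
  if (any(rho_e < 0)) stop("electron density must be non-negative")
  delta <- .const$r0 * wavelength^2 * rho_e / (2 * pi)
  .refractive_index(complex(real = 1 - delta, imaginary = 0))
}

## complemented refractive index nbar = 1 - n = delta + i*beta,
## the quantity the map amplitudes are weighted by
.nbar <- function(mat_or_ri, photon_energy = NULL) {
  if (inherits(mat_or_ri, "fxi_refractive_index")) return(1 - mat_or_ri$n)
  ri <- refractive_index_from_atom_density(mat_or_ri, photon_energy)
  1 - ri$n
}
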