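test_that("energy/wavelength conversion round-trips and matches hc/E", {
  cst <- fxi_constants()
  ## [DERIVED] lambda = h*c/E with CODATA constants at 1000 eV
  expect_equal(wavelength_from_energy(1000),
               cst$h * cst$c / (1000 * cst$e), tolerance = 1e-12)
  ## [TRIVIAL] round trip
  expect_equal(energy_from_wavelength(wavelength_from_energy(8000)), 8000,
               tolerance = 1e-12)
  ## [DERIVED] hc/e = 1239.84 eV nm, so ~1.24 nm at 1 keV
  expect_equal(wavelength_from_energy(1000) / 1e-9, 1.2398, tolerance = 1e-4)
  expect_error(wavelength_from_energy(-5), "positive")
})

test_that("element symbol/number lookup is consistent", {
  expect_identical(element_number("Fe"), 26L)
  expect_identical(element_symbol(26L), "Fe")
  expect_identical(element_number("H"), 1L)
  expect_error(element_number("Xx"), "unknown element")
})

test_that("scattering factors interpolate the bundled tables", {
  tab <- read.table(system.file("extdata/scatfact/c.nff", package = "fxisim"),
                    skip = 2, col.names = c("E", "f1", "f2"))
  i <- 70
  emid <- sqrt(tab$E[i] * tab$E[i + 1]) # between two grid points
  f <- atomic_scattering_factor("C", emid)
  ## [DERIVED] manual linear interpolation on the same table
  w <- (emid - tab$E[i]) / (tab$E[i + 1] - tab$E[i])
  expect_equal(Re(f), (1 - w) * tab$f1[i] + w * tab$f1[i + 1],
               tolerance = 1e-12)
  expect_equal(Im(f), (1 - w) * tab$f2[i] + w * tab$f2[i + 1],
               tolerance = 1e-12)
  ## on-grid energies reproduce table rows
  expect_equal(Re(atomic_scattering_factor("C", tab$E[i])), tab$f1[i])
  ## no extrapolation, ever
  expect_error(atomic_scattering_factor("C", 10), "outside")
  expect_error(atomic_scattering_factor("C", 1e6), "outside")
})

test_that("hydrogen scattering factor is exactly 1 + 0i", {
  for (E in c(300, 1200, 8000, 24000)) {
    expect_equal(atomic_scattering_factor("H", E), complex(real = 1))
  }
})

test_that("f1 tends to Z at high energy", {
  for (el in c("C", "N", "O", "S")) {
    f <- atomic_scattering_factor(el, 29000)
    expect_equal(Re(f), element_number(el), tolerance = 2e-2)
    expect_gte(Im(f), 0)
  }
})

test_that("materials resolve and validate", {
  m <- material("h2o", 1000, c(H = 2, O = 1))
  expect_s3_class(m, "fxi_material")
  expect_equal(m$composition[["H"]] / m$composition[["O"]], 2)
  w <- builtin_materials()$water
  expect_equal(w$mass_density, 1000)
  expect_identical(fxisim:::.resolve_material("water")$composition,
                   w$composition)
  expect_error(material("bad", -1, c(H = 1)))
  expect_error(material("bad", 1000, c(H = -1)))
  expect_error(fxisim:::.resolve_material("adamantium"), "unknown built-in")
})

test_that("atom and electron densities follow from the mass density", {
  ## [DERIVED] water: n_H2O = rho * N_A / M, M = 2*1.008 + 15.999 g/mol
  cst <- fxi_constants()
  M <- 2 * 1.008 + 15.999                       # g/mol
  n_mol <- 1000 * 1000 / M * cst$N_A            # formula units / m^3
  d <- fxisim:::.atom_densities(builtin_materials()$water)
  expect_equal(d[["O"]], n_mol, tolerance = 1e-12)
  expect_equal(d[["H"]], 2 * n_mol, tolerance = 1e-12)
  expect_equal(electron_density("water"), 10 * n_mol, tolerance = 1e-12)
})

test_that("refractive index matches a hand-written sum over species", {
  ## [DERIVED] n = 1 - (r0 lambda^2 / 2 pi) sum_a rho_a f_a
  cst <- fxi_constants()
  E <- 1200
  lam <- wavelength_from_energy(E)
  d <- fxisim:::.atom_densities(builtin_materials()$water)
  s <- sum(vapply(names(d), function(el)
    d[[el]] * atomic_scattering_factor(el, E), complex(1)))
  n_hand <- 1 - cst$r0 * lam^2 / (2 * pi) * s
  ri <- refractive_index_from_atom_density("water", E)
  expect_equal(ri$n, n_hand, tolerance = 1e-14)
  expect_equal(ri$delta, 1 - Re(n_hand), tolerance = 1e-12)
  expect_equal(ri$beta, -Im(n_hand), tolerance = 1e-12)
  ## physical regime: small positive delta, non-negative beta
  expect_gt(ri$delta, 0); expect_gte(ri$beta, 0)
  expect_lt(Mod(1 - ri$n), 1e-2)
})

test_that("electron-density route equals the atomic route when f -> Z", {
  ## with f_a replaced by Z_a the two formulations are algebraically equal
  cst <- fxi_constants()
  rho_e <- electron_density("protein")
  lam <- wavelength_from_energy(5000)
  ri <- refractive_index_from_electron_density(rho_e, lam)
  ## delta ~ 1e-5 is recovered from 1 - Re(n), which costs ~1e-11 relative
  expect_equal(ri$delta, cst$r0 * lam^2 * rho_e / (2 * pi), tolerance = 1e-9)
  expect_identical(ri$beta, 0)
  expect_error(refractive_index_from_electron_density(-1, lam),
               "non-negative")
})
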