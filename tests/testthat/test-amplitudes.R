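## shared small scene for this file
small_qmap <- function() {
  qmap_from_detector(detector_geometry(7, 6, 4e-3, 0.3), 1.2398e-9)
}

test_that("fast NUDFT equals the literal brute-force loop", {
  set.seed(21)
  qm <- small_qmap()
  pts <- matrix(rnorm(45, sd = 4e-9), 15, 3)
  w <- complex(real = rnorm(15), imaginary = rnorm(15))
  fast <- fxisim:::.nudft(pts, w, qm$q)
  oracle <- brute_force_dft(pts, w, qm)$F
  expect_lt(nrmse(fast, oracle), 1e-12)
})

test_that("atomic amplitude is r0 * sum f_a exp(-i q r)", {
  qm <- small_qmap()
  E <- energy_from_wavelength(qm$wavelength)
  set.seed(8)
  pos <- matrix(rnorm(24, sd = 3e-9), 8, 3)
  el <- c("C", "C", "O", "N", "H", "S", "O", "C")
  p <- particle_atoms(pos, el)
  amp <- amplitude_atoms(p, qm, E)
  ## [DERIVED] independent evaluation via the brute-force oracle with
  ## per-atom weights f_a, scaled by r0
  f <- vapply(el, atomic_scattering_factor, complex(1),
              photon_energy = E)
  oracle <- fxi_constants()$r0 * brute_force_dft(pos, f, qm)$F
  expect_lt(nrmse(amp$F, oracle), 1e-12)
})

test_that("single H atom at the origin scatters exactly r0 everywhere", {
  ## Thomson scattering: f(H) = 1 identically in the bundled tables, and a
  ## point at the origin has no phase, so |F| = r0 at every pixel
  qm <- small_qmap()
  amp <- amplitude_atoms(particle_atoms(matrix(0, 1, 3), "H"), qm, 1000)
  expect_equal(amp$F, rep(complex(real = fxi_constants()$r0), nrow(qm$q)))
})

test_that("map amplitude equals a weighted brute-force sum over voxels", {
  qm <- small_qmap()
  lam <- qm$wavelength
  n <- 5; dx <- 2e-9
  set.seed(12)
  vals <- array(complex(real = 1 - runif(n^3) * 1e-5,
                        imaginary = -runif(n^3) * 1e-6), c(n, n, n))
  p <- particle_map(vals, dx)
  amp <- amplitude_map(p, qm, lam)
  ## [DERIVED] oracle: voxel centres and weights written out by hand
  idx <- (seq_len(n) - (n + 1) / 2) * dx
  g <- as.matrix(expand.grid(x = idx, y = idx, z = idx))
  k <- 2 * pi / lam
  w <- (k^2 / (2 * pi)) * dx^3 * as.vector(1 - vals)
  oracle <- brute_force_dft(g, w, qm)$F
  expect_lt(nrmse(amp$F, oracle), 1e-12)
})

test_that("coarse map grids raise the warning flag", {
  qm <- qmap_from_detector(detector_geometry(8, 8, 2e-2, 0.2), 1e-10)
  qmax <- sqrt(max(rowSums(qm$q^2)))
  p <- particle_map(array(1 - 1e-5 + 0i, c(8, 8, 8)), 2 * pi / qmax)
  amp <- amplitude_map(p, qm, 1e-10)
  expect_match(amp$warning_flag, "too coarse")
  p2 <- particle_map(array(1 - 1e-5 + 0i, c(8, 8, 8)), 0.1 * pi / qmax)
  expect_null(amplitude_map(p2, qm, 1e-10)$warning_flag)
})

test_that("analytic sphere has the documented forward limit and shape", {
  lam <- 1.2398e-9
  d <- 2e-8; R <- d / 2
  p <- particle_sphere(d, "water")
  qm <- radial_qline(c(0, 1e8, 3e8), lam)
  amp <- amplitude_sphere(p, qm, lam)
  k <- 2 * pi / lam
  nb <- 1 - refractive_index_from_atom_density(
    "water", energy_from_wavelength(lam))$n
  s_tot <- k^2 / (2 * pi) * nb * 4 / 3 * pi * R^3
  ## forward scattering is the total scattering length
  expect_equal(amp$F[1], s_tot, tolerance = 1e-12)
  ## [DERIVED] off-axis values match the hand-written shape factor
  qn <- sqrt(rowSums(qm$q^2))[-1]
  expect_equal(amp$F[-1], s_tot * sphere_shape_oracle(qn * R),
               tolerance = 1e-10)
  ## forward limit also equals r0 * (electron content) as f -> Z is
  ## approximate: check within 3% at 1 keV
  expect_equal(Re(amp$F[1]),
               fxi_constants()$r0 * electron_density("water") *
                 4 / 3 * pi * R^3,
               tolerance = 3e-2)
})

test_that("sphere shape factor is continuous across the Taylor switch", {
  u <- c(0, 1e-7, 0.9999e-4, 1.0001e-4, 1e-3, 0.1)
  s <- fxisim:::.sphere_shape_factor(u)
  expect_equal(s[1], 1)
  expect_equal(s[4], sphere_shape_oracle(1.0001e-4), tolerance = 1e-12)
  expect_equal(s[3], 1 - u[3]^2 / 10, tolerance = 1e-12)
  ## the exact branch cancels catastrophically near u ~ 1e-4, so the jump
  ## across the switch is bounded by that cancellation (~1e-8), not by the
  ## Taylor truncation (~1e-17)
  expect_lt(abs(s[4] - s[3]), 1e-6)
})

test_that("spheroid reduces to the sphere at flattening 1", {
  lam <- 1.2398e-9
  qm <- small_qmap()
  ps <- particle_sphere(1.6e-8, "protein")
  pe <- particle_spheroid(1.6e-8, 1, "protein",
                          orientation = random_rotation())
  set.seed(99)
  expect_equal(amplitude_spheroid(pe, qm, lam)$F,
               amplitude_sphere(ps, qm, lam)$F, tolerance = 1e-10)
})

test_that("spheroid amplitude matches its voxelized map", {
  lam <- wavelength_from_energy(1000)
  det <- detector_geometry(16, 16, 4e-3, 0.4)
  qm <- qmap_from_detector(det, lam)
  r <- rotation_from_euler(c(0.7, 0.3, -1.2), "zyz")
  p <- particle_spheroid(1.2e-8, 0.7, "water", orientation = r)
  pm <- map_from_geometry("spheroid", 1.2e-8, 1.2e-8 / 24, "water",
                          flattening = 0.7, orientation = r)
  fa <- amplitude_spheroid(p, qm, lam)$F
  fm <- amplitude_map(pm, qm, lam)$F
  expect_lt(nrmse(fm, fa), 0.01)
})

test_that("superposition applies phase ramps and illumination weights", {
  qm <- small_qmap()
  lam <- qm$wavelength
  p <- particle_sphere(1e-8, "water")
  a <- amplitude_sphere(p, qm, lam)
  dr <- c(3e-9, -2e-9, 1e-9)
  two <- superpose(list(a, a), list(c(0, 0, 0), dr))
  ## [DERIVED] F (1 + exp(-i q dr))
  expect_equal(two$F, a$F * (1 + exp(-1i * drop(qm$q %*% dr))),
               tolerance = 1e-12)
  ## Gaussian illumination: off-axis particle weighted by sqrt(I/I0)
  src <- photon_source(photon_energy = 1000, pulse_energy = 1e-3,
                       focus_diameter = 1e-6, profile = "gaussian")
  pos <- c(0.4e-6, 0, 0)
  one <- superpose(list(a), list(pos), src = src)
  wgt <- sqrt(fluence_at(src, pos[1:2]) / fluence_at(src, c(0, 0)))
  expect_equal(one$F, a$F * exp(-1i * drop(qm$q %*% pos)) * wgt,
               tolerance = 1e-12)
  expect_error(superpose(list(a, a), list(c(0, 0, 0))), "equal|positions")
})

test_that("intensity matrix lays pixels out with x fast", {
  qm <- small_qmap()
  a <- amplitude_sphere(particle_sphere(1e-8, "water"), qm, qm$wavelength)
  m <- amplitude_intensity_matrix(a)
  expect_identical(dim(m), c(6L, 7L))
  ## pixel (i=2, j=4) zero-based lives at flat index j*nx + i + 1
  expect_equal(m[5, 3], Mod(a$F[4 * 7 + 2 + 1])^2)
})
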