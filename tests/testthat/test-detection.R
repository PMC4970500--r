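test_that("pixel solid angle follows (s^2/D^2) cos^3", {
  det <- detector_geometry(9, 9, 3e-4, 0.2)
  om <- solid_angle(det)
  ## [DERIVED] hand computation for the corner pixel (0,0)
  p <- c((0 - 4) * 3e-4, (0 - 4) * 3e-4, 0.2)
  ct <- 0.2 / sqrt(sum(p^2))
  expect_equal(om[1], (3e-4)^2 / 0.2^2 * ct^3, tolerance = 1e-12)
  ## on-axis pixel has the plain s^2/D^2 value and is the maximum
  centre <- 4 * 9 + 4 + 1
  expect_equal(om[centre], (3e-4 / 0.2)^2, tolerance = 1e-12)
  expect_equal(max(om), om[centre])
})

test_that("polarization factors match their closed forms", {
  th <- c(0, 0.3, 1.2); ph <- c(0.2, 1.0, -2.5)
  expect_equal(polarization_factor(th, ph, "ignore"), rep(1, 3))
  expect_equal(polarization_factor(th, ph, "horizontal"),
               1 - sin(th)^2 * cos(ph)^2)
  expect_equal(polarization_factor(th, ph, "vertical"),
               1 - sin(th)^2 * sin(ph)^2)
  expect_equal(polarization_factor(th, ph, "unpolarized"),
               (1 + cos(th)^2) / 2)
  ## horizontal + vertical = 2 * unpolarized (closure identity)
  expect_equal(polarization_factor(th, ph, "horizontal") +
                 polarization_factor(th, ph, "vertical"),
               2 * polarization_factor(th, ph, "unpolarized"))
})

test_that("expected intensity is I0 dOmega P |F|^2 QE per pixel", {
  det <- detector_geometry(6, 5, 2e-4, 0.25, quantum_efficiency = 0.8)
  src <- photon_source(photon_energy = 1200, pulse_energy = 1e-3,
                       focus_diameter = 1e-6)
  qm <- qmap_from_detector(det, src$wavelength)
  amp <- amplitude_sphere(particle_sphere(1e-8, "water"), qm, src$wavelength)
  ii <- expected_intensity(amp, det, src, pol_mode = "horizontal")
  ## [DERIVED] recompute one off-centre pixel by hand (i=4, j=1 zero-based)
  idx <- 1 * 6 + 4 + 1
  hand <- fluence_at(src, c(0, 0)) * solid_angle(det, idx) *
    polarization_factor(qm$theta[idx], qm$phi[idx], "horizontal") *
    Mod(amp$F[idx])^2 * 0.8
  expect_equal(ii$expected[2, 5], hand, tolerance = 1e-12)
  ## wavelength and shape guards
  src2 <- photon_source(photon_energy = 1300, pulse_energy = 1e-3,
                        focus_diameter = 1e-6)
  expect_error(expected_intensity(amp, det, src2), "wavelength mismatch")
  det2 <- detector_geometry(4, 4, 2e-4, 0.25)
  expect_error(expected_intensity(amp, det2, src), "shape")
})

test_that("Poisson sampling is reproducible and integer", {
  det <- detector_geometry(8, 8, 2e-4, 0.25)
  expected <- matrix(5, 8, 8)
  ii <- fxisim:::.intensity_pattern(expected, NULL, det$mask, list())
  s1 <- apply_poisson(ii, rng_seed = 42)
  s2 <- apply_poisson(ii, rng_seed = 42)
  expect_identical(s1$sampled, s2$sampled)
  expect_true(is.integer(s1$sampled))
  expect_true(all(s1$sampled >= 0))
  ## zero expectation gives zero counts, always
  iz <- fxisim:::.intensity_pattern(matrix(0, 8, 8), NULL, det$mask, list())
  expect_true(all(apply_poisson(iz, rng_seed = 1)$sampled == 0))
  ## read noise perturbs but keeps counts non-negative integers
  sn <- apply_poisson(ii, rng_seed = 9, read_noise_sigma = 2)
  expect_true(all(sn$sampled >= 0))
})

test_that("saturation clips and sets bit 8; invalid bit propagates", {
  mask <- matrix(0L, 4, 4); mask[2, 3] <- 1L  # one invalid pixel
  det <- detector_geometry(4, 4, 2e-4, 0.25, mask = mask,
                           saturation_level = 10)
  expected <- matrix(c(rep(1, 14), 50, 200), 4, 4)
  ii <- fxisim:::.intensity_pattern(expected, NULL, det$mask, list())
  ii <- apply_poisson(ii, rng_seed = 3)
  out <- apply_mask_and_saturation(ii, det)
  expect_true(all(out$sampled <= 10))
  expect_true(all(out$expected <= 10))
  over <- expected > 10
  expect_true(all(bitwAnd(out$mask[over], 256L) == 256L))
  expect_identical(bitwAnd(out$mask[2, 3], 1L), 1L)
  ## unsaturated valid pixels keep mask 0
  expect_identical(out$mask[1, 1], 0L)
})

test_that("projection image of a sphere is a disc of the right size", {
  ## small-angle configuration: real-space pixel 5 nm, particle d = 100 nm
  lam <- wavelength_from_energy(8000)
  det <- detector_geometry(64, 64, 194e-6, 0.4)
  qm <- qmap_from_detector(det, lam)
  amp <- amplitude_sphere(particle_sphere(1e-7, "water"), qm, lam)
  pr <- projection_image(amp)
  expect_null(pr$warning_flag)
  m <- Mod(pr$image)
  ## [DERIVED] projected thickness of a sphere is 2 sqrt(R^2 - r^2): its
  ## half-max is at r = R sqrt(3)/2, so the half-max diameter in pixels is
  ## sqrt(3) * R / pixel
  prof <- m[33, ]  # row through the centre (floor(n/2) 0-based = index 33)
  half <- max(prof) / 2
  above <- which(prof >= half)
  width <- max(above) - min(above) + 1
  expect_equal(width * pr$pixel_size[2], sqrt(3) * 0.5e-7,
               tolerance = 2 / width)
  ## image is centred: peak at the centre pixel
  expect_equal(which.max(prof), 33, tolerance = 1)
  ## wide-angle geometry raises the flag
  det2 <- detector_geometry(16, 16, 5e-3, 0.2)
  qm2 <- qmap_from_detector(det2, lam)
  amp2 <- amplitude_sphere(particle_sphere(1e-8, "water"), qm2, lam)
  expect_match(projection_image(amp2)$warning_flag, "small-angle")
})
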