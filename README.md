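# fxisim

Forward simulation of flash X-ray imaging (FXI) experiments in R: coherent
far-field diffraction patterns of single nanoparticles — spheres, spheroids,
voxelized density maps, and atomic models — recorded by a photon-counting
pixel-array detector, one free-electron-laser pulse at a time.

## What it computes

In an FXI experiment an intense femtosecond X-ray pulse hits a stream of
injected particles; each detector frame records the far-field diffraction of
whatever the pulse caught in the focus. `fxisim` models this chain under the
first-order Born approximation:

1. **Optical properties.** Complex atomic scattering factors
   `f = f1 + i f2` (bundled tables, 16 biologically relevant elements,
   250 eV–30 keV) combine with atomic number densities into the complex
   refractive index `n = 1 − δ − iβ`, or equivalently an electron density.
2. **Geometry.** Every detector pixel maps to a scattering vector on the
   Ewald sphere, `q = (2π/λ)(ŝ − ẑ′)`, so `|q| = (4π/λ) sin(θ/2)` and
   full-period resolution is `d = 2π/|q|`. Orientations are unit
   quaternions, uniform over SO(3) when sampled.
3. **Amplitudes.** Four particle models share one scattering-length
   convention and agree with each other where their domains overlap:
   analytic uniform spheres and spheroids, voxelized maps
   (`F = (k²/2π) Δx³ Σ n̄ e^{−iq·x}`), and atomic models
   (`F = r0 Σ f_a e^{−iq·r}`) evaluated by an exact dense non-uniform DFT
   in C++. Rotations act on `q`, never by resampling coordinates.
   Multiple particles superpose coherently with per-particle phase ramps
   and illumination weights.
4. **Detection.** Expected counts are
   `I_pix = I0 · ΔΩ · P · |F|² · QE` with the flat-detector solid angle
   `ΔΩ = (s²/D²) cos³θ′` and a selectable polarization factor, followed by
   Poisson shot noise, optional read noise, saturation clipping and
   CXI-convention mask bits.
5. **Experiments.** A stochastic injection model (Poisson arrival numbers
   per species, size/shape jitter, positions in the focus, random
   orientations) drives multi-shot runs that are written to CXI/HDF5 files
   with full per-shot ground truth, either from R or from an INI-style
   configuration file via the bundled `fxisim` command-line script.

A small analysis toolbox (radial averaging, central speckle size, Guinier
effective diameter, real-space projection images) supports checking the
physics of what comes out.

## Worked example

A one-pulse snapshot of protein complexes injected into a 1 keV beam:

```r
library(fxisim)

## optics: water at 1 keV
refractive_index_from_atom_density("water", 1000)
#> <fxi_refractive_index> n = 1 - 2.3580e-04 - 3.8736e-05i (delta, beta)

## source: 1 mJ pulses focused to 1 um
src <- photon_source(photon_energy = 1000, pulse_energy = 1e-3,
                     focus_diameter = 1e-6)
photons_per_pulse(src)
#> [1] 6.241509e+12

## detector: 128 x 128 pixels, 750 um pitch, 0.74 m downstream
det <- detector_geometry(128, 128, 75e-5, 0.74)
min(resolution_at_pixel(qmap_from_detector(det, src$wavelength))) * 1e9
#> [1] 13.66445   # corner resolution, nm

## injected species: ~8 nm protein spheroids, Poisson rate 0.9 per shot,
## jittered size, random flattening and orientation
sp <- species_spec(particle_spheroid(8e-9, material = "protein"),
                   arrival_rate = 0.9, diameter_sigma = 1e-9,
                   flattening_range = c(0.8, 1.0),
                   position = "uniform-in-focus",
                   orientation = "uniform-random", label = "complex")

conf <- experiment(src, sp, det, seed = 7, shots = 1)
shot <- propagate(conf, shot_index = 1)
length(shot$instances)                          # particles caught in beam
#> [1] 2
shot$instances[[1]]$particle$diameter * 1e9     # sampled diameter, nm
#> [1] 8.328557
shot$instances[[1]]$particle$flattening
#> [1] 0.8667564
sum(shot$intensity$expected)                    # expected photons
#> [1] 20206.28
sum(shot$intensity$sampled)                     # Poisson-sampled photons
#> [1] 20335
```

Every shot is deterministic given `(configuration, seed, shot index)` and
carries its complete ground truth; `replay_shot()` reproduces the expected
intensity exactly, and `run_experiment()` writes frames, geometry and
ground truth to a CXI file.

The same experiment as a configuration file:

```ini
[source]
photon_energy = 1000        # eV
pulse_energy  = 1e-3        # J
focus_diameter = 1e-6       # m

[particle_complex]
model = spheroid
material = protein
diameter = 8e-9
diameter_sigma = 1e-9
flattening_min = 0.8
flattening_max = 1.0
arrival_rate = 0.9
position = uniform-in-focus
orientation = random

[detector]
nx = 128
ny = 128
pixel_size = 75e-5
distance = 0.74

[simulation]
shots = 100
output = run.cxi
```

```sh
fxisim --config run.conf --seed 7
```

## Verification

The test suite (`tests/testthat/`) checks every fast path against
independent oracles: a literal brute-force DFT written in plain R
(agreement to 1e-9), the closed-form sphere amplitude against a 64-voxel
sphere (< 1% with the first intensity zero at qR = 4.4934 ± 0.01),
cross-model consistency between analytic, voxel and pseudo-atom
representations of the same water sphere (< 2% in |F|²), Friedel symmetry,
translation/rotation invariances, the single-electron Thomson cross-check,
Poisson Fano factors, χ² arrival statistics of the injection model, and
more.

To reproduce:

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "fxisim",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

`scripts/acceptance.R` writes the headline quantities (oracle agreement,
first-zero location, refractive index of water, Fano factors, arrival-test
p-values, speckle-size ratios, end-to-end mixture statistics) as a flat
JSON object.

See `vignette("fxisim-methods")` for the full model description, unit
conventions and numerical choices.

## License

MIT (see `LICENSE`).
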