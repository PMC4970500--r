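---
title: "fxisim: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fxisim: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the physical model behind `fxisim`, the unit
conventions, and the numerical choices that a user of the simulated data
should know about. All quantities are SI unless noted; photon energies are
in eV.

# Scattering model

## The first-order Born approximation

A single X-ray pulse illuminates a particle small enough (and a pulse short
enough) that multiple scattering and sample motion are negligible. The
far-field scattered amplitude is then the Fourier transform of the
scattering potential evaluated on the Ewald sphere. `fxisim` works with a
*scattering length* $F(\mathbf q)$ carrying units of metres, so the
expected photon count in a pixel is

$$ I_{\mathrm{pix}} = I_0\,\Delta\Omega\,P\,|F(\mathbf q)|^2\,\epsilon, $$

with $I_0$ the fluence at the particle (photons/m²), $\Delta\Omega$ the
pixel solid angle, $P$ a polarization factor and $\epsilon$ the quantum
efficiency. One free electron has $|F| = r_0$, the Thomson scattering
length, which makes the normalization auditable: the on-axis expected count
of a single electron is exactly $I_0\,\Delta\Omega\,r_0^2$ (this identity
is an acceptance test).

## Scattering vectors

A flat detector orthogonal to the beam samples, at each pixel with unit
scattering direction $\hat s$,

$$ \mathbf q = \frac{2\pi}{\lambda}(\hat s - \hat z'), $$

where $\hat z'$ is the (possibly tilted) incident direction. The $2\pi$
factor is *included*: $|\mathbf q| = (4\pi/\lambda)\sin(\theta/2)$ and
full-period resolution is $d = 2\pi/|\mathbf q|$. `qmap_from_detector()`
builds this map with the x pixel index as the fast axis and 0-based,
possibly fractional, beam centres; `qmap_manual()` accepts arbitrary
$\mathbf q$ points (e.g. radial lines) for analysis work.

## Optical constants

Atomic scattering factors $f = f_1 + i f_2$ for 16 biologically relevant
elements are bundled (250 eV–30 keV, log-spaced, computed from
Cromer–Liberman anomalous-dispersion theory with $f_1 = Z + f'$) and
linearly interpolated in energy; requests outside the tabulated range are
an error, never an extrapolation. The hydrogen table is identically
$1 + 0i$, which keeps the single-electron Thomson check exact.

A material (mass density plus stoichiometry) yields per-species atom
densities $\rho_a$ and the complex refractive index

$$ n = 1 - \delta - i\beta
     = 1 - \frac{r_0\lambda^2}{2\pi}\sum_a \rho_a f_a . $$

An electron density instead gives $\delta = r_0\lambda^2\rho_e/2\pi$ with
$\beta = 0$; the two routes coincide exactly in the high-energy limit
$f \to Z$ (tested). The quantity the map-based amplitude uses is the
complemented index $\bar n = 1 - n = \delta + i\beta$.

# Particle models

All four models produce the same scattering-length amplitude and are
cross-validated against one another:

* **Sphere** (closed form):
  $F = s_{\mathrm{tot}}\,3[\sin u - u\cos u]/u^3$ with $u = |q|R$ and
  $s_{\mathrm{tot}} = (k^2/2\pi)\bar n\,(4/3)\pi R^3$. For
  $|u| < 10^{-4}$ the Taylor form $1 - u^2/10$ avoids cancellation.
* **Spheroid** (closed form): the ellipsoid reduction with
  $u = |q| R_{\mathrm{eff}}(\psi)$,
  $R_{\mathrm{eff}}^2 = a^2\sin^2\psi + c^2\cos^2\psi$, $\psi$ the angle
  between $\mathbf q$ and the symmetry axis. Sizes are parameterized by
  the equal-volume-sphere diameter and the flattening $c/a$, so changing
  the flattening never changes the particle volume.
* **Voxel map**: $F = (k^2/2\pi)\Delta x^3\sum_j \bar n_j
  e^{-i\mathbf q\cdot\mathbf x_j}$. Voxel values may be complex refractive
  indices, electron densities, or total atom densities (distributed over a
  material's composition). If the grid is coarser than $\pi/q_{\max}$ the
  returned pattern carries a `warning_flag` rather than silently aliasing.
* **Atoms**: $F = r_0\sum_a f_a\sum_{i\in a}
  e^{-i\mathbf q\cdot\mathbf r_i}$, evaluated per element by an exact
  dense non-uniform DFT in C++ (no gridding or interpolation error). The
  deliberately naive `brute_force_dft()` — a literal double loop in plain
  R — is exported as the testing oracle; the fast path matches it to
  $10^{-9}$ relative.

Orientation is always applied by rotating the scattering vectors into the
particle frame, $F_R(\mathbf q) = F(R^{-1}\mathbf q)$; coordinates and
voxel grids are never resampled, so rotation introduces no numerical error
beyond the rotation matrix itself. Rotations are unit quaternions with
constructors from quaternions, extrinsic Euler angles (all 12 orders;
later rotations multiply from the left) and matrices; `random_rotation()`
normalizes 4-D Gaussians, which is uniform over SO(3).

Multiple particles in one shot superpose coherently:
$F_{\mathrm{tot}} = \sum_j F_j\,e^{-i\mathbf q\cdot\Delta\mathbf r_j} w_j$
with $w_j = \sqrt{I(x_j,y_j)/I_0}$ the illumination weight at particle
$j$'s transverse position.

## Voxelization of geometric shapes

`map_from_geometry()` fills a sphere, spheroid or regular icosahedron with
a material at its bulk atom density. Surface voxels get fractional
occupancy from the local signed distance to the surface through a
one-voxel linear ramp ($\mathrm{occ} = \mathrm{clip}(1/2 + d/\Delta x)$),
which suppresses hard-edge staircase artefacts; `antialias = FALSE` gives
a binary map for comparison work. Icosahedron face normals are derived
from the vertex set $(0,\pm1,\pm\phi)$ (cyclic), and the voxelizer's
output is invariant under the 60-element icosahedral rotation group
(tested against an independently generated group).

# The stochastic experiment

`species_spec()` describes how instances of a template particle arrive:
Poisson arrival numbers (or a fixed count), truncated-normal diameter
jitter, uniform flattening ranges, positions fixed / uniform over the
focus / normal, and fixed or uniform-random orientations. `propagate()`
runs one shot: sample pulse energy and beam tilt, draw the ensemble,
superpose amplitudes, convert to expected counts, apply Poisson noise
(and optional Gaussian read noise, rounded and floored at zero), then
saturation clipping (CXI mask bit 8) and the static bad-pixel mask
(bit 0).

Determinism: every shot's RNG state derives from
`(base seed, shot index)` through a fixed integer map, so any shot of any
run can be reproduced in isolation, and `replay_shot()` recomputes the
expected intensity of a recorded shot exactly from its stored ground
truth.

# Input and output

* **PDB** (`read_pdb()`): ATOM/HETATM records via `bio3d`; waters and
  hydrogens are *kept* by default (flags drop them); where alternate
  locations exist only the highest-occupancy conformer is kept;
  coordinates are converted to metres and centred.
* **CCP4/MRC 2014** (`read_map()`/`write_map()`): mode-2 (float32) cubic
  grids; the MAPC/MAPR/MAPS axis permutation is honoured on read, so
  arrays are always `[x, y, z]` in the lab frame. Non-cubic or
  anisotropic maps are rejected rather than resampled.
* **CXI/HDF5** (`write_cxi()`): frames, mask, detector geometry and source
  metadata in the standard layout under
  `/entry_1/instrument_1`, plus complete per-shot ground truth
  (particle table with positions, sizes, flattenings, quaternions;
  species labels; pulse energies; beam tilts) under
  `/entry_1/simulation_1`.
* **Configuration files** (`parse_config()`): INI syntax with `[source]`,
  `[detector]`, one or more `[particle_*]` sections and an optional
  `[simulation]` section. Unknown keys fail fast with a nearest-key
  suggestion; unspecified keys take the documented defaults (64×64
  detector, 75 µm pixels at 0.74 m; 1 mJ, 1 µm flat-top focus; seed 1).
  The command-line entry point `fxisim` reads `./fxisim.conf` by default
  and accepts `--config`, `--output`, `--shots`, `--seed`, `--quiet`.

# Analysis utilities

* `projection_image()`: in the small-angle regime the detector samples a
  nearly flat 2-D slice of reciprocal space, so a dense inverse DFT of
  $F$ over the detector raster yields the complex projection of the
  scattering potential along the beam, with real-space pixel
  $2\pi/(N\Delta q)$; fractional beam centres are handled by phase ramps,
  and patterns beyond ~5° scattering angle carry a warning flag.
* `central_speckle_size()`: the full width at half maximum of the
  azimuthally averaged central lobe, in $\Delta q$ units. For a uniform
  ball the exact value is $3.63/R \approx 1.156 \times 2\pi/D$.
* `guinier_diameter()`: $D_{\mathrm{eff}} = 2\sqrt{(5/3)}R_g$ from
  (optionally weighted) coordinates; exact for a uniform ball. When
  comparing to a *single* pattern of an anisotropic particle, note that
  the pattern sees the particle's transverse projection; the projected
  analogue $2\sqrt{(5/2)}R_{g,2D}$ is the matched comparator.

# Numerical choices and limitations

* The dense NUDFT is exact but $O(n_{\mathrm{points}} \times
  n_{\mathrm{pixels}})$; it is intended for the detector rasters (up to a
  few hundred pixels per axis) and particle sizes (up to ~$10^5$ atoms or
  occupied voxels) typical of FXI simulation studies.
* The forward-scattering approximation uses one $f(E)$ per element at all
  angles; this is appropriate for nanometre-scale resolutions, well above
  atomic length scales.
* First-order Born only: no multiple scattering, absorption along the
  path, or pulse-duration effects.
* Scattering-factor tables cover 250 eV–30 keV and 16 elements; other
  elements or energies raise errors rather than guesses.
* Maps must be cubic grids with isotropic spacing.
* The projection utility assumes the small-angle regime; it warns, but
  does not correct, beyond it.
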