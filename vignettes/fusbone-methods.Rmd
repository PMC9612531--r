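---
title: "Modelling transcranial focused ultrasound through a flat bone layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcranial focused ultrasound through a flat bone layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fusbone)
```

## The problem

Low-intensity focused ultrasound (LIFU) for non-invasive neuromodulation has
to pass through the skull, which both attenuates the focal intensity (often
by more than half) and displaces the focal point by millimetres to
centimetres.  Whether a planned sonication actually reaches its target at a
useful intensity depends jointly on five experimental parameters: carrier
frequency, bone thickness, the trajectory angle at which the beam meets the
bone, the focal depth, and the transducer diameter.  Running a full acoustic
simulation for every candidate parameter set is slow and requires
specialised tooling, so `fusbone` precomputes a *surrogate model*: paired
bone/water simulations on a grid over the five-dimensional parameter space,
reduced to two tensors —

* **attenuation** — the peak focal intensity with bone present, as a percent
  of the peak intensity of an identical water-only simulation, and
* **refraction** — the Euclidean distance (mm) between the two peak
  locations,

which are then queried by multilinear interpolation in milliseconds.

## The acoustic model

The solver integrates the first-order linear acoustic equations for
heterogeneous media — particle velocity `u` and a split acoustic density
`rho_x, rho_y, rho_z` per axis with `p = c^2 * sum(rho_d)` — using the
k-space pseudospectral time-domain (PSTD) method: spatial derivatives are
evaluated spectrally on staggered grids
(`exp(+/- i k dx / 2)` shifts), and the time step carries the k-space
dispersion correction `kappa = sinc(c_ref k dt / 2)` with `c_ref` the
scene's maximum sound speed, which makes propagation exact for a homogeneous
medium at `c_ref` and keeps the scheme stable at the default
Courant-Friedrichs-Lewy number of 0.3.  A split-field perfectly matched
layer (PML) of 10 voxels per side with a quartic absorption profile
(`pml_alpha = 2`, peak absorption `pml_alpha * c_ref / dx`) terminates the
domain.  The PML width can be set per axis; a width of zero leaves an axis
periodic, which is how the validation suite builds exact plane waves from a
full-width line source.

Scenes are two-valued voxel maps: water (1000 kg/m^3, 1482 m/s, absorption
quadratic in frequency from a pure-water temperature fit at 37 C) and bulk
bone (1732 kg/m^3, 2850 m/s, 85 Np MHz^-1 m^-1, linear in frequency).
Because every simulation is narrowband at its carrier, absorption is applied
as a *stationary* per-voxel loss: both `u` and the density components are
multiplied by `exp(-alpha(f0) c dt)` each step, which makes a travelling
wave decay as `exp(-alpha x)` exactly (verified against Beer-Lambert to
under 1%).  This choice avoids a dispersive fractional-Laplacian absorption
operator; it reproduces amplitude physics at the carrier but not
absorption-related dispersion, a deliberate fidelity trade-off.

Density is evaluated on the staggered velocity grids as the neighbour
average, which noticeably improves two-valued interface accuracy.  The
remaining sharp-interface systematic of the scheme — measured as a 5-7%
intensity (~3% pressure) deficit in steady-state transmission through a
flat layer relative to the closed-form three-medium coefficient — does not
vanish with grid refinement; it is an intrinsic property of collocated
sharp media under Fourier collocation and is shared by production solvers
of this family.  It largely cancels in the attenuation ratio because both
members of a bone/water pair see the same discretisation.

## Transducer model

A focused bowl is a spherical cap with radius of curvature
`sqrt(focal_depth^2 + (diameter / 2)^2)`, so the geometric focus lies
`focal_depth` beyond the aperture plane.  The cap shell is rasterized by
marking voxels whose centre lies within half a voxel diagonal of the
defining sphere and inside the aperture cone.  Two corrections compensate
rasterization artefacts, both standard for gridded curved sources:

* **surface-density normalisation** — the marked shell is locally 1-2 voxels
  thick, so the per-voxel drive is scaled by the ideal shell count
  (cap area / dx^2) over the actual count;
* **focal phase alignment** — each shell voxel sits up to `dx * sqrt(3) / 2`
  off the ideal sphere; it is driven with a phase offset
  `k (r - ROC)` so its contribution arrives at the focus in phase.  Without
  this, the staircase phase spread decoheres the focus (about 10% amplitude
  loss at six points per wavelength, which we observed directly before
  adding the correction).

The drive is an additive pressure source: a sinusoid at the carrier with a
cosine-taper onset over 3 carrier cycles, scaled so a plane sheet of source
voxels radiates exactly the configured amplitude (1.0558 MPa by default;
all outputs are bone/water ratios, so the value is arbitrary).  Maximum
pressure recording starts only after the ramp completes, excluding onset
transients.

At normal incidence (trajectory 90 degrees) the bowl meets the flat bone
slab along its aperture plane.  Oblique trajectories rotate the bowl about
the aperture-rim point that stays on the bone face, tilting the beam away
from the domain faces — while the bone slab itself remains axis-aligned and
flat for every trajectory, because an aliased (staircased) bone surface is
the dominant error source in this class of simulation.  The slab occupies
`round(thickness / dx)` whole voxel planes starting immediately behind the
rim plane.

## The sweep and its bookkeeping

`build_surrogate()` enumerates the Cartesian product of the five level
vectors in row-major order (first axis slowest), pre-flagging points whose
focus would sit inside bone (`focal_depth <= thickness`) or outside the
simulated head (focus or bowl not inside the interior with a 2-voxel
margin).  Flagged points are skipped and stored as invalid — never silently
zero — and queries whose enclosing interpolation cell touches an invalid
entry raise an error rather than extrapolating.  Each valid point runs the
bone and water simulations with identical geometry, drive, duration and
search mask; the search mask covers interior voxels strictly beyond the
slab's inner face, outside the transducer concavity (whose near field is
noisy) and outside the PML.  Builds checkpoint after every point and
resume from the checkpoint file.  Per-scene simulation time defaults to
1.01 x (interior axial extent / water speed) — the time the wavefront needs
to cross the useful domain, matching the full-scale convention of 8.0375e-5
s for the 11.8 cm interior.

Everything is deterministic: there is no randomness anywhere in the
pipeline, so rebuilding a grid reproduces the tensors bit-for-bit, and the
test suite asserts exactly that.

## Validation procedures

Two validation commands mirror the study-level checks:

* `cmd_validate_oneil()` runs water-only 3-D simulations for a set of
  (depth, diameter) combinations, extracts the on-axis maximum-pressure
  profile from the transducer's geometric centre, and compares it to the
  closed-form O'Neil spherical-cap solution via the *focal-region AUC
  deviation*: each profile is restricted to the contiguous region around
  its peak where intensity (pressure squared) is at least 50% of its own
  maximum (the -3 dB focal region), the pressure is integrated by
  trapezoid, and the deviation is `100 |AUC_sim - AUC_oneil| / AUC_oneil`.
  The O'Neil solution itself is verified against an independent
  Rayleigh-Sommerfeld surface integral (1% RMS agreement over the focal
  region across a 3 x 3 grid of geometries).
* `cmd_validate_convergence()` re-runs one fixed parameter point across a
  grid of CFL numbers and points-per-wavelength (PPW) values and tabulates
  attenuation and refraction per setting.

Both default to the full-scale configuration (1 MHz, 12 mm bone, 90
degrees, 80 mm depth and width at 256^3 voxels) and accept desk-scale
configs.  The test suite runs them scaled down, sizes chosen once as the
package's study conditions:

* O'Neil: 200 kHz, spacing 1.2 mm (PPW 6.18), 3-D grids of at most 96^3,
  three combinations — depths 28-35 mm, diameters 30-36 mm.  Weaker
  focusing than the full-scale study (ka around 13-15 instead of 170)
  makes this a conservative check: relative voxelization effects are
  larger at this scale.
* Convergence: 2-D, the fixed point with depth/diameter scaled from 80 mm
  to 25 mm, corners (CFL 0.3, PPW 3) vs (CFL 0.1, PPW 6).  At these
  conditions the attenuation values (0.78% coarse, 0.92% fine) bracket the
  same regime as the full-scale study; true refraction at normal incidence
  through a flat slab is below one voxel at both resolutions, so the
  refraction check asserts agreement at the grid-resolution floor (one
  coarse voxel) rather than a relative difference between two near-zero
  numbers.  Tilted variants produce centimetre-scale refraction that
  converges to a few percent, but their attenuation at 3 PPW suffers from
  oblique-interface error; the normal-incidence point follows the
  reference procedure.

## What the synthetic data does and does not emulate

The toy study space used by the tests (two levels per axis, 2-D scenes,
0.75 mm spacing, 350-500 kHz, bone 0-2.25 mm, trajectories 75-90 degrees,
depths 22.5-30 mm, diameters 15-18 mm) exercises every code path —
tilting, zero-thickness degeneracy, validity flagging, interpolation — at
desk scale.  It does not emulate: 3-D diffraction in the sweep itself
(tests cover 3-D separately), realistic skull curvature or heterogeneity
(out of scope by design: the model is a flat homogeneous layer), shear-mode
conversion at oblique incidence (the solver is fluid-only, as is the
reference toolchain), or nonlinear propagation.  Passing tests therefore
demonstrate the correctness of the machinery and its agreement with linear
layered-media and radiator theory — not the clinical accuracy of flat-layer
predictions for any individual skull.

## Numerical choices and degenerate inputs

* Indices are 1-based (R convention); voxel `i` has its centre at
  `(i - 0.5) * dx`.  Axis 1 is the beam axis at normal incidence.
* `dt = cfl * dx / max(c)` per scene: bone-bearing scenes step at the bone
  speed, water-only scenes at the water speed.  Both members of a pair
  share `t_end`, not `dt`.
* Peak search ties break toward the lowest linear (column-major) voxel
  index.  Nearest-simulation lookup ties break toward the lower level.
* Queries exactly on the hull faces of the parameter grid are accepted
  (closed bounding box); anything outside errors, as does any query whose
  32-corner cell touches an invalid entry.
* Zero bone thickness yields an empty slab: the bone and water runs are
  identical, attenuation is exactly 100% and refraction 0 mm — asserted as
  a property.
* Grid shapes from `suggest_grid()` are rounded up to 5-smooth lengths so
  the FFTs stay in their fast regime; 256 (the full-scale dimension) is
  already a power of two.
* Serialization uses R's native format with schema checks; round trips are
  bit-exact.

## Known limitations

* Sharp-interface transmission carries the ~3% pressure systematic noted
  above; it does not shrink with resolution.
* The stationary loss omits absorption dispersion; broadband or pulsed
  drives would need the full fractional-Laplacian operator.
* Oblique incidence ignores shear waves in bone, as does the reference
  model; beyond the longitudinal critical angle (about 31 degrees from
  normal) transmitted energy is underestimated.
* The published full-scale dataset (6,048 environments) cannot be
  reconstructed because its per-axis discretisation is not printed; the
  default grid levels here span the published parameter ranges with
  configurable level counts.
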