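---
title: "Simulating focal attenuation of transcranial focused ultrasound by skull-like plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating focal attenuation of transcranial focused ultrasound by skull-like plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Focused ultrasound delivered through the skull loses focal pressure and
focal sharpness to absorption, impedance mismatch, and refraction in bone.
`tfusim` simulates the canonical bench model of this situation: a
single-element spherically curved transducer (0.9 MHz, 100 mm aperture,
80 mm focal length, 50 mm central hole) insonifying degassed water through a
curved skull-mimicking plate, and quantifies how the focal field degrades as
the plate's structural parameters (thickness, curvature radius, standoff
distance) and acoustic parameters (density, sound speed, absorption) are
varied one at a time.

## Model

Propagation is governed by the Westervelt equation for the acoustic
pressure $p$,

$$\nabla^2 p \;-\; \frac{1}{c^2}\frac{\partial^2 p}{\partial t^2}
  \;+\; \frac{\delta}{c^4}\frac{\partial^3 p}{\partial t^3}
  \;+\; \frac{\beta}{\rho c^4}\frac{\partial^2 p^2}{\partial t^2} = 0,$$

with per-material density $\rho$, sound speed $c$, thermoviscous
diffusivity $\delta$, and coefficient of nonlinearity $\beta$.  The loss
term encodes absorption through
$\delta = 2\alpha c^3/\omega^2$, where $\alpha$ (Np/m) is the amplitude
absorption coefficient at the drive frequency; material absorption is
stored per MHz and scaled linearly in frequency.  Default media:

| medium  | $\rho$ (kg/m³) | $c$ (m/s) | $\alpha_0$ (Np/m/MHz) | $\beta$ |
|---------|---------------:|----------:|----------------------:|--------:|
| water   | 998.2          | 1482      | 0.02                  | 3.5     |
| acrylic | 1203           | 2600      | 18                    | 4.4     |

Skull-like plates for the acoustic sweeps take
$\rho = 1850\ \mathrm{kg/m^3}$, $c = 3500\ \mathrm{m/s}$ and
$\alpha = 2600\ \mathrm{dB/m}$ at 0.9 MHz (1 Np = 8.686 dB) unless the
swept parameter overrides one of them.

The equation is advanced with an explicit three-level finite-difference
time-domain (FDTD) scheme, by default on an axisymmetric $(r, z)$ grid
(the scene is rotationally symmetric); a full 3-D Cartesian mode is
available for cross-checks.  First-order Mur one-way conditions absorb the
outer boundaries; the beam axis uses the cylindrical regularity condition.
The bowl source is "hard": cap-surface cells are overwritten with the
drive $p_0 \sin(\omega t)$, with a per-node phase offset that compensates
the staircase rasterization of the cap (each node is driven as a sample of
the true curved wavefront).  The plate is a spherical shell between
concentric spheres of radii $R$ and $R-T$, convex face toward the
transducer, its nearest surface crossing the axis a standoff $D$ behind
the transducer rim plane.

## Numerical choices

Several choices matter at the resolutions this package is meant to run at
(a desk-scale laptop core, seconds per solve):

* **Isotropic stencils.**  The standard 5-point (2-D) and 7-point (3-D)
  Laplacians propagate waves up to ~11 % slower along grid axes than along
  diagonals at four points per wavelength.  For a focused bowl this
  anisotropy acts like a lens error: in our tests it displaced the pure
  water focus by more than ten millimetres at the coarsest grid.  In
  uniform-material regions the solver therefore uses isotropic-error
  stencils (9-point in $(r,z)$, 27-point in 3-D) whose leading dispersion
  error is direction-independent; at material interfaces and in a small
  halo around the source it falls back to the conservative heterogeneous
  form $\rho \nabla\!\cdot\!(\rho^{-1}\nabla p)$ with face-averaged inverse
  densities, which reproduces impedance-governed transmission.
* **Dispersion-tuned sound speed.**  With direction-independent dispersion
  a single scalar correction per material,
  $c_\mathrm{sim} = \Delta x \sin(\omega \Delta t/2) /
  (\Delta t \sin(\omega \Delta x / 2c))$,
  makes the numerical phase speed at the drive frequency equal the
  physical one.  Densities are inversely adjusted so characteristic
  impedances $\rho c$ — and with them reflection and transmission — stay
  physical.
* **Time step.**  $\Delta t$ starts from the smaller of 90 % of the
  Courant bound and one twentieth of the drive period, then shrinks until
  the combined stability condition of the explicit loss term,
  $(c_\mathrm{sim}\Delta t/\Delta x)^2 + 2\delta \Delta t/\Delta x^2 \le
  L$ ($L = 1/2$ in 2-D, $1/3$ in 3-D, with a 10 % margin), holds for the
  most demanding medium.  This matters for strongly absorbing plates
  (thousands of dB/m), where the explicit loss update otherwise diverges.
* **Steady state and amplitude.**  The drive is continuous-wave.  A solve
  runs for twice the slowest domain-traversal time plus 15 drive cycles;
  the per-cell amplitude is half the peak-to-peak pressure range over the
  final two cycles, recorded as two one-cycle windows whose difference in
  global peak is reported as a convergence residual.  Peak-to-peak (rather
  than max $|p|$) rejects any static offset; with 20 time samples per
  period its sampling bias is a fraction of a percent and identical across
  runs, so it cancels from every ratio.
* **Source calibration.**  The drive amplitude corresponding to the
  reference bench condition is not part of the model; `calibrate_source()`
  scales $p_0$ so the pure-water focal peak matches a target (549.3 kPa
  for the reference condition), using exact linear-mode proportionality
  plus one fixed-point refinement when the quadratic term is on.

Resolution presets: `"paper"` ($\lambda_\mathrm{water}/8$ = 0.206 mm),
`"ci"` ($\lambda/6$), and `"coarse"` ($\lambda/4$, the sweep default;
~122 × 244 nodes, a few thousand steps, roughly one second per solve).
Sweeps and the shipped acceptance script run entirely at `"coarse"`; the
1-D verification runs use $\lambda/12$–$\lambda/32$ where the plane-wave
closed forms are meaningful.

## What the verification layer shows — and what it does not

The `oracles` functions provide independent ground truth: the closed-form
on-axis field of a focused annular bowl (checked to 0.1 % against direct
Rayleigh-integral quadrature), plane-wave decay, interface and lossy-layer
(Fabry–Pérot) transmission, and the Fubini harmonic series for nonlinear
plane waves.  The test suite verifies, among other things:

* numerical phase speed within 0.5 % at 8 points per wavelength
  (CFL 0.95), and plane-wave decay within 2 % of $e^{-\alpha x}$;
* transmission into an impedance step within 2 % of $2Z_2/(Z_1+Z_2)$ and
  through an 8 mm acrylic slab within 3 % of the exact lossy-layer value
  (the single-pass product of interface factors and absorption is *not*
  the right answer here — steady-state reverberation inside a weakly
  absorbing layer shifts transmission by ~10 %);
* focal gain of a miniature lossless bowl within 5 % of the closed form
  on a $\lambda/12$ grid;
* exact linearity in the drive, monotone dissipation in $\delta$, and
  grid convergence of the focal peak below 3 % between $\lambda/12$ and
  $\lambda/16$.

Known numerical limitations, stated so that coarse-preset results are read
correctly:

* At $\lambda/4$ the scheme accrues a slow amplitude inflation of roughly
  1.4 % per wavelength of propagation (an $O(\Delta x^2)$ artifact that
  vanishes by $\lambda/12$), so *absolute* focal gains at the coarse
  preset are high by a factor approaching two.  Every quantity the
  package reports for the study — positions, lengths, percent drops, dB
  slopes — is either a position or a ratio of two runs under the identical
  protocol, and the drive is calibrated, so this artifact largely cancels.
  The same artifact differs slightly between the 2-D and 3-D stencils,
  which is why the axisymmetric/3-D cross-check asserts focal position at
  one cell but amplitude only at 10 % on a $\lambda/6$ miniature scene.
* The Mur condition is first-order: excellent at normal incidence
  (< 1 % in the tests), progressively worse at grazing incidence.
  Domains should not place strong grazing propagation along a boundary.
* Sources are driven with a single global phase plus the staircase
  correction; arbitrary per-element phasing (e.g. oblique plane-wave
  injection) is not supported.

## Design decisions on the scene

Two points of the physical arrangement are genuinely underdetermined and
were fixed as follows:

* **Plate orientation.**  The shell's convex face points toward the
  transducer, as a skull seen from outside the head, and both plate faces
  are concentric spheres.  With an 80 mm-focus bowl and $R$ = 60 mm at
  $D$ = 10 mm this puts the shell's centre of curvature close to the
  focus, so the converging wavefront crosses both faces near normal
  incidence.  The consequence is that plate attenuation is dominated by
  absorption (path ≈ $T$) and impedance mismatch, while
  refraction-induced aberration is mild.  We examined the alternatives —
  concave-forward shells, flat slabs, and plano-curved plates — and none
  reproduces all of the published bench/simulation attenuation figures at
  once: concave-forward arrangements roughly double the attenuation but
  make it implausibly sensitive to curvature radius and standoff and push
  the focus away from the transducer; flat or plano plates give large
  thickness-proportional aberration but break the thin-plate limit.  The
  concentric convex arrangement is the one consistent with the shell
  geometry examples, the acoustic-parameter sweeps and the focal
  positions; readers should expect the *structural* attenuation magnitudes
  (thickness/curvature/distance trends) to be smaller than bench values
  obtained with mounted CNC plates, whose effective geometry evidently
  defocuses more strongly.
* **Unit attenuation convention.**  The per-unit-step dB attenuation of a
  linear trend is referenced to the fitted intercept,
  $20\log_{10}\!\big(b/(b - |m|\,\Delta)\big)$.  This reproduces the
  published thickness figure (0.357 dB/mm at display precision: the
  formula gives 0.3560 from the printed coefficients) and the distance
  figure (0.0495 vs 0.048), but not the published curvature figure (0.023
  vs 0.027); no single convention we tried reproduces all printed values,
  and the discrepancy is reported rather than patched.

Other defaults: sweeps keep the quadratic term on with the calibrated
drive (its effect on the ratio metrics is small at these amplitudes);
sweep metrics search for the focus only beyond the plate's back face plus
2 mm, so strongly attenuated runs do not mistake the plate's internal
standing waves for a focus; the $-6$ dB length uses the half-amplitude
convention.  Note that the exact closed-form $-6$ dB length of this
annular bowl in water is 11.7 mm; the solver converges to ~11.5 mm at
every resolution, noticeably longer than the 9.8 mm reported from the
bench-calibrated reference simulation.

## Problem sizes

The shipped acceptance script and the test suite run: one calibration pair
and two reference solves on the 122 × 244 coarse grid; six sweeps
totalling ~65 coarse solves (a few minutes altogether); miniature
$\lambda/12$ bowls (≈ 2 s each) for the oracle checks; and 1-D tracks of a
few hundred to a thousand nodes for the plane-wave verifications.
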