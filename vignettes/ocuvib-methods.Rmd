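---
title: "Modelling corneal vibrography: methods and design choices"
author: "ocuvib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling corneal vibrography: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

Optical-coherence-tomography (OCT) vibrography measures the nanometre-scale
oscillation of the cornea while the eye is excited by sound. The frequency
response function (FRF) of the central cornea — apex oscillation amplitude
versus drive frequency — peaks at the natural frequencies of the
tissue/fluid system, and those natural frequencies are governed by the
corneal elastic modulus, the geometry, the density, the mounting state and
the surrounding media. `ocuvib` implements the forward model of this
experiment — an axisymmetric finite-element harmonic analysis of corneal
flaps and whole eye globes — together with the inverse step that adjusts
the corneal modulus until simulated resonances match an observed set.

## Governing equations and discretisation

The steady harmonic response at imposed circular frequency $\Omega = 2\pi f$
solves

$$(-\Omega^2 [M] + i\Omega[C] + [K(\Omega)])\,(\{u_1\} + i\{u_2\})
  = \{F_1\} + i\{F_2\},$$

with consistent mass $[M]$, optional viscous damping $[C]$ (retained for
Rayleigh damping, zero by default) and a complex, frequency-dependent
stiffness $[K(\Omega)]$. Tissue viscoelasticity enters exclusively through
the Prony-series complex modulus

$$E^*(f) = E_{\mathrm{inst}}\Big(1 - \sum_i \frac{p_i}{1 + i\Omega T_i}\Big),
  \qquad E_{\mathrm{inst}} = \frac{E}{1 - \sum_i p_i},$$

where $E$ is the long-term (relaxed) modulus stored in the configuration
(default single term $p_1 = 0.1$, $T_1 = 1$ ms). Because the element
stiffness is linear in $E$, each material's stiffness block is assembled
once and rescaled by $E^*(f)/E$ per frequency; this also makes the
elasticity inversion cheap (no re-meshing per objective evaluation).

Solids are axisymmetric (circumferential order $n = 0$) quadrilaterals:
4-node bilinear for the thin flap, 8-node serendipity for the curved globe
tissues, with midside nodes placed on the true spherical surfaces. At the
near-incompressible Poisson ratio 0.499 the volumetric part of the
elasticity tensor is integrated one Gauss order below the deviatoric part
(selective-reduced integration), which removes volumetric locking without
changing the convergence order; a locking guard test compares the
$\nu = 0.499$ flap against $\nu = 0.49$ scaled by the analytic
bending-stiffness ratio. The mass matrix is consistent.

The ocular humours are a lossless acoustic fluid in pressure formulation
(4-node elements), coupled to the tissue through edge integrals
$R = \int N_u\, n\, N_p\, 2\pi r\, ds$; the structural edge shape functions
are quadratic and the pressure interpolation linear on the same geometric
edge, so the mixed-order interface needs no node matching. The coupled
pencil is unsymmetric and every frequency is solved by a direct sparse LU
factorisation of the real $2n \times 2n$ embedding of the complex matrix,
with two steps of iterative refinement (the reciprocity property is tested
to $10^{-10}$). The Table-1 humour viscosity is carried as metadata only:
the acoustic model is lossless and no absorption coefficient is derived
from it.

## The two study geometries

**Flap.** A clamped circular flap (diameter 4 mm, thickness 120 µm,
density 1160 kg m⁻³) meshed 27 × 2 = 54 bilinear elements; the mounting
stress (0.67 kPa) acts as a uniform equi-biaxial tension through the
geometric stiffness. The clamp sustains this tension, and it matters: it
roughly triples the fundamental (55 → 165 Hz at the default modulus
14.58 kPa).

**Globe.** A full axisymmetric eye: spherical-cap cornea in two
through-thickness layers with independent anterior/posterior moduli
(24.8/19.8 kPa), a limbal wedge, a scleral shell (diameter 19 mm) and the
humour fluid. The corneal anterior edge lies on the scleral sphere by
construction, so the three tissues join smoothly; the limbus interpolates
the corneal edge cross-section into the scleral shell. Tissue element
counts follow the reference discretisation (80 cornea, 12 limbus, 182
sclera; 1233 fluid). The globe is held by a fixed ring of 1 mm width on
the outer sclera, 5 mm (arc length) from the posterior pole. The scleral
shell thickness is not among the published parameters; it is fixed at
1.0 mm, continuous with the ~1.0 mm peripheral corneal thickness implied
by the two corneal radii of curvature.

## Design choices in ambiguous territory

Several published parameter values are internally inconsistent, and some
modelling details are undocumented. The package fixes them as follows; all
alternatives stay reachable through the configuration.

* **Scleral stiffness.** The parameter table prints 79.2 kPa, but the
  results section explicitly calls 744 kPa the *normal* scleral elasticity
  (with 74.4 kPa as the *low* variant). With 79.2 kPa every globe mode is
  60–80 % sclera-dominated and corneal elasticity barely moves the
  spectrum, contradicting the reported cornea-dominated mode shapes and
  elasticity sensitivities; the default is therefore 744 kPa. The printed
  low value reproduces the reported extra low-frequency sclera resonance.
  The limbus stays at its printed 37.2 kPa — a compliant hinge ring
  between cornea and sclera, which concentrates the corneal modes'
  strain energy in the cornea.
* **Humour domain.** Fluid–structure interaction is stated to act within
  2.8 mm of the tissues, and the fluid element budget matches a 2.8-mm
  layer lining the eye coat (9 rings × 137 columns = 1233). The default
  humour model is therefore that coupled layer, terminated by a
  pressure-release surface towards the deep humour. The alternative closed
  cavity (`fluid_region = "cavity"`) adds a compressibility stiffness to
  every volume-changing mode; with it, the summed elasticity exponents of
  the natural frequencies drop to ≈ 0.25, whereas the reported elasticity
  and sclera sensitivities imply exponents summing to ≈ 0.5 (purely
  elastic stiffness scaling) — which the layer model reproduces.
* **IOP prestress.** A homogeneously distributed initial stress equal to
  the IOP self-equilibrates in a nearly free body: it converts into
  deformation and leaves a vanishing residual stress, so it contributes no
  geometric stiffness to the harmonic operator. Consistently, the reported
  IOP dependence of the natural frequencies is 0–0.14 Hz mmHg⁻¹. Retaining
  the full stated stress as a stiffening state instead produces
  1.3–4.5 Hz mmHg⁻¹ — twenty times the reported ceiling — and a static
  equilibrium solve under IOP pressure loading (membrane stresses
  ≈ pR/2t ≈ 9–13 kPa) is stronger still. The globe default is therefore
  `prestress = "none"`; `"uniform"` and `"static"` are implemented and
  unit-tested (tension raises frequencies; the static solve pushes the
  apex outward). The flap keeps its mounting tension: its clamp sustains
  the stress, so no equilibration argument applies.
* **Excitation.** The sound field is described as forcing every node at
  the drive frequency, i.e. a rigid-frame inertial drive; that is the
  default (`excitation = "base"`, load $\Omega^2 [M]\,\hat z$ in the frame
  of the mount). A uniform pressure on the anterior surface is available
  as `excitation = "pressure"`; detected peak frequencies agree within
  0.5 % between the two (a tested property), but pure pressure loading
  suppresses the higher harmonics' amplitudes ($\propto 1/\Omega^2$
  relative), pushing the third flap peak below the default 5 % prominence
  threshold although it is plainly present in the response.
* **Damping scope.** The Prony term applies to all tissues by default
  (`prony_all_tissues`); a purely elastic sclera produces implausibly
  sharp sclera-dominated peaks.
* **Units.** Configurations use the field's bench units (mm, µm, kPa);
  everything internal is strict SI. Elasticity sensitivity slopes are
  reported in Hz kPa⁻¹ (a literal Pa⁻¹ reading of the reference slope
  table would imply > 10⁴ Hz shifts over a ±20 % sweep, four orders off
  the plotted responses).

## Response analysis

`frf_sweep()` performs one solve per grid point (grid steps restricted to
the validated 1–50 Hz range) and can refine locally around detected peaks
down to 1 Hz. `find_peaks()` selects local maxima by topographic
prominence (default 5 % of the global maximum), refines each peak by
three-point quadratic interpolation and reports half-prominence widths.
`classify_mode()` counts zero crossings of the phase-aligned real part of
the vertical displacement along the anterior corneal arc — the
nodal-circle count of the axisymmetric harmonic — and computes scleral
participation as the scleral share of the mass-weighted deformation
energy (modes below 0.2 are flagged cornea-dominated). Crossing counting
masks samples below 10⁻³ of the arc maximum so numerical noise near nodes
does not create spurious circles.

Parameter sweeps (`sensitivity_sweep()`) rebuild the model at each level
(default ±20 %, 5 levels) and track modes across levels by an
order-preserving alignment that penalises nodal-circle mismatches
(`pair_modes()`), not by raw peak index; lost modes are recorded as
missing. Slopes are ordinary least-squares fits of peak frequency versus
parameter value.

## Elasticity inversion

`fit_elasticity()` minimises the sum of squared differences between
simulated and observed resonance frequencies over the corneal long-term
modulus — amplitudes deliberately do not enter, matching the analysis
protocol of the measurements. The simulated peak list is recomputed per
candidate modulus by rescaling the corneal stiffness blocks; observed and
simulated sets are paired by mode order with a sliding-window alignment
when the counts differ (missing simulated peaks are penalised). Because
detected peak counts change discontinuously with the modulus, the
objective has plateaus; a coarse 8-point scan brackets the basin before
Brent refinement (convergence tolerance 0.05 kPa). A fit on the bounds, or
a peak-count mismatch at the fitted modulus, is an error, not a result.
The retrieval uncertainty propagates the frequency resolution of the
observations through the most responsive matched mode,
$\sigma_E = \Delta f / \max_k |df_k/dE|$ with slopes from a ±2 % finite
difference; this is one plausible reconstruction of the published
30 % uncertainty at a 40 Hz step, whose exact derivation is not stated.

## Synthetic data and the measurement pipeline

`make_records()` turns the forward model's apex response into displacement
time series (48 kHz sampling, default 20 drive periods) with optional
common-mode reference motion, second-harmonic loudspeaker contamination
(default 10 %) and seeded additive Gaussian noise; `make_noisy_frf()`
applies multiplicative log-normal noise to the FRF amplitudes
(displacement noise is additive in phase-sensitive OCT; amplitude spectra
are positive). `extract_amplitude()` subtracts the reference trace,
truncates to an integer number of drive periods and projects onto
cos/sin at the known drive frequency — identical to the DFT bin on an
integer-period window, exact for a pure tone on any window, and immune to
start phase, DC offset and higher harmonics. Records travel in a flat CSV
container (`record, f_hz, fs_hz, pos_m, t_s, displacement_m`, reference
rows flagged by `pos_m = NA`).

What the generator does *not* emulate: OCT speckle and phase wrapping,
drift of the specimen during acquisition, spatially varying noise, or
amplitude calibration against sound pressure. Passing tests therefore
demonstrate correctness of the processing chain and invertibility of the
model under the stated noise models, not robustness to every artefact of
real acquisitions.

## Numerical choices and degenerate inputs

Direct solves refuse exactly singular systems (an undamped solve exactly
at an eigenfrequency) with advice to add damping or offset the frequency.
Degenerate element geometry fails assembly naming the element; meshes are
validated for positive Jacobians at all quadrature points (the polar fan
of collapsed quads at the humour centre in cavity mode keeps positive
Jacobians at the interior Gauss points). Mesh generation is arithmetic
only — the same configuration reproduces the identical mesh bitwise.
Weak zones that select no corneal element are an error; a zone whose
modulus equals the local value is a no-op that leaves the model untouched.

## Problem sizes used by the test-suite and acceptance runs

The flap model is 54 elements (~160 free dofs); its full 50–750 Hz sweep
at 5 Hz runs in under a second. The globe model is 1507 elements
(~3 400 free dofs, ~0.14 s per frequency), so globe-heavy studies use a
5 Hz grid with 1 Hz local refinement around peaks, which resolves peak
positions to the same 1 Hz as a uniform fine grid at a tenth of the cost.
The Monte-Carlo robustness studies (noise on synthetic records, noisy-FRF
fits) use 8–40 replicates; mesh-convergence checks quadruple the flap
element count. The elasticity inversions converge in ~20 objective
evaluations.

## Known limitations

The model is strictly axisymmetric: decentred keratoconus cones, fibril
anisotropy and non-symmetric holder contact are out of reach. Material
behaviour is linear (small-strain) by construction of the harmonic
analysis. The acoustic fluid is lossless; viscous absorption in the
humours is not modelled. Amplitudes are reported in consistent but
arbitrary units — only natural frequencies and mode shapes are
quantitative. Where the published parameter set is self-contradictory the
package commits to the reconstruction above; the alternative readings
remain one configuration flag away, and the globe mode count in
50–510 Hz (eight detected resonances at default prominence, versus five
reported) is the one simulation-level statement this reconstruction does
not reproduce.
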