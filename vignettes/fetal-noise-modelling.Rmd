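---
title: "Modelling in-utero exposure to airborne sound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling in-utero exposure to airborne sound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fetalsound)
```

## The problem

External airborne noise reaches the fetus through the maternal abdomen. The
question this package addresses is quantitative: for a unit-amplitude plane
wave in air incident on the abdomen, what sound pressure level arrives
inside the uterus, band by band across the human audio range
(20 Hz–20 kHz)? The answer is computed as a time-harmonic Helmholtz
transmission problem across piecewise-homogeneous acoustic regions — air,
abdominal soft tissue, uterine content, spine — separated by closed
triangulated interfaces, solved with a boundary-element method and
summarised by exposure metrics over the uterine volume.

Subject-specific anatomies are outside the scope of this package; instead
it provides phantoms at anatomical scale, centred on the concentric-sphere
configuration used to validate the solver: an outer sphere of radius
0.25 m ("abdomen") and an inner sphere of radius 0.15 m ("uterus") in an
air exterior.

## Material model

Each region is a homogeneous fluid with equilibrium sound speed $c_0$,
density $\rho$ and a power-law attenuation anchored at 1 MHz,
$$\alpha(f) = \alpha_\mathrm{ref}\,(f/10^6\,\mathrm{Hz})^b,\qquad
b \in \{1, 2\},$$
linear in frequency for soft tissue and bone and quadratic (water-like)
for amniotic fluid. The constants shipped in `tissue_library()` are:
abdominal tissue (1489 m/s, 950 kg/m³, 0.1 Np/m, $b=1$), spine bone
(4020, 2700, 0.2, 1), uterine tissue (1500, 1000, 585.3, 1), amniotic
fluid (1500, 1000, 15·10⁻³, 2), plus a lossless air exterior
(343 m/s, 1.2 kg/m³ — standard values; air absorption is negligible over
these path lengths). Uterine tissue and amniotic fluid bracket the
uterine content as high- and low-attenuation bounds.

For muscle-like tissue the attenuation can alternatively be derived from a
viscoelastic loss tangent: with $\delta = \arctan(\tan\delta)$,
$$\alpha(f) = \frac{2\pi\sqrt{\cos\delta}}{c_0}\,
  \sin\frac{\delta}{2}\, f .$$
Evaluating this at $c_0 = 1500$ m/s, $\tan\delta = 0.3$ (human muscle near
100 Hz) and 1 MHz gives 595.3 Np/m, close to but not identical with the
tabulated 585.3 Np/m; the library keeps the tabulated constant and exposes
the loss-tangent path separately (`loss_tangent_attenuation()`).

**Sign convention.** With the time factor $e^{-i\omega t}$, a forward
plane wave is $e^{ikx}$ and dissipation requires $\mathrm{Im}\,k > 0$:
`wavenumber()` returns $k = 2\pi f/c_0 + i\,\alpha(f)$. Some texts write
the conjugate convention; the package enforces decay-along-propagation,
which is unambiguous physically, and the tests assert it.

## Phantoms, meshes and evaluation grids

`icosphere()` builds watertight spheres (subdivided icosahedra projected
onto the sphere); `nested_sphere_phantom()` assembles the two-sphere
validation topology. Mesh density follows the elements-per-wavelength
rule: the target mean edge length is $\lambda/n_\mathrm{epw}$ with
$\lambda$ taken in the adjacent medium with the *smaller* sound speed (air
controls the outer interface, tissue the inner one). Two numerical details
matter:

* **Geometric floor.** Icosphere subdivisions quantise the density in
  factors of two, and at low frequency the wavelength rule alone would
  permit very crude spheres (a bare icosahedron encloses only ~61% of the
  sphere volume). The generator therefore never goes below 2 subdivisions
  (320 triangles), which keeps the enclosed volume within ~1.5% of the
  true sphere. Because of this floor the wavelength rule can never demand
  a mesh the generator refuses.
* **Achieved density.** Projection onto the sphere stretches some edges,
  so a nominal 5 elements per wavelength yields an *achieved* mean density
  of ~4.6; `mesh_wavelength_audit()` reports the achieved value, and
  assembly warns below 4 — the 4-to-5 band is the solver's documented
  sufficiency range, which the validation results below confirm.

Exposure metrics are evaluated on an axis-aligned Cartesian grid inside
the uterine surface (`interior_grid()`; default spacing = region
diameter/20, giving $O(10^3)$ points). A point is kept only if it is
inside the surface (winding number from summed signed solid angles) *and*
no single boundary triangle subtends more than 0.5 steradian at it —
boundary-element field evaluation degrades element by element near a
surface, so the exclusion is interpreted per triangle (the maximum over
triangles), a documented choice where a cumulative construction would
also have been defensible. The same 0.5-sr rule flags unreliable points
in `evaluate_field()` and in field maps.

The "barycentre" used for the point response is the centroid of the
enclosed volume (divergence theorem over the surface), not a vertex mean,
so it does not depend on mesh grading.

## The analytical reference: layered-sphere series

For concentric spheres the transmission problem has a classical
separation-of-variables solution. The incident wave is expanded as
$e^{ikz} = \sum_n (2n+1) i^n j_n(kr) P_n(\cos\theta)$; each region carries
regular ($j_n$) and outgoing ($h_n^{(1)}$) radial terms, and at every
interface continuity of pressure and of normal velocity
$(1/\rho)\,\partial p/\partial r$ yields an independent $2L{\times}2L$
system per order, solved with column equilibration (the spherical Bessel
functions $y_n$ span hundreds of orders of magnitude at low $ka$).
The truncation order is $\lceil k_\mathrm{max} R_1\rceil + 12$
(a Wiscombe-style margin; about 104 orders at 20 kHz); results change by
less than $10^{-6}$ when 8 further orders are added. Complex arguments
(lossy media) are handled by downward recurrence with rescaling for
$j_n$ and upward recurrence for $y_n$; at audio frequencies
$|\mathrm{Im}(kr)| \lesssim 2$, so the $h_n = j_n + i y_n$ combination
loses at most one digit to cancellation.

The series implementation is exercised against base R's half-integer
Bessel functions, a closed-form order-0 transmission identity, the
optical theorem in the lossless case, and the long-wavelength limit.

One caveat worth recording: the often-quoted reciprocity of the monopole
transmission coefficient under exchange of the two media does *not* hold
for this quantity (the interface determinant has no exchange symmetry);
the test suite therefore checks the closed-form identity and the energy
balance instead.

## The boundary-element solver

The solver discretises the multi-domain PMCHWT formulation: unknowns per
interface are the pressure trace $\varphi$ and the scaled normal
derivative $w = (1/\rho)\,\partial p/\partial n$, both continuous across
the interface. Writing, for every region $m$ and every ordered pair of
its boundary surfaces, the single-layer $S$, double-layer $D$, adjoint
$D'$ and hypersingular $N$ operators with region wavenumber $k_m$, and a
sign $\varepsilon = +1$ for the region's outer boundary and $-1$ for
children, the blocked system is
$$\sum_m \varepsilon_i \varepsilon_j
  \begin{pmatrix} -D & \rho_m S \\ -N/\rho_m & D' \end{pmatrix}
  \begin{pmatrix} \varphi_j \\ w_j \end{pmatrix}
  = \begin{pmatrix} p^\mathrm{inc} \\ (1/\rho_0)\partial_n p^\mathrm{inc}
  \end{pmatrix}_i ,$$
with the incident terms only on surfaces bounding the unbounded exterior.
Adding interior and exterior Calderón identities cancels all jump terms,
so no identity blocks appear. Sibling sub-regions (e.g. uterus and spine
inside the abdomen) are handled by the same rule.

Discretisation choices (this package's own; a library was not used):

* Continuous piecewise-linear (P1) elements with Galerkin testing.
* The hypersingular operator via the Maue integration-by-parts identity,
  $\langle N\varphi,\psi\rangle = -\!\int\!\!\int G\,
  (\mathrm{curl}_\Gamma\varphi\cdot\mathrm{curl}_\Gamma\psi)
  + k^2\!\int\!\!\int G\, (n_x\!\cdot\!n_y)\,\varphi\psi$,
  so only weakly singular kernels are ever integrated.
* Regular panel pairs: a degree-4 symmetric triangle rule on each panel,
  dropped to degree 2 when the panels are separated by more than four
  summed panel radii (the kernel is smooth there).
* Singular and near pairs (shared vertices, or centroids closer than the
  summed panel radii): the outer integral keeps the regular rule (its
  points are interior, where the inner potential is smooth) and the inner
  integral is split at the closest point of the trial panel to the test
  point into up to three wedges integrated in polar-like (Duffy)
  coordinates, whose radial Jacobian cancels the $1/r$ singularity;
  5 Gauss points per direction by default.
* Solver: GMRES without restart to a relative residual of $10^{-4}$
  within at most 2000 iterations, on the symmetrically equilibrated
  system (the pressure and normal-derivative blocks differ by orders of
  magnitude in physical scale; the diagonal scaling is what makes the
  iteration counts small — 30–70 in the validation runs). A dense LU
  solve is available as a cross-check and agrees to the GMRES tolerance.
* No hierarchical-matrix compression and no on-surface-radiation-condition
  preconditioner: at the problem sizes this package targets (up to a few
  thousand unknowns per frequency, i.e. twelfth-octave bands up to
  ~2 kHz on the validation spheres) dense assembly and unpreconditioned
  GMRES are sufficient. Full-audio-range sweeps use the analytical
  solver.

Correctness is established against oracles rather than against any
reference implementation: a zero-contrast problem reproduces the incident
wave (transparency), the exterior representation of a point source
reproduces itself outside and vanishes inside (null field), GMRES matches
the direct solve, and — the primary check — the full nested solve matches
the analytical layered-sphere series: over all twelfth-octave bands up to
2 kHz at the wavelength-rule density, the inner-sphere RMS SPL differs by
at most ~0.09 dB (bound 0.5 dB) and pressure magnitudes by at most ~5%
(bound 7.5%), errors decreasing monotonically under mesh refinement.

## Frequency sweeps and exposure metrics

`twelfth_octave_grid()` enumerates centres $1000\cdot 2^{n/12}$ Hz inside
[20, 20000] — 119 bands under strict enumeration. (A sometimes-quoted total of
128 for the same range cannot be regenerated from any unambiguous
edge policy; `n_bands` can force a wider grid when matching an external
count matters.) Three quantities are tracked per band, all re 1 Pa so
that 0 dB means "equal to the unit incident wave": the impact SPL
$L_\mathrm{RMS} = 20\log_{10}\sqrt{\tfrac1N\sum_i |p_i|^2}$ (the ISO
10052 spatial-RMS construction — an average exposure over the possible
fetal positions), the worst-case $L_{\ell^\infty} = 20\log_{10}\max|p_i|$,
and the complex barycentre pressure that later drives auralization.
$L_{\ell^\infty} \ge L_\mathrm{RMS}$ always; both shift by exactly
$20\log_{10} g$ under input gain $g$ (the problem is linear). A solver
failure at one band is recorded and the sweep continues — a long sweep is
not lost to one bad band.

On the validation spheres the RMS response is flat near 0 dB at the lowest
frequencies, rolls off smoothly (crossing −6 dB near 500 Hz, reaching
about −10 dB at 1 kHz), and above ~3 kHz develops strong resonances. The
prominent peaks sit at the twelfth-octave bands nearest 3.0, 6.0 and
9.0 kHz — the monopole radial modes of a ~1490 m/s sphere of radius
0.25 m whose air boundary acts as a pressure release
($f_m \approx m\,c/2R$), with a weaker $\ell=1$ mode at 4.2 kHz.
Replacing the amniotic-fluid core by uterine tissue damps every peak, as
expected for the high-attenuation bound. Two properties often expected from anatomical
transmission modelling deliberately do **not** hold on this phantom and
are documented as such: the sphere is *not* within −6 dB of the incident
level all the way to 1 kHz (geometry matters; the claim is anatomical),
and the often-cited upper resonance near 8 kHz does not coincide with
any computed peak of this configuration — the series solution,
cross-checked against an independent implementation, puts the
neighbouring peaks at 6.0 and 9.0 kHz.

`validate_spheres()` packages the whole comparison — per-band remeshing,
BEM and series solves on a common interior grid (built once from the
coarsest inner mesh so that the same points are valid at every band),
resonance-band exclusion, and the 0.5 dB / 7.5% pass bounds. Relative
pressure error is normalised by the largest analytic magnitude in the
band (field-scale), not pointwise, so field nulls do not inflate it.

## Auralization

`build_fir()` turns the complex barycentre response into a causal FIR
filter: spline interpolation of magnitude and unwrapped phase onto a
uniform grid of 16,385 points over [0, 22.05 kHz] (phase is unwrapped on
the coarse twelfth-octave grid *before* interpolation — unwrapping after
interpolation is unstable), multiplication by a 200-sample linear-phase
delay, Hermitian extension to the full circle, and a least-squares fit of
a real impulse response — on a full uniform DFT grid the least-squares
optimum is simply the truncated inverse DFT, so the fit is exact and
fast. The order doubles from 256 until the relative magnitude-spectrum
MSE drops below $10^{-4}$ (cap 8192 taps); an unreachable tolerance is an
error carrying the achieved MSE. Below the lowest sweep band the
magnitude is held constant (the predicted transfer is flat into
infrasound) with phase through the origin; above the sweep the magnitude
rolls off to zero at Nyquist. A flat unit response therefore designs to a
near-delta at sample 200 with a mean group delay of exactly 200 samples
over 100 Hz–10 kHz.

`convolve_audio()` applies the filter to WAV audio (16-bit PCM or 32-bit
float; stereo filtered per channel), peak-normalises to −1 dBFS — the
source loudness handling being unspecified, a fixed headroom with the
gain logged in the sidecar is the reproducible choice — and records the
applied gain.

## Determinism, sizes and limitations

Every command is deterministic given its configuration: there is no
randomness anywhere in the pipeline, and repeated runs produce
byte-identical outputs. The shipped validation problem sizes — interior
grids of ~1.7·10³ points, BEM systems up to ~1.6·10³ unknowns
(twelfth-octave bands to 2 kHz), full-range analytic sweeps of 119
bands — were chosen so the complete validation suite runs on a single
CPU core in minutes while still spanning the mesh densities the accuracy
claims refer to.

What passing the sphere validation does and does not show: it
demonstrates that the material model, the PMCHWT discretisation, the
quadrature and the metric pipeline are correct to the stated bounds on
smooth geometry with realistic impedance contrasts (air/tissue ~3400:1).
It does not by itself certify accuracy on MRI-derived anatomies (sharp
features, thin structures), says nothing about shear-wave conversion in
tissue and bone (the model is purely acoustic), and treats attenuation
constants extrapolated from low-frequency viscoelastic measurements as
exact. The high-/low-attenuation uterine bounds are the model's own
hedge against that last uncertainty.
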