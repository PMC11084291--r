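---
title: "Methods: desk-scale haemodynamics of an LVAD outflow-graft anastomosis"
author: "graftflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale haemodynamics of an LVAD outflow-graft anastomosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftflow)
```

## Scope and intent

`graftflow` models, at the lumped-parameter ("0D") level, the haemodynamic
environment created when a HeartMate III (HMIII) left ventricular assist
device ejects into the aorta through a 14 mm outflow graft (OG). The package
covers the full desk-scale chain around that problem: synthesis of the two
inlet waveforms (the pump's artificial pulse and the residual native cardiac
cycle), estimation and solution of three-element Windkessel (RCR) outlet
models, a mass-conserving single-node simulation of the aortic flow network,
parametric enumeration and meshing of anastomosis geometries, the standard
near-wall and field metrics (TAWSS, OSI, vorticity, TKE, viscous energy
loss, reverse-flow indices), and Richardson-extrapolation grid-convergence
(GCI) analysis. Three-dimensional Navier–Stokes/RANS simulation is
deliberately out of scope: where a full CFD study computes spatially
resolved fields, this package computes the 0D surrogate and provides the
metric machinery, verified against analytic fixtures with known closed
forms.

Blood is treated as an incompressible Newtonian fluid with dynamic
viscosity 0.004 Pa s and density 1060 kg/m³ (`blood_properties()`). All
internal computation is SI; mmHg appears only at reporting boundaries, with
the conversion fixed at 133.322 Pa/mmHg.

## Inlet waveforms

Both inlets are represented as truncated Fourier series

$$V(t) = a_0 + \sum_{n=1}^{8} a_n \cos(n\omega t) + \sum_{n=1}^{8} b_n \sin(n\omega t),$$

with eight harmonics by default. Fitting (`fit_fourier()`) is ordinary
least squares on the design matrix of sines and cosines rather than an FFT,
so non-uniform sampling is supported; on a uniform grid covering one full
period the trigonometric columns are orthogonal to the intercept and the
fitted $a_0$ equals the sample mean — which is why the cycle mean of every
generated waveform is preserved exactly by its Fourier representation.

**Artificial pulse.** The HMIII controller modulates its set speed in a
fixed 2 s cycle: −2000 rpm for 0.15 s, then +4000 rpm *from the reduced
speed* for 0.2 s, then the set speed for 1.65 s (`pulse_schedule()`,
`hm3_speed()`). The "+4000 from reduced" reading matches published
descriptions of the artificial pulse (net overshoot of +2000 above set
speed); the alternative reading can be expressed through the schedule's
parameters. The published OG flow trace is digitised from echocardiography
and its coefficients are not available, so `og_flow_waveform()` maps speed
to flow by a linear calibration pinned so the cycle mean equals the target
output (6.7×10⁻⁵ m³/s by default). This preserves the two features the
downstream network consumes — the pulse shape and the mean — and is an
explicit modelling choice, not a digitisation.

**Residual native cycle.** The chronic-heart-failure aortic-valve waveform
(≈3.2 L/min in 0.7 s cycles) is likewise unavailable in sampled form.
`native_hf_waveform()` uses a half-sine ejection template with a systolic
fraction of 0.35 — a standard ejection shape with the stated period and
mean; 0.35 is a typical systolic fraction for a 0.7 s cycle. The template's
cycle integral matches the requested output to better than 1% after the
8-term fit (verified by independent quadrature in the tests).

**Valve program.** `inlet_program()` superimposes 5% of the native output
during exactly one native cycle at the start of every fifth pump cycle
(both numbers configurable), or silences the valve entirely for the
AV-closed condition. Gibbs oscillation from fitting the discontinuous speed
schedule is visible as small ripples in the OG series; it does not affect
cycle means and is the expected behaviour of a truncated Fourier
representation.

## Windkessel outlets

Each outlet is a three-element Windkessel: proximal resistance $R_p$,
distal resistance $R_d$, compliance $C$, governed by
$dP_c/dt = Q/C - P_c/(R_d C)$ with inlet pressure $P = P_c + Q R_p$.
`estimate_rcr()` derives branch constants from systemic haemodynamics by
treating the outlets as a parallel circuit: $R_{tot} = \mathrm{MAP}/CO$,
$R_i = R_{tot}/f_i$ for flow fraction $f_i$, split
$R_{p,i} = 0.07\,R_i$ / $R_{d,i} = 0.93\,R_i$, and
$C_i = f_i\,C_{tot}$.

Design choices here, made once and kept:

* **Proximal fraction 0.07.** Inverting the shipped seven-outlet table
  gives $R_p/(R_p+R_d) \in [0.0699, 0.0703]$ for every row, so 7% is the
  evident construction; the derivation behind the published table is not
  otherwise available.
* **Total compliance.** The default $C_{tot} = 1.117\times10^{-8}$ m³/Pa is
  the sum of the shipped table's compliances; the distensibility route
  ($C_{tot} = D \cdot V_{ref}/133.322$ with $D = 7.9\times10^{-3}$ mmHg⁻¹)
  is kept as the documented alternative, with the reference volume
  back-computed (≈189 mL) so the two defaults agree. The printed
  distensibility unit is ambiguous ("mm/Hg"); it is treated as a relative
  distensibility per mmHg.
* **Default flow fractions** are the conductance shares of the shipped
  table (`hm3_outlet_fractions()`, descending aorta ≈ 0.51); fractions are
  an explicit input for anyone preferring area-based or literature splits.

The shipped table is internally consistent: its parallel resistance is
within 1% of MAP/CO at the stated operating point (73 mmHg, 6.7×10⁻⁵ m³/s),
and `estimate_rcr()` fed with the inverted fractions reproduces each
printed $R_p$ to ~1%.

## The 0D aortic network

`simulate_network()` collapses the aorta to a single pressure node — the
rigid-wall assumption of the underlying flow problem means the only stored
compliances are the outlet capacitors, making the single-node collapse the
faithful desk-scale surrogate. At every derivative evaluation the node
pressure is eliminated algebraically,

$$P = \frac{q_{in} + \sum_i P_{c,i}/R_{p,i}}{\sum_i 1/R_{p,i}},
\qquad q_i = (P - P_{c,i})/R_{p,i},$$

so $\sum_i q_i = q_{in}$ holds to machine precision at every step — mass
conservation is structural, not approximate.

Numerical choices: classical fixed-step RK4 at $dt = 10^{-3}$ s (the time
step must divide the cycle evenly; the capacitor time constants are
0.1–1.5 s, so the scheme is far from its stability limit and halving the
step changes cycle-mean pressure by < 0.01%). Periodicity is declared when
the relative L2 distance between consecutive cycles of node pressure falls
below 10⁻³ — the repeating-pattern check used for periodic unsteady
simulations; the default pulsatile program converges in about 5–9 cycles
from cold start (the outlet time constants give roughly one decade of
transient decay per 2–3 cycles). Non-finite states abort with the failing
step and a smaller-step suggestion.

The mapping from this single node to a spatially averaged wall pressure in
a 3D simulation is a surrogate relationship, not an equivalence: the 0D
model reproduces operating points and cycle-mean flow splits, not spatial
gradients.

## Anastomosis geometry

Coordinates are right-handed patient coordinates: axial axis +z, coronal
plane x–z, sagittal plane y–z. The default `aorta_model()` is an idealised
Type-I candy-cane (straight ascending segment, semicircular arch in the
coronal plane, straight descending segment, 12.5 mm lumen radius), because
patient imaging is not among the package's inputs; all measurements are
defined against the model's own axial axis.

A placement (`anastomosis_params()`) is the distance $d$ from the
ventriculo-arterial junction measured between two parallel axial planes
(one through the junction, one through the graft ostium center), the
cardinal side (coronal/sagittal), and the angle between the graft axis and
that side's anatomical plane. The angle vertex convention — genuinely open
in the source material — is: the graft axis lies in the transverse plane,
tilted out of the named plane by the requested angle. `build_geometry()`
sweeps the aortic tube with parallel-transported frames and attaches an
open graft cylinder; no boolean union is performed (watertight CSG buys
nothing for parameter measurement or STL export and would be a heavy
dependency), so the junction is two labelled open tubes.

`measure_parameters()` never trusts the build inputs: it re-derives the
anatomical frame from the mesh itself (axial axis from the ascending ring
centroids, coronal normal from a plane fit through all ring centroids),
least-squares fits a cylinder to the graft vertices (PCA initialisation,
BFGS refinement of axis and center minimising the radial-distance spread),
and classifies the side from the ostium's radial direction. Because the
frame comes from the mesh, recovered parameters are invariant under rigid
motions; a straight-tube aorta leaves the arch plane — hence the side —
undefined, and is reported as `"ambiguous"` rather than guessed. Round-trip
accuracy on all 15 default configurations is well inside 0.5 mm and 0.5°,
and the fitted graft diameter reproduces 14 mm to ±0.1 mm.

The default enumeration — distances {45, 50, 55} mm, coronal angles
{35, 45, 55}°, sagittal angles {45, 55}° — gives the 15 configurations of
the comparative design. The distance triplet is the exercised set within
the stated 50 ± 10 mm admissible range; the full range remains valid
input.

## Field metrics

The source material defines TAWSS and OSI in words; the standard formulas
are adopted:

$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\boldsymbol\tau|\,dt,
\qquad
\mathrm{OSI} = \frac{1}{2}\left(1 -
  \frac{|\int_0^T \boldsymbol\tau\,dt|}{\int_0^T |\boldsymbol\tau|\,dt}\right),$$

with trapezoidal quadrature in time. OSI is clamped to [0, 0.5]; points
with zero cumulative shear are defined as 0 and counted in an attribute
rather than raising an error. TKE uses the resolved-fluctuation ensemble
definition $k = \tfrac12\langle|\mathbf u'|^2\rangle$ and is labelled as
such — whether a RANS solver's modelled $k$ would match is left open.

The viscous energy loss formula is stated in the source as a time integral
of $\tfrac{\mu}{2}\sum_{i,j}(\partial_j u_i + \partial_i u_j)^2$ with no
explicit volume integration; it is interpreted here as a dissipation
density integrated over both the sampled volume (via the per-point
measures) and the time window, giving joules. Gradients use second-order
central differences on structured grids, with second-order one-sided
stencils at boundaries (exact for quadratic fields — deliberately, since
the Poiseuille fixture is quadratic); unstructured gradient reconstruction
is out of scope. Section flow rate and reverse-flow indices operate on
grid-aligned slices, with per-point areas derived from the volume measures
so masked cells are excluded.

## Synthetic fixtures

`make_poiseuille()`, `make_solid_rotation()`, `make_oscillating_wss()` and
`make_noisy_waveform()` generate every input the metric modules need, each
carrying its closed-form expectations in an attached manifest — tests
compare computed metrics only against these manifests, never against
numbers typed into the tests. Design notes:

* The Poiseuille fixture stores the *unclamped* parabola with the lumen
  carried entirely in the quadrature weights (sub-sampled cell coverage
  fractions of the disc). Finite differences of the stored field are then
  exact, and the only discretisation error in integrated quantities is the
  smooth-density quadrature over the pixelated disc: at 64×64 cells in the
  cross-section, dissipation and flow rate agree with $\Delta P\,Q$ and
  Hagen–Poiseuille to ~0.03%.
* The oscillating-WSS fixture places direction switches on sample times
  with the jump midpoint value, so the discrete vector integral matches
  the piecewise closed form and OSI anchors (0, 0.25, 0.5) are hit
  essentially exactly.
* Randomness (waveform noise) flows through one recorded seed.

What the fixtures do *not* emulate: turbulence, jet impingement, secondary
flow in curved vessels, or any spatial structure of a real post-implant
aorta. Passing tests demonstrate that the metric machinery is correct on
fields with known answers — they say nothing about the clinical magnitude
of any metric in a real patient, which requires 3D CFD.

## Grid convergence

`observed_order()` solves the Richardson relation
$\varepsilon_{32}/\varepsilon_{21} = r_{21}^p(r_{32}^p-1)/(r_{21}^p-1)$
exactly (closed form for equal ratios, `uniroot` otherwise), preserving
the sign of the error ratio: a negative ratio (medium solution outside the
fine/coarse bracket) is oscillatory convergence and is flagged with a
warning instead of being silently absorbed — a published negative order is
a symptom of exactly this situation, and the package surfaces it rather
than reporting a GCI from it. `gci()` uses the standard
$F_s|e|/(r^p-1)$ form with safety factor 1.25 (the usual three-grid
choice; no value is stated in the source). GCI inherits the relative-error
term's scale dependence: it is invariant to rescaling $f$ only through
$|(f_c - f_f)/f_f|$, which the tests pin down. `grid_convergence()`
bundles order, pairwise GCI, Richardson-extrapolated value and the
asymptotic-range ratio $\mathrm{GCI}_{32}/(r_{21}^p\,\mathrm{GCI}_{21})$.

## Problem sizes and determinism

The shipped tests and the acceptance script run, by choice, at: 15-cycle
maximum network horizons at $dt = 10^{-3}$ s (a steady run converges in ~7
cycles, the pulsatile program in ~9), 64×64×8 Poiseuille grids for
dissipation checks, 32–48 segments per meshed circumference, and 400–800
sample Fourier fits. These sizes put every verified quantity well inside
its stated tolerance; larger grids sharpen nothing that the closed forms
do not already pin down. The solver is fixed-step and deterministic:
re-running `run_study()` with the same configuration reproduces summary
files byte-for-byte.

## Known limitations

* The 0D network has no inertance, no vessel compliance between inlets and
  outlets, and no wave propagation; it reproduces operating points, not
  waveform morphology along the aorta.
* The OG flow shape is a calibrated speed schedule, not a digitised
  echocardiographic trace; harmonics above the eighth are discarded.
* Geometry is idealised and the graft axis convention is one of several
  defensible readings (configurable, and documented above).
* Field metrics require structured grids; the package does not ingest
  unstructured CFD exports.
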