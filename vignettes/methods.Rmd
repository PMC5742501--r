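---
title: "Modelling double-slot coaxial microwave ablation with mwablate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling double-slot coaxial microwave ablation with mwablate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mwablate)
```

## The physical problem

A microwave ablation applicator for breast tumours is a semirigid
microcoaxial cable (here UT-085-class: conductor diameters
0.51 / 1.68 / 2.197 mm) whose outer conductor carries two ring slots near a
short-circuited tip, the whole sheathed in a 2.64 mm PTFE catheter. Driven
at 2.45 GHz (ISM band), the slots act as the radiating apertures; dielectric
heating of the surrounding tissue raises temperatures past the ablation
threshold. Tissue enclosed by the 55 °C isotherm is taken as irreversibly
destroyed (cell death in under a minute at that temperature), so the
quantities that matter to an antenna designer are the maximum temperature,
the radius of the 55 °C contour, and the standing wave ratio
$\mathrm{SWR} = (1+|\Gamma|)/(1-|\Gamma|)$ at the feed, which measures how
much power reflects instead of heating tissue (and produces undesired
"backward heating" along the shaft when poor).

The axial layout follows a quarter-wave design rule: with the tumour
permittivity $\varepsilon_r = 59.385$,

$$\lambda_\mathrm{eff} = \frac{c}{f\sqrt{\varepsilon_r \mu_r}} = 15.88\ \mathrm{mm},$$

and both the tip-to-slot and the slot-to-slot gaps default to
$0.25\,\lambda_\mathrm{eff} \approx 3.97$ mm (`effective_wavelength()`,
`antenna_geometry()`). The published description of this layout is
internally inconsistent — the design-rule statement gives both distances as
$0.25\,\lambda_\mathrm{eff}$ while a figure caption says the slots are
"separated by 5 mm" — and we resolve it by reading the 5 mm as a
centre-to-centre distance: a 3.97 mm gap between 1 mm slots puts the
centres 4.97 mm apart, making both statements true at once. Both gaps
remain user parameters.

## Electromagnetic model

Everything is rotationally symmetric, so the time-harmonic Maxwell problem
reduces to a scalar equation for the azimuthal magnetic field
$H_\varphi(r,z)$ on the $(r,z)$ half-plane (TM axisymmetric formulation),
with complex relative permittivity
$\tilde\varepsilon = \varepsilon_r - j\sigma/(\omega\varepsilon_0)$
(convention $e^{+j\omega t}$, peak phasors):

$$\partial_r\!\Big(\tfrac{1}{\tilde\varepsilon}\tfrac1r\partial_r(r H_\varphi)\Big)
 + \partial_z\!\Big(\tfrac{1}{\tilde\varepsilon}\partial_z H_\varphi\Big)
 + k_0^2 H_\varphi = 0 .$$

**Scaled unknown.** The solver discretises $w = r H_\varphi$, whose weak
form carries a $1/r$ weight and no $u/r$ cross terms. This matters
numerically: the coaxial TEM mode is $H_\varphi \propto 1/r$, i.e. $w =$
constant, which linear elements represent *exactly*. Discretising
$H_\varphi$ directly instead leaves a near-cancellation between the $u/r$
stiffness terms and the mass term that linear elements cannot maintain
inside the narrow coax annulus (we observed spurious exponential decay of
the fed wave); the $w$ form eliminates the cancellation by construction.

**Boundary conditions.**

* *Metal surfaces* (inner/outer conductor, shorting tip) are perfect
  electric conductors. In this weak form PEC is the natural (do-nothing)
  condition; conductors are excluded from the EM domain but kept in the
  mesh for the thermal solve.
* *Coaxial port* (top of the modelled coax): incident TEM mode
  $H_\varphi = C/r$ with $C = \sqrt{P_\mathrm{in}/(\pi Z_d \ln(b/a))}$ so
  the time-averaged incident power equals the requested input power, and a
  matched first-order condition for the outgoing part. The reflection
  coefficient is extracted by modal overlap of the port solution against
  the incident mode; its magnitude is reference-plane-invariant.
* *Exterior boundaries*: first-order absorbing (scattering) condition with
  the local medium's wave impedance. The published settings are ambiguous
  here (a table entry reads "Impedance (Air)" while the text says
  scattering condition); the air-impedance variant is available as
  `exterior_impedance = "air"`, but the medium-impedance condition is both
  the physically sensible absorber and the default.
* *Symmetry axis*: $w = r H_\varphi = 0$.

Element order is linear (P1) on a graded mesh. That is a deliberate choice:
the scaled-unknown formulation already removes the error mode that pushes
coax problems towards quadratic elements, the manufactured-solution test
(an exact Bessel mode $H_\varphi = J_1(kr)$ imposed on the boundary)
confirms the expected second-order $L^2(r)$ convergence, and the port and
thermal quantities change by under 1 % when every element size is halved.

From the solution the per-element fields follow as
$E_r = -\frac{1}{j\omega\varepsilon_0\tilde\varepsilon}\frac1r\partial_z w$,
$E_z = \frac{1}{j\omega\varepsilon_0\tilde\varepsilon}\frac1r\partial_r w$,
the specific absorption rate as
$\mathrm{SAR} = \frac{\sigma}{2\rho}|\mathbf E|^2$ (W/kg, the $1/2$ from
peak phasors), and the power bookkeeping closes: reflected + absorbed +
radiated-through-boundary input power agree to well under the 2 % the test
suite demands.

## Thermal model

The absorbed power density $Q_\mathrm{ext} = \rho\,\mathrm{SAR} =
\frac{\sigma}{2}|\mathbf E|^2$ drives the Pennes bioheat equation on the
same mesh (one-way coupling; material properties are
temperature-independent):

$$\rho c\,\partial_t T = \nabla\cdot(k\nabla T)
 + \rho_{bl} C_{bl}\,\omega\,(T_{bl} - T) + Q_\mathrm{ext},$$

with metabolic heating neglected. The perfusion rate $\omega$ is a
volumetric rate (1/s); the published table lists it as 0.0036 1/s together
with blood density 920 kg/m³ and heat capacity 3639 J/kg/K *among the
conditions used for the simulation*, so the stock scenarios enable the sink
with $T_{bl} = 37$ °C. Setting the rate to zero (or
`run_scenario(..., perfusion = FALSE)`) reproduces the ex vivo condition.
This reading is corroborated numerically: with perfusion the three
scenario maxima land within a few percent of the published 70.6 / 110 /
155 °C, while without it all three come out 15–20 % hot.

Discretisation: linear elements, *lumped* (row-sum) $r$-weighted mass, and
backward Euler with a default step of 1 s over 500 s ("time required for
steady state"). On the right-angled triangles the mesher produces, the
stiffness matrix is an M-matrix, so lumped mass + implicit stepping obey a
discrete maximum principle — nodal temperatures never undershoot the
initial/boundary minimum, which the suite asserts. All exterior boundaries
are held at 25 °C (the published condition; also the uniform initial
state), the axis is zero-flux, and one sparse Cholesky factorisation is
reused across all time steps. Halving the time step moves the 500 s maximum
temperature by well under 0.5 %.

Two thermal constants the published property set does not include are the
breast/tumour density and heat capacity; we use 1000 / 1050 kg/m³ and
3000 / 3600 J/kg/K from standard tissue-property literature. They deserve
little anxiety: the 500 s state is near steady, and the steady field
depends on $k$ and $Q_\mathrm{ext}$ only (density cancels out of
$\rho\cdot\mathrm{SAR}$), so these defaults shape the transient approach,
not the reported maxima. No phase change is modelled: reported temperatures
above 100 °C are to be read as the model's extrapolation, exactly as in the
source simulations.

## Geometry, mesh, and the numbers that matter

The domain is a $30 \times 80$ mm $(r,z)$ rectangle of tissue with the
antenna inserted from the top along the axis, slots at mid-height; the
tumour scenario adds a 12.5 mm-radius sphere (a semicircle in the
half-plane) centred on the slot pair. Domain extents are not printed in the
source (they appear only in a scale figure); the defaults keep the 55 °C
isotherm several conduction lengths from every exterior boundary, which we
verify in the reports. Construction details the source omits — the axial
extent of the shorting metal at the tip (0.5 mm), a 0.5 mm catheter cap
below it, and what fills the slot cut (air by default, PTFE via
`slot_fill`) — are parameters; the port quantities move by only a few
hundredths of SWR across their plausible ranges.

The mesher (`generate_mesh()`) builds a graded tensor-product
triangulation: every straight material interface (the four conductor/
dielectric/catheter radii, slot edges, tip, cap) is a grid line, so those
interfaces coincide with element edges exactly; the curved tumour boundary
is handled by a ~0.6 mm refinement band with centroid tagging. Sizes grade
from ~0.2 mm at the annuli and slots up to `h_max` (default 2 mm, safely
below a quarter of the 2.1 mm-wavelength-per-4 rule for the lossiest
tissue), giving ~7–9 k elements — the same order as the source model's
12 135 — and a 2–4 s harmonic solve. `refine` scales every target size for
convergence studies.

## Synthetic measurement models

Three emulators stand in for the study's measured inputs so that
validation-style analyses are testable without hardware; they are
statistical stand-ins, not fits to any measured spectrum.

* `dispersion_model()` — per-tissue dielectric curves, linear in
  log-frequency, anchored *exactly* at the 2.45 GHz values (tumour
  59.385 / 3.156 S/m, breast 5.1467 / 0.137 S/m) with permittivity
  decreasing and conductivity increasing over 2–3.5 GHz, the qualitative
  shape of measured tissue spectra. Slopes are plausible, not contractual;
  only the anchors and monotonicity are.
* `sample_properties()` — subject-to-subject variation as a
  mean-preserving multiplicative log-normal with coefficient of variation
  `cv` ($\sigma_{\ln} = \sqrt{\ln(1+cv^2)}$, mean offset $-\sigma_{\ln}^2/2$);
  `cv = 0` returns the anchors exactly, and draws are reproducible under an
  explicit seed (no global RNG state is touched).
* `simulate_probe()` — fibre-optic probe readings: first-order lag with a
  0.25 s response time (integrated exactly for piecewise-constant input),
  additive Gaussian noise, clipping to the 0–120 °C probe range, and
  quantisation to the thermometer's 0.01 °C resolution.

What passing these tests shows about real data is deliberately limited:
real tissue spectra have Cole–Cole structure, spatial heterogeneity and
temperature dependence that the emulators do not attempt.

## What the package reproduces, and what it does not

`reproduce_benchmarks()` runs the three stock scenarios (breast-only 10 W,
tumour 10 W, tumour 15 W, 500 s each) and tabulates computed values against
the published simulation results, printing both the narrative values and
the alternative ones the source's summary table carries (4.2 vs 5 mm,
11.2 vs 11.17 mm). On the default mesh the computed wavelength, tumour-case
SWR (1.86 vs 1.87), all three maximum temperatures (within 2–9 %) and both
lesion radii land inside the tolerance the source values support
(temperatures ±10 % given the unpublished density/heat-capacity pair,
SWR ±0.15, radii ±1–1.5 mm), including the qualitative contrast that 10 W
fails to ablate the full 12.5 mm tumour while 15 W covers it.

The one disagreement is the breast-only SWR: our converged model gives
1.61 where the source reports 1.84. The value is insensitive to every
ambiguous construction detail we probed (slot fill, tip metal length,
insertion depth, domain size, either exterior-impedance reading, either
slot-layout reading), and our breast-only SWR curve does pass through 1.84
slightly below 2.45 GHz, so a modest frequency-scale offset between the two
models would explain the difference. We report the model's own number
rather than adjust geometry to chase the published one; the corresponding
acceptance test is left failing by design. It is worth noting the published
pair — breast 1.84 barely below tumour 1.87 — is itself physically
surprising given the tenfold permittivity step at the slots.

Experimental results from the source study (90 °C in ex vivo swine tissue,
SWR 1.04 after stub-tuner matching, 4.3 mm lesion) involve hardware and
matching networks outside a simulation's reach and are not reproduction
targets.

## Numerical choices and degenerate inputs

* Complex linear systems are solved as the equivalent real $2n \times 2n$
  block system with a sparse LU (`Matrix`); the thermal system with one
  sparse Cholesky reused across steps. Everything is deterministic: an
  identical configuration reruns bit-identically.
* $1/r$ integrals use centroid quadrature; axis-adjacent singular entries
  fall on Dirichlet rows and never enter the solve.
* Isotherms are linear edge interpolants; the lesion radius is the maximum
  $r$ over isotherm points *and* supra-threshold nodes (so a contour
  clipped by the domain cannot shrink the measure), and is 0 exactly when
  no node reaches the level.
* Probe traces use barycentric interpolation (exact for linear fields and
  at nodes); positions outside the domain are errors, as are scenarios
  whose tumour does not fit the domain, slots outside the inserted length,
  non-positive thermal parameters, reflected power exceeding input, and
  $|\Gamma| \ge 1$ handed to the SWR map.
* Empty isotherms, zero sources and zero perfusion are valid inputs, not
  errors; `reflection_db(p, 0)` returns `-Inf` by convention.

## Problem sizes used in the test suite

The suite runs the full scenarios at the default mesh (~7–9 k elements,
500 × 1 s steps, a few seconds each, shared across test files via a
memoised fixture), the manufactured-solution pair at 16/32 radial cells,
and the convergence checks at `refine = 2` (~29 k elements). These sizes
put every reported quantity in its converged regime as shown by the
refinement tests themselves.

## Worked example

```{r example, eval = FALSE}
library(mwablate)

scn <- build_scenario("tumor_in_breast") # 12.5 mm tumour, 10 W, 2.45 GHz
run <- run_scenario(scn) # mesh -> EM -> SAR -> bioheat -> lesion
glance(run)
#>   kind  input_power  swr   t_max  lesion_radius ...
#>   tumor_in_breast 10 1.86  112.2  10.6

autoplot(run$sar) # SAR map
plot_temperature_field(run) # 500 s temperature field
autoplot(run$lesion$isotherm) # 55 C contour

mesh <- run$mesh
sweep <- frequency_sweep(mesh, scn, 2e9, 3.5e9, 31)
autoplot(sweep) # SWR across the band

reproduce_benchmarks() # full comparison table
```

## Known limitations

One-way EM→thermal coupling with temperature-independent properties (the
source's own stated limitation); no phase change or water vaporisation
above 100 °C; no thermal-dose model beyond the 55 °C criterion; 2D
axisymmetry excludes bent applicators and off-axis tumours; the structured
mesher trades boundary-fitted tumour elements for a refinement band; and
the synthetic dispersion/probe models are qualitative emulators, not
instrument calibrations.
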