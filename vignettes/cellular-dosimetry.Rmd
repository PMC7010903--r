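---
title: "Cellular dosimetry of Lu-177 radiopharmaceuticals in vitro: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular dosimetry of Lu-177 radiopharmaceuticals in vitro: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldose)
```

## The problem

Clonogenic survival after exposure to a beta-emitting radiopharmaceutical
such as ^177^Lu-DOTATATE is usually reported against the *added* activity
(MBq/ml), which says little about the physical dose the cell nucleus
actually received. `celldose` converts an in vitro exposure — a 4-h uptake
phase followed by a 6-day colony-forming follow-up — into absorbed dose to
the nucleus using the MIRD formalism,

$$D(N) = \tilde{A}_M\,S_{N \leftarrow M} + \tilde{A}_{CS}\,S_{N \leftarrow CS}
       + \tilde{A}_C\,S_{N \leftarrow C},$$

where $\tilde{A}$ are cumulated activities (Bq·s) in the medium (M), on the
cell membrane (CS) and inside the cell (C, either cytoplasm or Golgi), and
$S_{N \leftarrow X}$ is the absorbed dose to the nucleus per decay in
compartment $X$. The package provides every stage: electron emission
physics, cell geometry, a Monte Carlo S-value engine, time–activity
kinetics, dose assembly over the experiment, and linear / linear-quadratic
dose–response fitting with AIC selection. A synthetic-data generator
reproduces the statistical structure of the gamma-counter measurements so
the whole pipeline is testable end to end without any external data.

## Electron emissions and stopping power

The packaged ^177^Lu electron table is a compiled approximation: three
dominant beta branches (endpoints ≈ 498, 385 and 177 keV) whose spectral
shapes are computed with the allowed-shape Fermi approximation, plus the
main internal-conversion and Auger lines. Its mean emitted electron energy
per decay is Δ ≈ 147 keV, computed by quadrature at load time. Sampling
starts at a configurable low-energy cutoff (default 3.8 keV); electrons
below it travel well under a micrometre in water and are excluded from both
sampling and Δ. Any consistent compilation can be swapped in as a CSV
(`load_emission_spectrum()`).

Collisional stopping powers for water come from the relativistic Bethe
formula with a mean excitation energy of 78 eV and no density-effect
correction (negligible below ~1 MeV); spot checks against standard
tabulations agree to about 1% at 10–500 keV. The CSDA range is the integral
of $1/S(E)$; the cell-membrane lipid (0.92 g/cm³) is the density-scaled
water table. The nucleus is treated as water, a documented few-percent bias
relative to tissue-composition tables.

## Transport model

The engine uses straight-line continuous-slowing-down (CSDA) transport:
an electron travels along its emission direction, losing energy at the
collisional stopping-power rate, and stops at its CSDA range. There is no
multiple scattering, no energy-loss straggling and no delta-ray production —
the approximation used by MIRD-style cellular S-value calculations. The
energy deposited in the nucleus along a track is the difference of residual
energies at the chord entry and exit points, obtained by range–energy
inversion; for triangle-mesh nuclei the same quantity is accumulated from
signed surface crossings, which requires no sorting and is exact for
watertight meshes. The whole problem is a single material (water): the
membrane is a zero-thickness surface source, and all bulk compartments are
water-equivalent.

Validation anchors built into the test suite:

* **Full-absorption limit** — a nucleus much larger than the maximum range
  must give $S \to \Delta/m_N$; the engine agrees within two Monte Carlo
  standard errors at $10^6$ histories.
* **Charged-particle equilibrium** — a nucleus deep inside a large uniform
  medium must receive $\Delta \cdot c/\rho$; the medium-source estimator
  agrees within 5% (the small deficit is the non-radioactive cell volume).
* **Chord integral** — single-ray deposits match fine-step numerical
  integration of the stopping power along the chord to 0.1%.
* **Dual-route mesh check** — the same flat ellipsoid built as an exact
  mesh and as an analytic quadric gives consistent S values through the two
  independent chord solvers.

Two exact variance-reduction devices are used for the medium source, whose
S value is ~7 orders of magnitude below the self-dose: source points are
drawn with density $\propto 1/r^2$ about the nucleus (weight
$4\pi r^2 R_{max}/V_M$, zero score outside the medium or inside the cell),
and emission directions are drawn inside the cone subtending the nucleus
bounding sphere (weight $(1-\cos\theta)/2$); under straight-line transport
a direction outside that cone deposits exactly zero, so both weights are
exact, and they are recorded in the result's metadata.

## Cell geometries

Three families implement the same compartment interface (cytoplasm,
zero-thickness membrane surface, nucleus, Golgi):

* **Spheres** (`make_sphere_cell()`) — the classical concentric (or
  eccentric) MIRD configuration.
* **Truncated cones** (`make_truncated_cone_cell()`, `tc_cell()`) — a
  conical frustum with an oblate ellipsoidal nucleus near the base and a
  half-torus Golgi wrapped around the nucleus equator at a minimum surface
  distance $d_{G\text{-}N}$ (default 1 µm). The default family follows the
  spread adherent-cell morphology of U2OS+SST2 monolayers: footprint
  diameter 40 µm, height ≈ 4.8 µm, flattened nucleus (semi-axes 10.65,
  10.65, 2.2 µm) holding 30% of the cell volume. Similarity scaling by
  $(V/V_0)^{1/3}$ spans the observed cell volumes 1900–5500 µm³ and nucleus
  volumes ≈ 570–1650 µm³. No standard parameterisation exists for this
  shape family, so the exact dimensions are this package's own choice; the
  flat-spread dialect was chosen because it matches both the
  imaged morphology and the reported relation between truncated-cone and
  spherical self S values (engine: $9.1\times10^{-5}$ Gy/(Bq·s) for the
  cytoplasm source at the average volume, ≈ 0.65 of the equal-volume
  sphere).
* **Polygonal meshes** (`load_mesh_cell()`) — watertight ASCII OBJ/PLY
  triangle surfaces per compartment, volumes by the divergence theorem,
  containment verified by ray-casting point-in-mesh tests. Since no mesh
  package is available in the target environment, the minimal mesh tool
  chain (I/O, watertightness, areas, sampling, ray–triangle intersection)
  is implemented here.

Monolayers are hexagonal lattices on the $z=0$ plane (the densest packing;
the lattice itself is a package choice). `gap` is edge-to-edge spacing in
cell diameters, and all source cells whose centres lie within 280 µm — the
average beta range used as the neighbour cutoff — are enumerated. Colony
clusters for the follow-up days are the `size − 1` nearest lattice sites.

## Kinetics and cumulated activities

Activity fractions are decay-corrected fractions of the added activity.
During the 4-h uptake the membrane-bound fraction is fitted as linear in
time (it saturates within the first sampling interval) and the internalized
fraction as an exponential association $A_{plat}(1-e^{-kt})$; the uptake
interval's cumulated activity integrates the *fitted* curves (medium:
spline through the measurements) against $A_0 e^{-\lambda_p t}$ on a fine
grid. Follow-up days use the closed form

$$\tilde{A} = f\,A_0\,(e^{-\lambda_p T_1} - e^{-\lambda_p T_2})/\lambda_p,$$

with day 1 spanning 4–24 h (20 h) and days 2–6 spanning 24 h each, and the
$\lambda_p \to 0$ limit handled analytically. The physical half-life is
6.647 d (configurable). Cellular compartments are normalised per cell by
the day's cell count, interpolated exponentially between measurement days.
Fractions at unmeasured added activities are obtained by inverse-distance
weighting over (log₁₀ activity, time) within a compartment, with power
$p = 2$; the method's coordinates and power are not stated in the source
analyses, so both are explicit arguments, and the implementation is exact
at grid nodes and bounded by the node values.

## Dose assembly and uncertainty

`colony_schedule()` gives deterministic cluster sizes
$\mathrm{round}(2^{24d/T_d})$ (day 1 forced to 1 — isolated cells), for
doubling times in the observed 27–44 h range. Cross-dose on follow-up days
comes only from a cell's own cluster in touching packing; neighbouring
colonies lie beyond the electron range and are ignored. During uptake the
monolayer is equally spaced at 1 cell diameter. The medium source is
applied during uptake and day 1 only; afterwards the residual-medium term
is below the medium S-value scale and dropped. Dose SDs propagate the
component relative SDs in quadrature — activity fractions (5–33%), cell
counts (11–18%), added activity (1–3%) and S-value shape variance (18–27%)
— using class midpoints when measured replicate SDs are not supplied.

## Dose–response fitting

Survival is fitted as $SF = e^{-\alpha D - \beta D^2}$ (or $\beta \equiv 0$
for the linear model) by unweighted least squares on the SF scale, matching
the stated fitting protocol; log-domain fitting is available as an option,
and $R^2$ is reported on both scales because the convention for nonlinear
fits is ambiguous. $\alpha, \beta \ge 0$ are enforced as physical bounds.
Model choice uses $AIC = n\ln(RSS/n) + 2k$ (plain AIC; the small-sample
variant is not used), ties preferring the smaller model, with the
classification "linear regime" when the linear model wins or
$\alpha/\beta > 100$ Gy.

## The synthetic-data generator

`generate_uptake_dataset()` emulates the measurement design: added
activities 0.1–2.5 MBq/ml, 15-min sampling through 4 h, daily samples for 6
days, two experiments in triplicate, multiplicative lognormal noise at the
component CVs above, and per-day cell counts. The truth model uses
receptor-limited uptake: the internalized plateau fraction follows
$f(a) = f_{ref}(a_{ref}+K)/(a+K)$ with $f_{ref} = 0.8\%$ at 2.5 MBq/ml and
$K = 1$ MBq/ml. That saturation — not a constant fraction — is what makes
absorbed doses nearly equal at intermediate activities and keeps the
cumulative doses in the 0.2–2 Gy range with the medium term contributing
10–17% of the total, delivered during the uptake phase, as observed.
Retention decays at $\lambda_{eff} = 0.024$ h⁻¹; colonies double every 35 h.
Every dataset carries its analytic ground truth (cumulated-activity
integrals and generating parameters), enabling the closed-loop test:
fit → cumulate → dose → dose–response returns the generating α within 0.5%
on noiseless data.

What the generator does **not** emulate: cell-to-cell uptake heterogeneity
(activity is uniform across the population), receptor recycling kinetics
(empirical curve forms only), morphology–uptake correlations, and real
microscopy geometry (`generate_mesh_cell()` produces smoothly perturbed
ellipsoids rescaled to target volumes, labelled synthetic — useful for
exercising the mesh pipeline, not for reproducing imaged cells' S values).
Passing closed-loop tests therefore demonstrates internal consistency of
the pipeline, not fidelity to any particular measured dataset.

## Numerical choices and problem sizes

Monte Carlo functions take explicit integer seeds and are bit-reproducible;
the RNG state of the session is restored afterwards. The test suite runs
S values at $10^4$–$10^6$ histories; proximity comparisons (gap 0 vs 1 and
5 diameters) use up to $4\times10^6$–$4\times10^7$ histories because the
cross-dose estimator is heavy-tailed — rare histories in which an electron
stops inside the target nucleus dominate the variance — and the analysis
script sizes were chosen to hold the gap-reduction estimates to about half
a percentage point. Simulation studies (parameter recovery, coverage, AIC
selection) use 100 seeds. Degenerate inputs are guarded: rejection sampling
aborts below an acceptance rate of $10^{-4}$, energies above the
stopping-power table maximum refuse to extrapolate, and zero survival
fractions are flagged and excluded from log-domain fits.

## Known limitations

* **Straight-line transport overestimates mid-range cross-dose.** Relative
  proximity effects reproduce reported condensed-history results well
  (total cross-dose falls ~86% at 1 cell diameter and ~99.5% at 5,
  against reported values of 82% and 99%), but the *absolute*
  cross-to-self ratio for touching monolayers comes out near 50–57%,
  roughly twice the ~23% obtained with condensed-history codes. With
  straight-line kernels the energy deposited 30–80 µm from the source is
  systematically different from scattered transport, and the summed
  contribution of ~200 touching neighbours amplifies that difference;
  self-dose, which is dominated by the first few micrometres, is much less
  affected. Conclusions that depend on the absolute cross/self split
  should treat the cross term as an upper bound.
* Photon emissions, secondary electrons, straggling and voxelised
  geometries are out of scope; bystander effects, repopulation and
  cell-cycle dependence are not modelled.
* The emission table and stopping powers are compiled approximations
  (swappable via CSV) rather than evaluated nuclear-data files.
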