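---
title: "From segmented leaf volumes to mesophyll conductance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From segmented leaf volumes to mesophyll conductance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgas)
```

`leafgas` connects three scales of leaf function: the 3D architecture of the
mesophyll airspace (from segmented microCT stacks), leaf-level CO2 transport
(mesophyll conductance from gas exchange combined with carbon isotope
discrimination), and the optical environment inside the leaf (chlorophyll
fluorescence profiles across depth and around bundle-sheath extensions).
This vignette explains the models implemented, the parameters that matter,
the numerical choices made where the methods literature leaves latitude, and
what the synthetic generators do and do not emulate.

## 1. Anatomical traits from label volumes

A segmented stack is a 3D integer array with seven classes: background,
adaxial and abaxial epidermis, mesophyll cells, intercellular airspace
(IAS), bundle-sheath extensions (BSEs), and veins. The depth axis z runs
adaxial to abaxial; voxels are isotropic.

**Porosity** is the airspace share of the mesophyll,
$\theta_{IAS} = N_{IAS} / (N_{IAS} + N_{cell})$. BSE and vein voxels are
excluded from both numerator and denominator by default: BSE area is
quantified separately (Section 1.3), and treating BSEs or vasculature as
mesophyll would mix tissues with different function. The exclusion is
configurable (`denominator_extra`). The ratio
$V_{IAS}/V_{cell} = \theta/(1-\theta)$ is reported as well; it is exactly
determined by porosity, which the test suite asserts to machine precision.

**Surface area per volume** ($SA_{mes}/V_{mes}$) measures the
cell-wall area available for CO2 dissolution. Counting exposed voxel faces
overestimates oblique and curved interfaces by up to 50% (a 45-degree plane
counts $\sqrt{2}\times$ its true area), so the package uses a
normal-weighted face estimator: each cell/IAS face contributes its area
times $\|n\|_2/\|n\|_1$ of the local surface normal, estimated from the
gradient of a Gaussian-smoothed cell indicator (default smoothing scale 1.5
voxels — narrow enough to track single-cell curvature, wide enough to
suppress voxelization noise). The estimator is exact for axis-aligned
planes and measured at −0.25% error for a digitized sphere of radius 22–25
voxels; both bounds are enforced in the tests.

**Thicknesses** are per-column z-extents (leaf = all non-background;
mesophyll = cells + IAS + BSEs + veins), averaged over columns intersecting
the leaf. The measurement is deliberately axis-aligned — the same convention
as reading distances off a cross-section — so a tilted leaf reads thicker
by $1/\cos\alpha$; samples are expected to be mounted approximately
paradermal.

**Porosity depth profiles** bin mesophyll voxels by relative depth,
normalized per column (0% = adaxial mesophyll edge of that column,
100% = abaxial edge), excluding both epidermes. Per-column normalization
follows the convention used for fluorescence profiles, and makes profiles
of leaves with undulating surfaces comparable. Because bins partition
exactly the voxels that define scalar porosity, the voxel-weighted mean of
the bin porosities reproduces the scalar value to machine precision — a
conservation property asserted in the tests.

**BSE area fraction** is $100 \cdot N_{BSE} / (N_{BSE} + N_{cell} + N_{IAS})$
per cross-section, averaged over sections. Veins are excluded from the
denominator (the quantity describes the mesophyll cross-section); this is a
documented choice, as the convention is ambiguous in the methods
literature.

**Paradermal palisade diameter** labels in-plane connected mesophyll-cell
components at a chosen relative depth (4-connectivity) and reports the mean
equivalent-circle diameter. Components touching the slice border are
excluded (they are truncated by the field of view and bias the mean
downward); components under 10 voxels are treated as segmentation speckle.

## 2. Diffusion geometry

CO2 entering a stomate travels through the connected airspace to the cell
walls. Three distance fields capture that geometry:

* $L_{geo}$ — geodesic distance from the nearest stomate, restricted to
  IAS voxels;
* $L_{Euc}$ — straight-line distance from the nearest stomate, ignoring
  obstacles (exact Euclidean distance transform);
* $L_{epi}$ — straight-line distance to the abaxial epidermis layer.

Tortuosity is $\tau = (L_{geo}/L_{Euc})^2$ and lateral path lengthening is
$\lambda = L_{Euc}/L_{epi}$; leaf-level values are arithmetic means over
IAS voxels face-adjacent to mesophyll cells ("the edge of mesophyll
cells"), which is where diffusing CO2 is consumed. The mean is
voxel-weighted; a surface-area weighting would require the area estimator
of Section 1 per edge voxel and changes values by well under the
measurement noise of segmentations, so the simpler convention is used and
stated.

### 2.1 Numerical design of the geodesic

Geodesic distance is computed by Dijkstra propagation over integer voxel
moves whose weights equal their Euclidean lengths. The classic 26-neighbor
(1, √2, √3) chamfer metric is available (`nb_order = 1`) but overestimates
free-space distances by up to ~12% (direction-dependent), which would bias
an obstacle-free tortuosity to ~1.08–1.12 rather than 1. The default move
set (`nb_order = 4`) uses all primitive integer displacements within a
9×9×9 neighborhood, with intermediate-voxel line-of-sight checks so long
moves cannot jump through walls. Measured free-space error is 0.42% mean /
1.5% max, giving an open-slab tortuosity of 1.010. Exactness of the
propagation itself (as opposed to the metric) is verified against an
independent graph shortest-path oracle (igraph Dijkstra on the identical
move set), which agrees to floating-point precision.

Two structural invariants are guaranteed by construction, not just tested:
$L_{geo} \ge L_{Euc}$ (each geodesic step weight equals its Euclidean
length, so any path is at least as long as the straight line), and
$L_{Euc} \ge L_{epi}$ (the stomatal pore voxels are included in the
epidermis-layer seed set — pores are part of that surface — so the nearest
epidermis-layer point is never farther than the nearest stomate). Hence
$\tau \ge 1$ and $\lambda \ge 1$ on every input.

Airspace not connected to any stomate keeps $L_{geo} = \infty$, is
excluded from means, and is reported as `1 - reachable_fraction`.
Disconnected airspace is real in heterobaric leaves, where BSEs
compartmentalize the mesophyll laterally; the phantom generator reproduces
exactly this behavior when BSE slabs are enabled.

Stomata seeds are taken from a caller-supplied coordinate table when
available, otherwise detected as IAS voxels inside the abaxial epidermis
that touch the outside background (i.e., the pore mouths).

### 2.2 Airspace conductance

$$g_{IAS} = \frac{\theta_{IAS}\, D_m}{0.5\, L_{mes}\, \tau_{leaf}\, \lambda_{leaf}} \cdot \frac{P}{RT}$$

The diffusion path length is half the mesophyll thickness, the standard
assumption for hypostomatous leaves. The first factor has velocity units
(m s⁻¹); multiplying by the ideal-gas molar density $P/(RT)$ (40.34 mol m⁻³
at 298.15 K, 1 bar) expresses the conductance in mol m⁻² s⁻¹ bar⁻¹, the
unit in which leaf conductances are tabulated. $D_m$ defaults to CO2 in
air at 25 °C (1.54×10⁻⁵ m² s⁻¹); temperature and pressure are explicit
arguments. The gas-phase share of total mesophyll resistance is
$(1/g_{IAS})/(1/g_m) = g_m/g_{IAS}$, valid because the airspace is one
series element of the CO2 pathway; the function refuses $g_m > g_{IAS}$,
which would be unphysical.

## 3. Mesophyll conductance from ¹³C discrimination

Rubisco discriminates against ¹³CO2, so the isotopic signature of air
drawn down by a leaf encodes how far CO2 concentration falls along the
diffusion path. Comparing observed discrimination $\Delta_o$ (from the
isotope ratios of air entering and leaving an open cuvette) with the
discrimination predicted if the drawdown stopped at the substomatal cavity
($\Delta_i$), after removing respiratory ($\Delta_e$) and photorespiratory
($\Delta_f$) contributions, leaves the component attributable to the
substomatal-to-chloroplast gradient:

$$\Delta_{gm} = \Delta_i - \Delta_o - \Delta_e - \Delta_f, \qquad
g_m = \frac{1+t}{1-t}\left[b - a_i - \frac{e\,R_d}{A_n+R_d}\right]
\frac{A_n/C_a}{\Delta_{gm}}, \qquad C_c = C_i - A_n/g_m.$$

All components (drawdown ratio ζ, combined boundary-layer/stomatal
fractionation a′, ternary correction t) are exposed as separate functions
and stored in the result, and the identity
$\Delta_{gm} = \Delta_i - \Delta_o - \Delta_e - \Delta_f$ holds exactly in
every result object.

Conventions worth stating:

* Fractionation constants default to a = 4.4‰ (stomata), a_b = 2.9‰
  (boundary layer), a_i = 1.8‰ (dissolution + liquid diffusion, 25 °C),
  b = 29‰ (carboxylation), f = 11.6‰ (photorespiration). b and f are
  sometimes printed with negative signs in the literature (discrimination
  *against* ¹³C); the discrimination equations as implemented require the
  positive magnitudes to produce positive $\Delta_i$ and $\Delta_f$, so
  constants are stored as magnitudes and are fully configurable.
* The respiratory fractionation e is not a constant: respired carbon was
  fixed from tank air, so e equals the offset between the tank isotope
  ratio and greenhouse air (δ¹³C_atm, default −8‰).
* a′ enters the ternary correction in fractional form, (1 + a′/1000); all
  Δ quantities are kept in per mil.
* Transpiration is accepted as mmol m⁻² s⁻¹ in record tables (`E_mmol`),
  matching gas-exchange system output, and converted internally.
* In batch sampling sequences where reference and plant vials alternate,
  `average_bracketing_refs()` pairs each plant sample with the mean of its
  two neighboring references (single-neighbor fallback at the ends).
* No temperature corrections are applied to a_i or Γ*; records are assumed
  measured at 25 °C. Day-respiration R_d is taken as supplied.

A nonpositive $\Delta_{gm}$ (observed discrimination at or above the
prediction net of corrections) means the data carry no resolvable
mesophyll drawdown; the estimator flags the record `gm_unresolvable`
rather than returning a negative conductance.

## 4. Leaf physiology

**Leaflet hydraulic conductance** uses the evaporative flux method:
$K_{leaflet} = E/(\Psi_{bagged} - \Psi_{unbagged})$, transpiration over the
water-potential drop between a non-transpiring (bagged, equilibrated)
leaflet and a transpiring one. A negative gradient is flagged with a
warning instead of being silently accepted.

**Stomatal anatomy**: aperture ratio = inner pore width / length; stomate
size = guard-cell length × pair width; anatomical maximum conductance

$$g_{smax} = \frac{d_w}{v}\cdot\frac{SD\cdot a_{max}}{l + \frac{\pi}{2}\sqrt{a_{max}/\pi}}$$

with $a_{max}$ the elliptical pore area from the inner pore axes, pore
depth l taken as a single guard-cell width (half the pair width — a stated
convention, since pore depth is rarely measured directly), water-vapor
diffusivity $d_w = 2.49\times10^{-5}$ m² s⁻¹ and molar volume of air
v = 0.0224 m³ mol⁻¹. All constants are arguments.

**A–Ci fitting** uses the two-limitation FvCB model,
$A = \min(W_c, W_j) - R_d$ with
$W_c = V_{cmax}(C_i-\Gamma^*)/(C_i+K_m)$ and
$W_j = J(C_i-\Gamma^*)/(4C_i+8\Gamma^*)$. TPU limitation is not modeled.
$\Gamma^*$ and $K_m$ are fixed, caller-supplied kinetics (defaults 40 and
710.3 µmol mol⁻¹, the 25 °C in-air values). The fit is a joint
least-squares over the whole curve — no pre-assignment of points to
regimes, which would impose arbitrary C_i cutoffs — minimized by restarted
Nelder–Mead from a small grid of day-respiration seeds (the kink of the
min() makes single-start gradient methods unreliable; the restart grid
costs milliseconds and eliminated every convergence failure we constructed).
Points are labeled Rubisco- or RuBP-limited afterward by the smaller
limitation; a parameter whose regime claims at most one point is reported
as unidentified. $A_{max}$ is the fitted A at C_i = 1500 µmol mol⁻¹.

**Pairwise testing** follows the divided-alpha convention: the family
alpha (0.05) divided by the number of mean pairs per test, reported
rounded to 4 decimals (0.05/6 → 0.0083) with the raw quotient retained
for flagging. Group comparisons are Welch t tests — the safer default
since the pooled-variance variant is unstated in common practice — with
percent change reported against a reference (e.g., well-watered) group.

## 5. Synthetic generators: what they emulate

The generators provide seeded inputs with ground truth that can be
recomputed by direct counting on the emitted artifact. They emulate the
*geometry and signal structure* the estimators consume, not the imaging
physics: no beam hardening, phase contrast, segmentation error
(volumes are emitted post-segmentation), cell-wall thickness, or
chloroplast placement. Passing tests therefore demonstrate correctness of
the measurement pipeline on known geometry, not robustness to segmentation
noise.

**Leaf phantom** (`generate_leaf_volume`): four layers with configurable
thicknesses (defaults 20/100/80/15 µm — a ~215 µm walnut-like leaflet at
1.3 µm voxels). Palisade cells are vertical cylinders on a hexagonal
lattice; the lattice spacing is set by bisection so the voxelized section
hits the target porosity at fixed cylinder diameter (hexagonal packing
reaches cell fractions up to 0.907, so porosities down to ~0.09 are
achievable without merging cylinders). Spongy mesophyll is a Gaussian
random field (correlation length ~8 µm, a typical spongy cell scale)
thresholded at the porosity quantile, which hits the target fraction
essentially exactly. BSEs are full-depth slabs joining vein cylinders to
both epidermes — deliberately sealing, as in heterobaric leaves. Stomata
are elliptical through-pores of the abaxial epidermis on a jittered grid
at the requested density (default 62 mm⁻²), each connected to the spongy
airspace by a one-voxel channel so stomate-seeded distance fields are well
defined. The emitted truth records *achieved* quantities (by counting),
not requested ones.

**Isotope records** (`generate_isotope_records`): the discrimination model
run forward from a known g_m, inverted exactly for the cuvette-air isotope
ratio, plus i.i.d. Gaussian noise on δ¹³C_a (the measured quantity; the
replicate-level error magnitude is a user parameter — no published value
exists to calibrate it). The default cuvette state (C_a 400, C_i 280,
A_n 14 µmol m⁻² s⁻¹) sets the reference-air CO2 to C_e = 455 µmol mol⁻¹:
at a typical 150 µmol s⁻¹ cuvette flow and 6 cm² aperture, a leaf
assimilating 14 µmol m⁻² s⁻¹ draws the air stream down by
$A_n \cdot \text{area}/\text{flow} \approx 55$ µmol mol⁻¹. This matters
because the drawdown ratio ζ = C_e/(C_e−C_a) multiplies δ-noise into
observed discrimination: unrealistically small drawdowns make g_m
estimation far noisier than real cuvette work.

**Fluorescence images** (`generate_fluorescence_image`): a caller-supplied
nonnegative function of relative depth paints the mesophyll band of a
cross-section, optionally modulated laterally around BSE stripe positions,
plus Gaussian noise. Kautsky decay, focal-plane variation and absolute
intensity are not modeled — consistent with the profile extractors, which
report only relative values normalized to the profile maximum (100%).

**A–Ci curves** (`generate_aci_curve`): the FvCB forward model on a
50–1500 µmol mol⁻¹ grid with Gaussian noise; true parameters travel with
the table.

## 6. Problem sizes and numerical tolerances

The test suite and the acceptance script run phantoms of 48³–96×72×72
voxels and full-pipeline stacks of 180×96×96 (≈1.7M voxels) — sizes at
which every oracle (graph shortest path, closed-form areas, voxel
counting) is exact or near-exact while the full suite completes in about a
minute. Key tolerances: geodesic-vs-oracle agreement 2% (observed:
floating-point identical at matching move sets); open-slab tortuosity
1.00 ± 0.02 (observed 1.010, the residual being the free-space metric
error); sphere area 5% (observed 0.25%); plane area 2% (observed exact);
phantom porosity ±0.02 (quantile thresholding is exact up to ties;
palisade bisection converges to ~0.01); FvCB recovery 1% on noise-free
curves (observed <0.1%); zero-noise isotope closure 10⁻¹⁰ relative
(algebraic inversion). Monte-Carlo g_m recovery at 0.1‰ noise and n = 200
shows the expected Jensen-type positive bias of ~1–2% (the estimator is a
reciprocal of a noisy discrimination residual); the documented check uses
a fixed seed and the spec-level 2% bound.

## 7. Known limitations

* Anisotropic voxels and streaming of larger-than-memory stacks are not
  supported.
* The tortuosity mean is voxel-weighted, not surface-area-weighted.
* Reaction–diffusion effects (assimilation sinks shortening effective
  paths) are outside the geometric model, as is liquid-phase conductance;
  g_IAS is the gas phase only.
* The variable-J fluorescence route to g_m is not implemented; the
  isotope route is the package's estimator.
* Automatic BSE detection in grayscale fluorescence images is out of
  scope; BSE positions come from the label volume or the caller.
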