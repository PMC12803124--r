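---
title: "Methods: atlas-based surrogates for biventricular mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atlas-based surrogates for biventricular mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, assumptions, numerical choices and
known limitations behind `shapemech`. It states no empirical result; the
numbers the package produces come from the test suite and from
`scripts/acceptance.R`.

## The problem

Forward finite-element (FE) models of ventricular mechanics map an
unloaded (stress-free) geometry, chamber pressures and material
parameters to deformed end-diastolic (ED) and end-systolic (ES) shapes.
Inverse estimation of material properties requires many forward solves,
which motivates a fast learned surrogate. A statistical shape atlas
provides the low-dimensional latent space that makes this tractable:
shapes are encoded by a few principal-component (PC) scores, the FE
output is projected back into the same space, and the surrogate is a
small regression between score vectors instead of full meshes.

## Synthetic shape atlas

Real cardiac atlases are built from large imaging cohorts. This package
emulates one with a parametric template family (`template_params()`):

* LV cavity: a truncated ellipsoid about the long (z) axis; the LV wall
  is the region out to a coaxial ellipsoid offset by the wall thickness.
* RV cavity: a laterally offset ellipsoid clipped to lie outside the LV
  epicardial ellipsoid, so the septum is LV wall; the RV free wall is a
  constant-thickness outward offset.
* Epicardium: the union of the LV epicardial ellipsoid and the RV outer
  ellipsoid, blended with an 8-norm so the concave crease between them is
  padded (the epicardial fat-pad region). The blend is not cosmetic: a
  hard union pinches the wall to a membrane at the junction, which makes
  the FE problem ill-conditioned on extrapolated shapes.
* Base: one truncation plane carrying the four valve rings (MV, AV, TV,
  PV) as labelled circles.

Every surface is sampled on a fixed (longitude x z-level) grid plus an
apex point, so point correspondence across cohort members holds by
construction; PCA needs it. The paired ES shape is generated from ED by
a fractional radial contraction of both cavities (default 0.3), an
epicardial reduction that approximately conserves wall area per
horizontal slice (incompressible-wall heuristic), and a mild longitudinal
shortening (45% of the radial fraction) towards the fixed base plane.
These defaults give an LV EDV near 110 mL and an ejection fraction near
55% at adult scale — chosen once as physiologically plausible values for
a healthy adult family, with cohort jitter (4% semi-axes, 8% wall
thickness and global scale, 0.04 contraction SD) producing LV EDV spread
of roughly 60-140 mL.

The atlas itself (`build_atlas()`) is standard PCA of the mean-centred
concatenated [ED; ES] coordinate vectors; scores are reported in units of
per-mode cohort SD (score 1 = one SD along that mode), which makes
sampling bounds interpretable. Cohort scores are sampled as independent
standard normals truncated at 3 SD.

## Unloaded geometry

FE mechanics needs a stress-free reference state. The unloaded LV volume
is extrapolated from LVEDV with the empirical linear relation
`V0 = 0.5025 LVEDV + 5.7574` (mL), and `unload_scores()` finds modified
shape-mode scores whose ED LV cavity volume matches `V0` within 0.1 mL:
the objective `(V(s) - V0)^2 + lambda ||s - s_ED||^2` is minimized by
gradient descent with central finite differences (step 1e-3 SD),
backtracking (Armijo) line search, and a trust-region-style cap of 0.5 SD
of score movement per iteration. The quadratic penalty (default
`lambda = 0.1` mL^2/SD^2) and the movement cap address the same issue
from two sides: a pure volume constraint is under-determined in two or
more modes, and an uncapped descent can jump into distant basins where
the linear shape model extrapolates into geometric nonsense. In the
scaled study configuration the descent is additionally restricted to the
leading 10 modes — exactly the modes the surrogate later receives as
inputs — which keeps the unloaded anatomy within the well-sampled part
of shape space. The unloaded cloud is the ED half of the reconstruction
at the optimized scores, re-tagged `UNLOADED`.

## Meshing and fibers

`mesh_from_surfaces()` is an implicit-domain tetrahedral mesher: a
Cartesian lattice (anchored to the LV axis and the base plane, spacing =
characteristic length) is split into six tetrahedra per cell (Kuhn
subdivision, conforming across cells); lattice vertices within 0.45 cells
of a surface are first warped onto it (this avoids sliver elements);
elements whose centroid lies inside the wall are kept; remaining boundary
vertices are snapped onto the nearest surface with a minimum-separation
and inversion guard. Surface membership is evaluated against the
star-shaped radius functions interpolated from the ordered cloud grids.
Two robustness guards matter on strongly extrapolated shapes: the RV
cavity radius is clipped to stay at least half a cell inside the
epicardium (minimum-wall guard), and lattice anchoring makes the
discretization consistently phased across geometries, so discretization
error behaves as a smooth function of shape rather than per-geometry
noise — which the surrogate can then absorb.

The characteristic length is 5 mm at adult scale in the reference
configuration and scales with the cube root of the unloaded volume for
individual geometries; the scaled-down preset uses 13 mm (a few hundred
to a thousand elements), the problem size used throughout the test suite
and the acceptance script.

Fibers follow a single-Laplace rule: the transmural coordinate t solves
Laplace's equation with t = 0 on both endocardial facet groups and t = 1
on the epicardium (natural conditions on base and rings); the helix angle
varies linearly from +60 deg (endo) to -60 deg (epi); the local frame is
built per element from the volume-weighted nodally-recovered transmural
gradient (recovery removes the vanishing gradients that coarse curved
shells otherwise produce), the template long axis projected orthogonal to
it, and their cross product. Only the fiber direction f0 is needed
because the constitutive law is transversely isotropic; sheet
architecture is out of scope.

## Mechanics

The passive law is the transversely isotropic exponential energy
`Psi = a/(2b)(e^{b(I1-3)} - 1) + af/(2bf)(e^{bf(I4-1)^2} - 1)` with
`I1 = tr C`, `I4 = f0 . C f0`; exponents are fixed at `b = 9.726`,
`bf = 15.779` (biaxial testing values) and the stress scales default to
`a = 1.28`, `af = 1.7` kPa. The fiber term is active in compression as
written (a switch disables it for `I4 < 1`). Active contraction is an
additive Cauchy stress `Ta (f (x) f + eta (I - f (x) f))` with
`eta = 0.2` and the deformed unit fiber `f = F f0 / |F f0|`; the
configuration of the added stress is a modelling decision documented
here (pulled back to first Piola-Kirchhoff for assembly).

Discretization: P2 displacements / P1 pressure multiplier (Taylor-Hood
type) tetrahedra; 4-point volume quadrature, 6-point (degree-4) surface
quadrature. Incompressibility is enforced by the multiplier with a small
artificial-compressibility stabilization (`J - 1 = eps p`,
`eps = 1e-6 /kPa` by default): coarse meshes with fully fixed ring
elements otherwise carry exact spurious pressure modes, and the
stabilized system is quasi-definite, which enables a fast symmetric LDL'
factorization. At physiological multiplier magnitudes the compressibility
it introduces is at the 1e-5 level of |J - 1|. Cavity pressures are
follower loads (deformed-normal tractions) on the endocardial facets; all
valve-ring facet nodes are fully fixed.

The nonlinear solver is a damped modified Newton method: element
residuals are analytic; element tangents are one-sided finite differences
of the residual (the converged solution only depends on the residual);
the tangent is factored once per load step via LDL' of its symmetrized
form and reused while the residual contracts by at least a factor 0.6 per
iteration, with sparse-LU fallback; updates are damped by halving (best
of alpha in {1, 1/2, 1/4, 1/8}) and capped at half an element size of
maximum nodal movement per iteration — exponential materials punish
overshoot severely. Load legs ramp linearly with automatic step halving
on divergence (floor 1/64 of a step) and a per-leg Newton iteration
budget; exhausting either marks the case non-converged, and such cases
are excluded from the training data and logged, mirroring the
convergence-driven attrition any such study exhibits (stiffer parameter
sets converge more reliably, so they end up over-represented).

Loading follows the two-phase protocol: filling from unloaded to ED
pressures with Ta = 0 (default 10 steps; 5 in the scaled preset), then a
linear ramp of pressures and Ta to the lowest requested ES case (20
steps; 12 scaled), then further ES pressure increments at constant peak
tension, so the ED state and the active ramp are shared across the three
ES levels of a family.

## Projection and surrogate

ED and ES displacement fields are interpolated at the unloaded cloud
coordinates by inverse-distance weighting (power 1) of the 4 nearest
mesh nodes (P2 nodes, i.e. vertices and edge midpoints), with an
exact-hit rule below 1e-9 mm; the displaced clouds preserve ordering and
labels, are concatenated to an atlas vector, and projected to recover
the deformed scores. The first 5 are the regression targets; the inputs
are the first 10 unloaded scores, LVEDP, LVESP, RVEDP, RVESP, a and af
(active tension is constant across simulations and therefore excluded).

The network is a 16 -> 128 -> 64 -> 5 MLP with ReLU and dropout 0.1
after each hidden layer: 2,176 + 8,256 + 325 = 10,757 trainable
parameters. Training minimizes the mean squared error with AdamW
(decoupled weight decay); inputs and outputs are z-scored with
training-set statistics stored in the model; a geometry-stratified 20%
validation split is monitored every epoch and the lowest-validation-loss
state is returned. The reference configuration (learning rate 5e-6,
weight decay 1e-2, batch 32, up to 10,000 epochs) is the default; the
scaled preset uses learning rate 1e-3, weight decay 2.0 with dropout
disabled, batch 8, 6,000 epochs and five validation-selected restarts,
sized once to its much smaller dataset (tens of records rather than
hundreds): with so few records strong decoupled weight decay is the
regularizer that generalizes, dropout mostly adds gradient noise, and
keeping the lowest-validation-loss state across a few restarts removes
initialization luck (state selection by validation loss is also how the
reference training procedure operates).

## Scaled-down study conditions

The reference configuration — 50 geometries, the 2 x 3
material grid (a in {0.50, 1.28}, af in {1.7, 10, 20} kPa), all nine
ED/ES pressure combinations per geometry and material, 5 mm elements —
is the package default. The test suite and the acceptance script run the
"coarse" preset, chosen once as a desk-scale analogue: a 40-member atlas
cohort, 32 sampled geometries, 13 mm elements, the two stiff material
pairs (a = 1.28 with af in {1.7, 10} kPa) assigned one per geometry in
rotation, one ED level per geometry in rotation with all three ES
levels (so all four pressure inputs still vary across the dataset), and
a 26/6 geometry train/test split. The stiff-material restriction follows
the same rationale as the convergence-driven attrition above: soft
isotropic scales fail far more often on coarse meshes, and a scaled
study is better served by a complete stiff-material design than by a
sparse soft-material one.

What passing at this scale does and does not show: the synthetic family
has one anatomy parameterization and smooth, noise-free surfaces, so
results here demonstrate the pipeline's internal consistency (atlas
algebra, unloading tolerance, FE verification against closed forms, the
EF-afterload trend, surrogate fidelity on held-out geometries) — not
performance on real imaging-derived anatomy, whose shape variance,
segmentation noise and fiber architecture are richer.

## Numerical choices and degenerate inputs

* Volume tolerance of unloading: 0.1 mL, the stated default.
* Newton tolerances: relative 1e-8 / absolute 1e-10 (defaults); the
  scaled preset relaxes to 1e-6 / 1e-8, far below any quantity of
  interest at its mesh resolution.
* Finite-difference steps: 1e-6 x element scale (displacements), 1e-6
  kPa (multiplier) for element tangents; 1e-3 SD for unloading
  gradients.
* Overlap threshold boundary-inclusive (<= 2 mm); directed average
  distance reported predicted -> true, with a symmetric option.
* Zero-contraction templates reproduce the ED cloud exactly; a zero
  truncation bound for cohort sampling is rejected as an error; clouds
  whose labels or ordering disagree with the atlas are rejected before
  projection; non-positive EDV cases are flagged and excluded from
  cohort metrics with a warning.
* PCA modes with zero variance project to score 0 rather than dividing
  by zero; R-squared of a zero-variance test component is reported NA.

## Known limitations

* The ES pairing in the atlas family is a kinematic heuristic, not a
  mechanics solve; the atlas only needs statistically plausible ED/ES
  pairs, and the training deformations come from the FE model.
* The unloading heuristic is volumetric only; a mechanics-consistent
  inverse (inflating the candidate unloaded state and comparing to the
  subject ED shape) is future work, as is any coupling between unloading
  and material parameters.
* Fixed valve rings are restrictive and leave their signature in the
  higher deformed modes; basal boundary conditions are a recognized
  artifact source in this class of models.
* Coarse meshes bias cavity volumes by a few percent and the surrogate
  inherits the coarse-mesh forward map, not the mesh-converged one.
* The single-Laplace fiber rule omits separate LV/RV/apex coordinates
  and sheet directions; only f0 enters the law used here.
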