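---
title: "Methods: finite-element stretch analysis of calcified plaque cross-sections"
author: "plaqueStretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-element stretch analysis of calcified plaque cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific question and scope

Advanced carotid atherosclerotic lesions contain three mechanically distinct
tissue classes recoverable from CT angiography: fibrous/cellular matrix
(MATX), macro-calcification (CALC), and lipid-rich necrotic core (LRNC).
Macro-calcification is roughly an order of magnitude stiffer than the
surrounding soft tissue at small strain and is hypothesized to be
load-bearing: it should carry the pressure-induced wall load and thereby
*shield* the adjacent soft matrix from cyclic stretch, while soft tissue far
from calcification sustains the full physiological stretch. Because the
mechanobiology of vascular smooth muscle cells depends strongly on the
stretch they experience, this stretch partitioning is a candidate mechanism
for the association between extensive macro-calcification and clinically
stable plaques.

This package implements the in-silico half of that argument end to end on
*synthetic* geometry: generate a labeled vessel cross-section, inflate it to
diastolic (80 mmHg) and systolic (140 mmHg) luminal pressure with a
hyperelastic finite-element model, and quantify how principal tissue stretch
distributes relative to the calcification — per-tissue distributions,
centerline profiles, and near-(<1 mm) versus distant-(>1 mm) zone statistics
against a 12.5% reference stretch line. Patient imaging, image restoration
and segmentation are out of scope; the synthetic generator stands in for the
segmentation product.

## Constitutive model

Each tissue is an isotropic, quasi-incompressible three-parameter Yeoh
solid. With deformation gradient $F$, $J = \det F$, isochoric first
invariant $\bar I_1 = J^{-2/3}\,\mathrm{tr}(F^TF)$:

$$W = c_1(\bar I_1 - 3) + c_2(\bar I_1 - 3)^2 + c_3(\bar I_1 - 3)^3
      + \tfrac{\kappa}{2}(J-1)^2 .$$

The constants (Pa) are literature-based experimental fits per tissue:

| | MATX | CALC | LRNC |
|---|---|---|---|
| $c_1$ | $2.35\times10^4$ | $3.02\times10^5$ | $2.96\times10^4$ |
| $c_2$ | $1.26\times10^5$ | $-2.28\times10^5$ | $-3.32\times10^4$ |
| $c_3$ | $1.12\times10^5$ | $2.61\times10^5$ | $1.29\times10^5$ |

The small-strain shear modulus is $\mu_0 = 2c_1$ (CALC $6.04\times10^5$ >
LRNC $5.92\times10^4$ > MATX $4.70\times10^4$ Pa). The negative $c_2$ of
CALC and LRNC never produces softening in the working range: the cubic in
$(\bar I_1-3)$ has a negative discriminant for both, and
`energyPathMinimum()` verifies non-negativity along incompressible uniaxial
and equibiaxial paths for stretches in [0.8, 1.5].

**Design choices.** Whether published plaque-tissue Yeoh fits use the full
or the isochoric first invariant is rarely stated; we fix the isochoric split
with a quadratic volumetric penalty — the standard choice for
near-incompressible soft tissue — and note that stress predictions may
differ marginally from a full-$I_1$ implementation of the same constants. Incompressibility is
enforced by penalty rather than a Lagrange-multiplier (mixed) formulation:
$\kappa = 1000\,\mu_0$ per tissue keeps $|J-1| \lesssim 10^{-3}$ at
physiological loads while avoiding saddle-point solvers; both $\kappa$ and
the positivity-scan range are configurable.

## Boundary-value problem and discretization

The primary solve is 2D plane strain on the cross-section (out-of-plane
stretch fixed at 1), reflecting axially tethered vessels and the
cross-sectional readout; patient-imaging analyses of this kind solve 3D
tetrahedral models but read stretch out on cross-sections, which the 2D
model targets directly. Quadratic interpolation is retained:
6-node isoparametric triangles with the 3-point interior quadrature rule
(the standard slightly-reduced rule for quadratic triangles, which also
mitigates volumetric locking under the penalty).

The segmented/synthetic geometry is treated as stress-free reference and
pressure is applied from zero: no residual stress or prestretch recovery,
a standard limitation of image-based plaque models, whose imaged (loaded)
configuration is all that is observable. Luminal pressure
(1 mmHg = 133.322 Pa) acts as a *follower* load on the deforming lumen
boundary; the outer boundary is traction-free. Since the pressure on a
closed loop is self-equilibrated, only the three in-plane rigid-body modes
need removing. Constraints are placed tangentially to the expected radial
motion ($u_y = 0$ at the outer nodes nearest 0 and 180 degrees, $u_x = 0$
nearest 90 degrees): a fully fixed node would locally obstruct inflation
and visibly pollute the verification against the cylinder solution, whereas
tangential constraints are exactly compatible with axisymmetric expansion
and carry (numerically) zero reaction at equilibrium — `reactionBalance()`
checks this.

Geometry is kept in mm with stresses in Pa throughout; (Pa, mm) is a
consistent per-unit-thickness 2D system, so no unit conversion ever enters
the solver.

### Newton continuation

Each load case is reached in 10 uniform pressure increments, each solved by
Newton's method with the consistent tangent including the (unsymmetric)
follower-load stiffness. Two numerical choices deserve explanation:

* **Linear solves.** The tangent is unsymmetric only through the
  follower-load block, which is small and confined to lumen-boundary dofs.
  We factor the symmetric part with sparse Cholesky and solve the true
  unsymmetric system by iterative refinement (preconditioned Richardson,
  tolerance $10^{-12}$ relative), falling back to general sparse LU when
  the refinement stalls or the symmetric part is indefinite. This keeps the
  exact Newton direction at roughly the cost of a symmetric solve.

* **Line search.** The search is *admissibility-based*: the Newton step is
  backtracked only when it inverts an element (or explodes), never on the
  residual norm. With a quadratic volumetric penalty the residual norm
  overshoots transiently on perfectly convergent Newton steps (the
  second-order remainder of $\kappa(J-1)$ scales with $\kappa$); a
  norm-descent backtracking search then accepts tiny step fractions and
  stalls, while the full step self-corrects within a few iterations.
  Divergence is guarded by an explosion cap, the iteration cap, and
  automatic load-step halving (up to 5 levels) in the continuation.

Convergence requires the free-dof residual below $10^{-8}$ of the applied
load norm. Everything is deterministic: identical mesh, materials and
settings reproduce bit-identical displacements.

## Verification

`cylinderInflationOracle()` provides the independent semi-analytic check:
plane-strain, exactly incompressible inflation of a homogeneous thick-walled
cylinder, where radial equilibrium reduces to a one-dimensional integral
$P = \int_a^b 2 W'(I_1)(\lambda^2 - \lambda^{-2})\, dr/r$ solved for the
inner-wall stretch by quadrature plus root finding (tolerances $10^{-12}$).
Its value for the MATX annulus (inner radius 3 mm, outer 4 mm, 80 mmHg) was
frozen in the test suite against a fully independent quadrature/bisection
implementation written before the solver existed; both agree to 12 digits.

`convergenceStudy()` meshes the annulus at h = 0.4, 0.2, 0.1 mm and
tabulates the error of the finite-element inner-wall stretch against the
oracle. Two penalty-related subtleties: the study raises
$\kappa = 10^5 \mu_0$ so the quasi-incompressible gap to the exactly
incompressible oracle ($|J-1| \sim$ mean stress / $\kappa$) sits well below
the discretization errors being measured; and it relaxes the Newton
tolerance to $10^{-6}$ because at that $\kappa$ the attainable
double-precision residual floor is near $10^{-7}$ of the load scale. The
observed convergence is monotone at order ≈ 2, and the h = 0.1 mm error is
well under 1%.

## Synthetic geometry

`crossSectionSpec()` describes the section in a polar chart anchored at the
lumen center: a circular outer wall (radius $R_o$, origin-centered), a
circular lumen (radius $R_i$) offset along +x by
`eccentricity` × (largest offset compatible with the 0.5 mm minimum wall
thickness), CALC arcs and LRNC pools given by angular windows (degrees) and
radial windows (fractions of local wall thickness). Overlapping regions are
rejected by name. The mesher inserts every region boundary into the
structured chart grid, so tissue regions are unions of whole elements and
the element label — the label of the region containing the parametric
centroid, ties broken stiffest-first (CALC > LRNC > MATX) — is unambiguous.
All nodes including midside nodes are mapped through the chart, giving
curved isoparametric elements that follow the circular boundaries; element
count scales as expected and total area matches $\pi(R_o^2 - R_i^2)$ to
well under 1% at the default h. An optional seeded angular jitter of the
grid lines is off by default; the generator is then fully deterministic.

How proprietary segmentation products interpolate voxel labels onto
analysis meshes is not documented; the centroid-label rule is this
package's choice.

**Reference stenotic preset** (`referenceStenoticSpec()`): $R_i$ = 2.5 mm,
$R_o$ = 5.5 mm, eccentricity 0.4 (1 mm lumen offset: 2 mm thin wall at 0°,
4 mm thick wall at 180°), one 120°-span CALC arc of 1.2 mm thickness
centered mid-wall on the thick side (radial fractions 0.35–0.65), one
60°-span LRNC pool opposite at mid-wall. These are package choices, made so
the soft matrix contains both near-CALC (<1 mm) and distant (>1 mm) zones:
placing the calcification in the thickened (plaque) side mirrors real
lesions, where calcification develops within the intimal plaque. The
optional thin 3D extrusion mentioned as a validation alternative is not
implemented; verification rests on the cylinder oracle.

## Stretch readout

"Principal tissue stretch" has no universally fixed formula; we
define it as the maximum in-plane principal stretch
$\lambda_1 = \sqrt{\max \mathrm{eig}\, F^TF}$ at the element's
quadrature-point-averaged $F$ (nodal extrapolation on quadratic triangles
has superconvergent-point artifacts), reported as percent elongation
$(\lambda_1 - 1)\times 100$ to match the 12.5%-line convention. Under plane
strain the out-of-plane stretch is identically 1 and excluded, so
compressive values below 0% are representable.

Zone statistics split MATX elements at 1 mm (default) distance from the
CALC region boundary — corner-node segments separating CALC from non-CALC
elements, exact to element-scale faceting — and report per-zone means,
medians, the fraction above the 12.5% reference line, and the distant/near
mean ratio. Element means are unweighted (per the element-population
reading of the zone statistics); profiles are sampled at h/2 along
diametral lines at 0°, 60° and 120° by default, standing in for the
multiple per-vessel cross-sections of a 3D analysis, a construct with no
2D equivalent.

## What the synthetic study shows — and does not

At h = 0.2 mm with the preset geometry and materials, systolic (140 mmHg)
distant MATX averages ≈ 10.7% stretch with ≈ 31% of elements above the
12.5% line, while near-CALC MATX averages ≈ 5.7%; the distant/near ratio is
≈ 1.9 and is mesh-insensitive (1.87–2.05 over h = 0.3–0.15 mm). Replacing
the CALC material by MATX with geometry and zoning frozen raises the near
zone to ≈ 7.7% and collapses the ratio to ≈ 1.4, isolating the material
(load-bearing) effect from wall-thickness geometry. The shielding is
strongly anisotropic around the arc: the abluminal layer behind the
calcification averages ≈ 1.3% while the arc flanks still stretch ≈ 8.6%,
which dilutes the near-zone mean; a 2-fold mean separation is therefore at
the edge of what this particular single-arc geometry yields, and the
package's acceptance suite reports that check honestly rather than tuning
the geometry to it.

Loading is monotone in the bulk — systolic stretch exceeds diastolic in
about 99% of elements — but not exactly elementwise: in near-neutral
elements ($\lambda_1 \approx 1.000$–$1.001$, mildly compressed zones
flanking the arc) the maximum *in-plane* principal stretch can decrease by
up to $\sim 10^{-3}$ as the load redistributes. Elementwise monotonicity is
not a theorem in heterogeneous plane strain, and the test suite states the
strict form and reports its failure rather than hiding it behind a loose
tolerance.

The generator emulates the *topology* of a segmented plaque (eccentric
stenosis, an arc-shaped confluent calcification, a lipid pool) but not its
morphological irregularity, multi-fragment calcifications, residual
stresses, axial variation, or patient-to-patient variability (CTA-based
plaque biomechanics studies are typically small cohorts). Passing tests
therefore demonstrate the
mechanistic claim on idealized sections — stiff inclusions shield adjacent
soft tissue from stretch, by material stiffness and not geometry — not a
patient-level reproduction. Stretch, not stress, is the reported quantity throughout: stretch is what
cell-scale mechanobiology experiments impose, and reporting both invites
confusion between them.

## Problem sizes and runtimes

Default analyses use h = 0.2 mm (≈ 4,400 quadratic triangles, ≈ 18k dof on
the reference geometry); a 140 mmHg case solves in well under a minute on
one core. The verification study's finest annulus is also ≈ 18k dof. The
test suite and the acceptance script use these sizes throughout.

## Known limitations

* Plane strain omits axial stress gradients and out-of-plane shear; the
  thin-extrusion cross-check is future work.
* No residual stress / prestretch: the synthetic (or imaged, hence loaded)
  configuration is treated as stress-free reference.
* Penalty incompressibility caps $|J-1|$ near $10^{-3}$ at the default
  $\kappa$; a mixed u–p element would remove that floor at the cost of a
  saddle-point solver.
* Tissue properties are homogeneous per class and identical across
  sections; no anisotropy (collagen fiber families), viscoelasticity or
  damage.
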