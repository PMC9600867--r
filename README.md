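# plaqueStretch

Finite-element analysis of principal tissue stretch in calcified
atherosclerotic vessel cross-sections.

## The problem

Late-stage carotid plaques mix three tissue classes with very different
stiffness: fibrous/cellular matrix (**MATX**), macro-calcification
(**CALC**, roughly 13× stiffer at small strain) and lipid-rich necrotic
core (**LRNC**). If a large calcification carries the pressure-induced wall
load, the soft matrix next to it is *shielded* from cyclic stretch while
soft tissue far from it sustains the full physiological stretch — a
biomechanical mechanism by which extensive macro-calcification could
stabilize lesions via the stretch-dependent phenotype of smooth muscle
cells. This package is for researchers who want that mechanism as a
reproducible, testable computation: generate an idealized labeled
cross-section, inflate it, and quantify the stretch partition around the
calcification.

## The model

Each tissue is a quasi-incompressible three-parameter Yeoh solid,

W = c₁(Ī₁−3) + c₂(Ī₁−3)² + c₃(Ī₁−3)³ + (κ/2)(J−1)²,  Ī₁ = J^(−2/3) tr(FᵀF),

with literature-based constants per tissue (μ₀ = 2c₁: MATX 4.70e4, LRNC
5.92e4, CALC 6.04e5 Pa) and κ = 1000·μ₀. The cross-section is solved in
plane strain with 6-node isoparametric triangles; diastolic (80 mmHg) and
systolic (140 mmHg) luminal pressures act as follower loads on the deformed
lumen boundary; Newton's method with consistent tangent and load stepping
finds equilibrium. The readout is the maximum in-plane principal stretch
λ₁ = √(max eig FᵀF) per element, reported as percent elongation, summarized
per tissue, along diametral profiles, and as near-CALC (<1 mm) versus
distant (>1 mm) soft-matrix zones against a 12.5% reference stretch line.
The solver is verified against the semi-analytic incompressible
thick-walled-cylinder inflation solution. See the methods vignette
(`vignettes/plaque-stretch-methods.Rmd`) for assumptions and numerical
choices.

## Worked example

```r
library(plaqueStretch)

mesh <- meshGeometry(generateCrossSection(referenceStenoticSpec()), 0.2)
mesh
#> LabeledMesh: 9030 nodes, 4386 quadratic triangles (h = 0.2 mm)
#>   labels: MATX 3564, CALC 602, LRNC 220
#>   boundary edges: LUMEN 129, OUTER 129

materials <- plaqueMaterialPresets()
sol <- solveQuasistatic(mesh, materials, loadCase(140))
stretch <- principalStretch(sol, mesh)
tissueStretchSummary(stretch, mesh)
#>      case pressure_mmHg tissue    n  mean_pct median_pct     p5_pct  p95_pct
#> 1 systole           140   MATX 3564  9.425764   9.547279  0.4881020 17.29897
#> 2 systole           140   CALC  602  1.792902   1.652016  0.6552714  3.07331
#> 3 systole           140   LRNC  220 12.306153  12.342493 11.0359859 13.59439

zoneStatistics(stretch, distanceToCalc(mesh), mesh)
#>      case pressure_mmHg    zone    n mean_pct median_pct frac_above_ref
#> 1 systole           140    near  938  5.73329   5.813868    0.006396588
#> 2 systole           140 distant 2626 10.74471  10.398241    0.311500381
#>   ratio_far_near
#> 1             NA
#> 2       1.874091
```

Reading: at systole the calcification itself barely stretches (1.8% mean),
soft matrix within 1 mm of it averages 5.7%, and distant soft matrix
averages 10.7% with 31% of elements above the 12.5% line — the
calcification shields its surroundings, and the distant tissue carries
stretch on the scale of the 12.5% reference. Swapping the CALC material for
MATX (`substituteMaterial()`) with geometry unchanged raises the near zone
to 7.7% and drops the distant/near ratio from 1.9 to 1.4, isolating the
material effect.

`runPipeline()` drives the whole chain from a YAML/list config and writes
VTK fields, profile CSVs and a deterministic JSON report; a thin CLI
(`inst/exec/plaquestretch.R`, subcommands `generate | solve | analyze |
run | fixtures`) wraps the same functions for shell use.

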