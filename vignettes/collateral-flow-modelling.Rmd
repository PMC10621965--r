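---
title: "Modelling collateral blood-flow redistribution in cortical microvascular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collateral blood-flow redistribution in cortical microvascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(collateralflow)
```

## The problem

Leptomeningeal collaterals (LMCs) are pial vessels connecting branches of
the middle and anterior cerebral arteries (MCA, ACA) across the watershed
line between their territories. At baseline they are nearly dormant -
pressures on both sides are similar, so they carry little flow. When the
MCA is occluded the pressure on its side collapses, and the collaterals
become the main route by which the ACA side back-feeds the ischaemic
territory. `collateralflow` provides an in silico laboratory for this
process: networks with controllable collateral counts, a flow solver, an
inverse model that anchors the network to sparse velocity measurements,
and perturbation states representing occlusion and vasodilation.

## Network representation and flow model

A network is a geometric graph: vertices with 3-D positions (z is
cortical depth, 0 at the surface) and vessels with a diameter, a
hydraulic length, a type (`SA`, `SA_to_CoW`, `LMC`, `DA`, `C`, `AV`) and
a territory side. Units are fixed globally: micrometres, mmHg, mm/s,
um^3/s, mPa s; the single conversion constant (1 mmHg = 133.322 Pa) is
applied only inside the conductance computation.

Flow obeys Poiseuille's law per vessel with an effective viscosity
`mu_eff = mu_p * mu_rel(d, H_D)`. The relative viscosity is the empirical
in vitro tube law of Pries and co-workers; the package exposes
`viscosity_law = "in_vivo"` as an alternative dialect because published
variants differ in whether an endothelial-surface-layer correction is
included. We default to the in vitro law since the flow model makes no
other wall-layer assumption. Haematocrit is constant at 0.3 everywhere -
phase separation at bifurcations is deliberately neglected, so
red-blood-cell velocity equals bulk mean velocity. This is adequate for
network-scale redistribution questions and wrong for single-capillary
haemodynamics, which are out of scope.

Pressure boundary conditions are 100 mmHg at the unique circle-of-Willis
(CoW) inflow vertex and 10 mmHg at every ascending-vein root, held fixed
across all scenarios. The linear system is symmetric positive definite
and solved by sparse Cholesky factorisation; interior mass conservation
holds to ~1e-13 relative on the default fixture (tested at 1e-8).

## Synthetic fixture: what it emulates, and what it does not

Real pial reconstructions with per-vessel measurements are not shipped
with the package, so `synth_pial()` + `default_fixture()` generate a
stated world that reproduces the *structure* of such data:

* one CoW inflow feeding an MCA and an ACA branch (`SA_to_CoW` edges);
* one SA trunk per territory with inner branches toward the midline and
  outer branches away from it, every branch tip carrying a DA root so all
  surface arteries are perfused at baseline;
* 3 LMCs joining matched tips across the midline, spaced > 310 um apart;
* AV roots placed 1:3 around each DA root on a rhombic pattern;
* penetrating trees (random bifurcating, symmetric Murray tapering
  `d_child = d_parent * 2^(-1/3)`) descending to 500 um;
* a stacked hexagonal capillary lattice with the canonical capillary
  geometry: diameter 4 um, length 62 um, tortuosity 1.37.

Default scale is a 1 mm^2 footprint and ~3300 vessels - roughly 30x
smaller than the cranial-window reconstructions the model family targets
(~29 mm^2, ~200k vessels). Scale interacts with collateral physics: on a
small footprint a collateral of realistic calibre would short-circuit the
two territories, because the pial path resistances on either side are far
smaller than in a full-size network. The fixture therefore uses thin
default collaterals (4 um median, bridging a 300 um gap) so that the
*ratio* of collateral conductance to territory demand matches the
physiological situation in which an occlusion collapses MCA-side flow by
~90% while the collaterals carry a several-fold flow increase. Generator
defaults (root diameters 14/18 um, two-leaf trees, 20% inter-layer
connector density) were chosen once so that the baseline fixture lands in
physiological ranges - cortical blood flow of order 100-200 ml/min/100g,
DA-root velocities of a few mm/s, capillary velocities below 1 mm/s - and
are not revisited per experiment.

A green scenario test on this fixture establishes that the implemented
mechanisms produce the expected redistribution *given* the stated world;
it does not establish quantitative agreement with any particular animal,
which would require the original reconstructions.

## The inverse model

Measurements constrain velocity magnitudes on a sparse subset of edges:
precise targets where a line scan exists, ranges (2-10 mm/s at DA roots,
0.4-2 mm/s at AV roots) from literature elsewhere; LMCs without a
measurement default to the median measured LMC velocity (0.53 mm/s when
none is available). The cost is a sum of parabolas, zero at the target or
inside the range. Two design choices the sources leave open:

* **Normalisation.** Each parabola is divided by the squared target (or
  range midpoint) so that a 10% miss on a 0.4 mm/s collateral weighs the
  same as a 10% miss on a 6 mm/s root. Exposed as `normalize` and ON by
  default; without it, slow-vessel constraints are numerically invisible.
* **Magnitudes, not signs.** Line scans measure speed; flow direction is
  not constrained.

The gradient of the cost with respect to every diameter is computed with
the adjoint method: one solve of the (symmetric) system with the
right-hand side `d(cost)/d(pressure)` yields multipliers from which all
sensitivities follow, so an iteration costs two linear solves regardless
of the parameter count. The derivative of the viscosity law with respect
to diameter is taken by a central difference with step `1e-4 d` - the law
is smooth and this contributes error orders of magnitude below the 1e-5
validation tolerance against full finite differences.

The optimizer is projected gradient descent in *relative* diameter space
(`theta = d / d_prior`), which equalises gradient scales across calibres,
with Barzilai-Borwein steps safeguarded by a monotone Armijo
backtracking line search and projection onto the per-category boxes:
+-5% (measured SAs), +-20% (unmeasured SAs, LMCs, feeders), +-50% (DAs,
capillaries, AVs). The solution is intentionally non-unique - thousands
of diameters, dozens of constraints - so tests assert cost and constraint
residuals, never individual diameters. Typical behaviour on the default
fixture: cost ~1e-6 in ~200 iterations (~15 s single-core).

## Perturbation states

* **MCAo** splits a 50 um segment out of the MCA feeder edge upstream of
  the pial network and constricts it to 10% of its baseline diameter. The
  segment is flagged and excluded from tuning and dilation.
* **LMC dilation** multiplies collateral diameters by 1.7 (the uniform
  factor used when no per-vessel dilation measurement exists).
* **Arterial dilation** adds +10% to all SAs and DAs, a simplified proxy
  for autoregulatory or therapeutic vasodilation.
* **Elasticity.** Passive calibre changes follow a linearised
  pressure-diameter law around the baseline state,
  `d = d_ref (1 + c (p_mid - p_mid_ref))`, iterated to a fixed point.
  The sources cite linear elastic theory but print no constants, so the
  default compliance is a package calibration: 0.0012/mmHg, set so that
  occlusion-induced passive constrictions stay below 10% on the default
  fixture (observed maximum ~9%), after which rigid and elastic solutions
  differ by ~2% in median flow. Zero compliance reproduces the rigid
  solve exactly.
* **Collateral counts.** `remove_lmcs()` (uniform random retention) and
  `add_lmcs()` (sequential rejection sampling with spacing > 310 um and
  length <= 1000 um) build the 0% / 50% / 100% collateral scenarios.

## Analysis conventions

Territory sides are assigned by tracing each DA root's supply upstream
along surface arteries, always following the incoming edge with the
largest inflow, until the MCA or ACA feeder is reached; capillaries and
venous trees inherit the side of the nearest DA root in the pial plane -
exactly the Voronoi-cell membership around the DA roots, computed as
nearest-root queries (cell areas, where needed, come from grid
quadrature over the convex-hull footprint; no polygon library is
required). Relative changes are `(agg_new - agg_base)/agg_base` with
mean or sum aggregation; flows enter as magnitudes because occlusion
reverses directions and perfusion is reported positive, while pressures
enter signed. Feeder edges and leaf-to-capillary connectors are excluded
from class statistics, and capillaries farther than 200 um from any DA
edge can be excluded from velocity summaries as border artefacts.
Distances to collaterals are planar point-to-segment distances binned at
250 um. Cerebral blood flow is total inflow normalised per footprint
area, per tissue volume (area x lattice depth) and per mass at
1046 kg/m^3.

## Numerical choices and degenerate inputs

* Flow sign convention: positive from endpoint `v1` to `v2`; direction
  changes between states compare these signs on common edges, excluding
  dead edges (|q| below 1e-10 of the median magnitude).
* Ties when attaching a sampled DA root to equidistant SAs break toward
  the lower edge id; attachment splits the host edge at the orthogonal
  projection point.
* Tortuosity is encoded as hydraulic length exceeding the chord; no
  wiggly polylines are generated, since only length enters resistance.
  Inter-layer capillary connectors span a layer gap larger than the
  in-plane chord and carry a correspondingly longer hydraulic length.
* Networks whose free vertices are disconnected from every boundary
  vertex produce a singular system; the solver reports the offending
  vertices instead of returning garbage.
* `validate_network()` reports violations rather than raising, so a
  partially built network can be inspected.

## Known limitations

Phase separation, haematocrit heterogeneity, pulsatility, autoregulation
dynamics, reperfusion and oxygen transport are all out of scope. The
penetrating trees are statistical stand-ins, not samples from an
anatomical database; collateral diameters in the fixture are scale
compensations, not measurements. Quantitative reproduction of published
per-animal relative-change percentages is not attainable without the
original case reconstructions, and the package does not attempt it.
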