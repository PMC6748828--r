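---
title: "Edge and face mechanics of a turgid meristematic cell: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge and face mechanics of a turgid meristematic cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(turgorcell)
```

## The scientific question

Directional (anisotropic) growth of plant cells is classically attributed
to the net orientation of cellulose microfibrils at cell faces: the wall
extends preferentially perpendicular to the stiff fibrils. A second,
independent mechanism acts at the geometric *edges* of the cell, where
membrane trafficking can locally modify wall properties. `turgorcell`
implements a cell-scale mechanical model in which both knobs — fractional
anisotropy of the fibril phase at faces, and a multiplicative stiffness
factor at edge bands — can be turned independently, so that their
interaction can be explored under turgor-driven inflation. The package
asks the qualitative question: *can increased fibril anisotropy at faces
compensate for softened edges?* Its companion morphometrics module
implements the statistics used to quantify fibril/microtubule anisotropy,
edge-localised fluorescence, root thickness and 3D cell growth in
microscopy data, each validated on synthetic data with known truth.

## Constitutive model

The wall composite is hyperelastic with strain-energy density

$$\Psi = \frac{K}{2}(\ln J)^2
 + \frac{(1-\vartheta_f)\,\mu_m + \mu_c}{2}\,(\bar I_1 - 3)
 + \frac{\vartheta_f\,\mu_f}{2}\,(I_4^* - 1)^2 ,$$

with $J = \det F$, $\bar I_1$ the isochoric first invariant, and the
generalized fiber invariant $I_4^* = \mathrm{tr}(H \bar C)$, where

$$H = \xi\, a_0 \otimes a_0 + \frac{1-\xi}{3} I$$

is the structure tensor of a fibril distribution with mean direction
$a_0$ and fractional anisotropy $\xi \in [0,1]$ (`fa`). $H$ interpolates
between the isotropic second moment $I/3$ ($\xi = 0$) and perfect
alignment $a_0 \otimes a_0$ ($\xi = 1$), and $\mathrm{tr}\,H = 1$ so that
$I_4^* = 1$ in the reference state for every $\xi$.

Choices worth making explicit:

* **Functional forms.** The volumetric, matrix and cross-link terms are
  the simplest neo-Hookean forms compatible with an isotropic matrix plus
  isotropic cross-linking, and the fiber term is the standard-reinforcing
  quadratic in $(I_4^*-1)$. The matrix term is weighted by
  $(1-\vartheta_f)$ and the fiber term by $\vartheta_f$; the cross-link
  term is unweighted, treating cross-linking as a property of the whole
  network rather than of either phase alone.
* **Fiber compression.** By default the fiber term is active in both
  tension and compression; instantaneous inflation puts the wall in
  tension, so the distinction rarely matters here. A `tension_only_fibers`
  solver option disables the fiber contribution when $I_4^* < 1$.
* **Units.** Internally micrometre–megapascal (stresses in MPa, lengths in
  µm), which keeps the stiffness matrix well scaled at cell scale; config
  readers accept SI and convert.
* **Near-incompressibility.** $K$ is a penalty bulk modulus
  ($K/\mu \sim 10^2$–$10^3$ with the printed parameters), not a mixed
  formulation; the element technology below is chosen to survive it.

Default face parameters are $K = 10$ GPa, $\mu_m = 18$ MPa,
$\mu_f = 1.2$ GPa, $\mu_c = 18$ MPa, $\vartheta_f = 0.5$.

## Geometry, regions and scenarios

The idealised meristematic cell is a closed box shell, by default
20 µm (longitudinal, x) × 10 µm (transverse, y) × 10 µm (radial, z) with
a uniform 0.5 µm wall. These dimensions are a modelling choice of this
package (a typical young lateral-root meristematic epidermal cell); they
are fully configurable. Elements whose centroids lie within 1 µm of one
of the twelve geometric edge lines form the edge region — the same 0–1 µm
band the image-analysis edge statistics use — and ties at corners go to
the nearest edge line, so corners belong to edges. Edges are sharp
(unfilleted): the mechanical distinction is carried by the band, not by
fillet geometry.

A *scenario* consists of: a case (which faces carry anisotropic fibrils —
case 1 none, case 2 the longitudinal-anticlinal and inner periclinal
faces, case 3 those plus the outer periclinal face), an edge factor
multiplying $\mu_m, \mu_f, \mu_c$ in the edge region (never $K$ or
$\vartheta_f$), the FA values of isotropic and anisotropic faces, and the
turgor pressure. The anisotropic mean fibril direction is transverse: in
the wall tangent plane and perpendicular to the organ axis (ŷ on
periclinal faces, ẑ on longitudinal-anticlinal faces). Isotropic faces
and edges carry the fixed convention $a_0 = \hat y$, mechanically
irrelevant at FA = 0 and nearly so at FA = 0.08.

Turgor defaults to 0.8 MPa — a typical root-cell turgor scale, stated
here as a package assumption and configurable per scenario.

## Discretisation and solver

* **Elements.** Trilinear hexahedra with an *energy-consistent F-bar*
  volumetric treatment: the element strain energy evaluates $\Psi$ at
  $\bar F = (J_0/J)^{1/3} F$ with $J_0$ the centroid Jacobian, and the
  internal force is the exact analytic gradient of that element energy
  (including the centroid coupling term). This mitigates volumetric
  locking at the penalty $K$ while keeping the discrete problem a genuine
  potential minimisation.
* **Follower pressure.** Turgor acts on the closed lumen surface through
  the enclosed-volume potential $-pV(u)$, with $V(u)$ evaluated by
  quadrature over the deformed facets and the load vector as its exact
  gradient. A dead-load option exists for diagnostics.
* **Constraints.** The pressure on a closed surface is self-equilibrated,
  so only rigid-body motion needs constraining: 3-2-1 pins on three
  well-separated nodes of the inner-periclinal face (pins carry no load).
  Because the pins fix an arbitrary rigid gauge, all displacement
  readouts first remove the best-fit (Kabsch) rigid motion; this makes
  them invariant to the pin choice to solver tolerance. An "in-tissue"
  `fix_inner` mode clamps the whole inner face instead.
* **Nonlinear solution.** The flat reference state of a thin pressurised
  wall is the hard part: bending stiffness is nearly singular, membrane
  stiffening only develops with deflection, and the volumetric penalty
  makes the residual violently nonlinear along the bending modes — plain
  load-stepped Newton stalls at line-search factors of $10^{-3}$.
  Because the discrete problem is a potential minimisation, the solver
  uses Newton directions with an Armijo backtracking line search *on the
  total potential*, an adaptive Levenberg diagonal shift whenever the
  direction fails to descend, and a switch to residual-norm acceptance in
  the endgame (where energy decrements drop below evaluation noise). One
  step of iterative refinement on each linear solve counters the
  conditioning of the penalty-stiffened shell. Warm starts (`init`/`u0`)
  let parameter sweeps skip the flat-state phase entirely.
* **Tangent.** Element stiffness is obtained by central finite
  differences of the element gradient (strain perturbation $10^{-6}$), so
  it is consistent with both the F-bar coupling and the follower load by
  construction; solver verification tests pin this consistency down to
  $10^{-9}$ relative.
* **Convergence.** $\|R\| \le \max(\text{rtol}\,\|f_\text{ext}\|,
  \text{atol})$ with rtol $10^{-8}$ by default; converged states are
  deterministic and independent of the load-step count to $10^{-6}$
  relative.

## Readouts

`max_outer_displacement` is the maximum displacement magnitude over nodes
of the outer-periclinal face after rigid-motion removal — the "cell
swelling" readout; a whole-cell variant (`max_displacement`) is also
reported. `edge_stress_concentration` is the volume-weighted mean element
von Mises stress over edge elements divided by the mean over face
elements.

## Morphometric statistics

* **Nematic texture anisotropy.** Per pixel, the unit direction normal to
  the intensity gradient (the local fibril direction) enters the mean
  nematic tensor $M$; the score is $\lambda_1 - \lambda_2 \in [0,1]$ and
  the angle is the principal eigenvector. Pixels with negligible gradient
  are excluded; a constant image is reported as anisotropy 0 with a
  degenerate flag and angle 0 by convention. This *raw* anisotropy is a
  different statistic from the *per-cell normalisation*
  $(A_{max}-A_{min})/(A_{max}+A_{min})$, which rescales each cell's
  extreme anisotropy values to [0, 1]; both are exposed and documented
  separately, and users should state which one a figure uses.
* **Hysteresis filter.** The printed rule "mean and maximum intensity +
  2 SD" is ambiguous; the implemented reading is low = mean, high =
  min(mean + 2 SD, max) — the only parse that guarantees low ≤ high —
  with both rules overridable by explicit numbers. Components of the
  low mask are kept when they contain a high voxel (26-connectivity).
* **Edge colocalisation.** Standard Manders $M_1, M_2$ per edge region,
  with regions occupied < 10% by either channel flagged excluded.
* **Root diameter.** Nearest-neighbour distances between two traced
  flanks, excluding points within 100 µm arc length of the tip; exact on
  parallel traces, sub-pixel on noisy ones.
* **Growth decomposition.** Volume ratio from watertight surface-mesh
  volumes; directional ratios from axis-aligned extents in the organ
  frame — exact for affine growth, which is also what the synthetic
  generator produces. Cells below 1.5-fold volume growth per interval are
  classified meristematic. Extent-based ratios (not principal strains)
  match the per-direction growth readout and keep the statistic exact in
  the affine case.
* **Edge enrichment.** Within the 0–2 µm outer shell, voxels within 1 µm
  of an anticlinal wall are edge voxels, assigned to the nearest edge;
  per-edge mean intensity is normalised by the voxel-weighted mean over
  all edge voxels (so the weighted mean of reported ratios is 1). The
  per-edge (unweighted) normalisation alternative would weight short and
  long edges equally; the voxel-weighted default was chosen so the
  normaliser is the cell's total edge signal. An edge is "transverse"
  when its direction is within 45° of the transverse axis.

## The synthetic generators

Every statistic has a seeded generator producing inputs with attached
ground truth, forming generate → estimate → compare loops in the test
suite: oriented stripe/noise blends of controlled coherence (fibril
textures), binary supports with controlled overlap (colocalisation
pairs), tapering two-flank outlines with an analytic retained-region mean
diameter, affinely grown cuboid surface meshes, and edge-banded intensity
volumes with labelled cuboid surfaces. Noise is additive Gaussian clipped
at zero (vertex jitter for meshes, off by default); all randomness is
seed-threaded with the caller's RNG state restored.

What the generators deliberately do *not* emulate: point-spread-function
blur and optical sectioning, curved or irregular cell geometry,
segmentation errors, and non-affine growth. Passing the recovery suite
therefore shows the statistics are implemented correctly, not that they
are robust to every property of real confocal data.

## Problem sizes and numerical tolerances used in the tests

The scenario-ordering suite runs on a coarse mesh (in-plane element size
3.4 µm, two elements through the wall, 436 elements), where every
qualitative ordering already holds; scenario solves there take seconds to
about a minute. The thin-shell verification uses a cubed-sphere shell
(radius 10 µm, wall 0.4 µm, 2368 elements) against the pressure-vessel
formula $pR/2t$ at 5%, and the mesh-convergence check compares the
default scenario at in-plane resolutions 1.0 µm and 0.8 µm (2348 and
3396 elements) — the swelling readout converges as $O(h^2)$ once the
in-plane size drops below about 1.8 µm, and this pair sits in that
asymptotic regime. Morphometric fixtures are 64–128 px
images and ~50³-voxel volumes. Material-point checks use relative
tolerances $10^{-5}$ (stress vs energy differences) and $10^{-10}$
(objectivity); solver determinism is bit-exact.

## Known limitations

* Instantaneous hyperelastic response only: no viscoelasticity, plastic
  yielding, growth over time, or wall-synthesis feedback.
* One cell in isolation; no neighbouring cells, contact or tissue
  stresses (beyond the crude `fix_inner` mode).
* Sharp-edged box geometry; real cells are rounded and tapering.
* Trilinear hexahedra resolve the thin wall economically but converge
  slowly in bending-dominated regimes; quantitative displacement values
  carry discretisation error at coarse resolutions even where the
  qualitative orderings are stable.
* The morphometrics run on synthetic fixtures; applying them to real
  microscopy requires upstream segmentation and registration outside this
  package's scope.
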