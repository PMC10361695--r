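---
title: "Modeling ventricular wall loading and periventricular WMH colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ventricular wall loading and periventricular WMH colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Periventricular white matter hyperintensities (pvWMHs) — bright FLAIR
lesions hugging the lateral ventricles — appear preferentially at the
anterior and posterior horns and along the edges of the ventricular body.
One candidate mechanism is mechanical: every heartbeat pressurizes the
ventricular system, and the ependymal cell monolayer lining the wall is
stretched most where the wall is most sharply curved. Chronic stretching of
the intercellular junctions would let CSF leak into periventricular tissue,
seeding lesions exactly where loading peaks.

`ventriwall` implements that analysis end to end as a tested pipeline:
quasi-static hyperelastic finite-element pressurization of a brain-like
domain, kinematic "mechanomarkers" of wall loading, FLAIR-style WMH
segmentation, and a statistical comparison of the markers in WMH-covered
versus adjacent wall regions. Because no subject MRIs are distributed with
the underlying study, all inputs are generated by a seeded synthetic phantom
module that is itself first-class, tested code.

## The model

### Constitutive law

Brain tissue is modeled as a one-term Ogden hyperelastic solid with
exponent 2 and a volumetric/isochoric split,

$$\Psi = \frac{\mu}{2}\left(\bar\lambda_1^2 + \bar\lambda_2^2 +
\bar\lambda_3^2 - 3\right) + \frac{\kappa}{4}\left(J^2 - 1 - 2\ln J\right),$$

where $J = \det\mathbf{F}$ and $\bar\lambda_i$ are the isochoric principal
stretches. With exponent 2 the isochoric term equals
$\tfrac{\mu}{2}(J^{-2/3}\,\mathrm{tr}\,\mathbf{C} - 3)$ — a compressible
neo-Hookean form — so the first Piola–Kirchhoff stress and the consistent
tangent are closed-form in $\mathbf{F}$ and no eigen-decomposition (or safe
branch for coalescent eigenvalues) is needed anywhere in the stress update.
Both are verified against finite differences of the energy at every release
(relative error below $10^{-6}$ over random states).

Default parameters (mm–kPa unit system):

| tissue | $\mu$ | $\kappa$ | note |
|---|---|---|---|
| gray matter | 0.34 kPa | 3.3 kPa | Poisson ratio $\approx 0.45$ |
| white matter | 0.68 kPa | 6.6 kPa | WM:GM stiffness ratio 2 (configurable) |
| WMH tissue | as WM | as WM | no separate properties are assigned |
| subarachnoid space | 0.3846 Pa | 0.8333 Pa | from $E = 1$ Pa, $\nu = 0.30$ |

### Loading and solver

Peak hemodynamic loading is a quasi-static surface pressure state: 0.300 kPa
on the ventricular wall acting into white matter and 0.290 kPa on the gray
matter–CSF interface acting into gray matter, with all outer-surface nodes
fixed (the skull is omitted). Pressures are *follower* loads by default
(they stay normal to the deforming surface, the standard model for fluid
pressure; a dead-load mode is retained for verification) and both loads ramp
proportionally over the increments. The discretization is displacement-based
linear tetrahedra with a single quadrature point — matching the mesh class
the analysis is designed for — solved by Newton iteration (default: 10
increments, relative tolerance $10^{-8}$, at most 25 iterations) with a
supernodal sparse Cholesky factorization; the follower-pressure tangent of a
closed pressurized surface is symmetric because enclosed pressure is a
conservative load, and a sparse-LU fallback covers indefinite states. At
$\nu = 0.45$ the elements are only mildly incompressible; the thick-walled
sphere oracle (below) quantifies the residual locking, so no mean-dilatation
stabilization is applied (for single-point tetrahedra the element-mean
dilatation is the quadrature-point dilatation, so such a switch would be a
no-op anyway).

Verification is oracle-based rather than regression-based:

- a pressurized thick-walled sphere against an independent 1D
  spherically-symmetric boundary-value solver (ODE shooting via `deSolve`),
  converging monotonically to within 3%;
- a homogeneous uniaxial-stress patch test reproduced to machine precision
  on an unstructured block;
- load linearity in the small-pressure limit;
- tangents against finite differences of assembled residuals.

### Direction field and mechanomarkers

Projection directions are computed a priori on the reference configuration
from a Laplace problem with Dirichlet values 1 on the ventricular wall, 0.1
on the gray matter–CSF interface and 0 on the outer surface, using the same
linear shape functions as the mechanical solver. For each tetrahedron owning
a wall face, $\mathbf{n} = -\nabla T / \lVert\nabla T\rVert$ points from the
cavity into the tissue (the field decreases away from the cavity); the
thinning ratio is insensitive to this sign choice. The per-element constant
gradient is used directly with no nodal smoothing.

From $\mathbf{C} = \mathbf{F}^\mathsf{T}\mathbf{F}$ the markers are:

- normal stretch $\lambda_n = \sqrt{\mathbf{n}\cdot\mathbf{C}\mathbf{n}}$
  (the square root makes it a true stretch so that the ratios below multiply
  area and thickness changes);
- extremal tangential stretches $\lambda_{t,\max} \ge \lambda_{t,\min}$,
  the square roots of the eigenvalues of the $2\times 2$ restriction of
  $\mathbf{C}$ to the tangent plane — eigen-stretches rather than stretches
  along fixed tangents, which makes them invariant under rotations of the
  tangent basis (tested to $10^{-10}$);
- the ependymal thinning ratio
  $\mathcal{T} = \lambda_{t,\max}\lambda_{t,\min} / \lambda_n$ (tangential
  area change over apical–basal thickness change; 1 in the reference state);
- maximum principal strain, by default the logarithmic strain
  $\ln\lambda_{\max}$ (the customary large-strain output of commercial FE
  codes; Green–Lagrange and nominal measures are selectable since the
  choice is not dictated by the analysis).

Element values are aggregated to wall nodes by reference-area-weighted
averaging over the adjacent wall faces.

### Wall curvature and pvWMH thickness

Mean curvature is computed on the reference wall by fitting the bi-quadratic
patch $S(u,v) = a u^2 + 2 b u v + c v^2$ to the 1-ring neighbors of each
wall node (extended to the 2-ring below 5 neighbors; 3 unknowns want an
over-determined fit) in a local frame whose height axis is the area-weighted
vertex normal, and evaluating

$$k_{1,2} = a + c \pm \sqrt{(a - c)^2 + 4 b^2}, \qquad
\mathcal{K} = \tfrac{1}{2}(k_1 + k_2).$$

These $k$'s are exactly the eigenvalues of the full patch Hessian
$[[2a, 2b], [2b, 2c]]$ (pinned by a 1000-case identity test), a convention
under which a sphere fit ($a = c = 1/(2R)$) yields $k = 1/R$; it is used
consistently everywhere, including the sphere benchmarks. The height axis
points *toward* the cavity, so horn tips — convex as seen from inside the
cavity — carry positive curvature; the analysis never depends on the sign
convention beyond this documented choice. The curvature frame is deliberately
the area-weighted surface normal, not the Laplace normal: curvature is a
property of the reference surface, while the Laplace frame serves stretch
projection and ray casting.

pvWMH thickness casts each WMH-overlapping wall node's outward normal ray
through the tetrahedra (exact interval clipping against the four face
half-spaces), stops at the first intersected element that is not
WMH-labeled, and reports the maximum distance from the node to the four
vertices of the furthest WMH element intersected. Rays that exit the mesh
while still in WMH tissue are flagged rather than manually adjusted. The
implementation is pinned to a brute-force ray-marching oracle on randomized
slab fixtures.

### WMH segmentation

The intensity rule: voxels of the whole-brain mask $\Omega$ brighter than
$\mu + k\sigma$ (defaults $k = 2.5$; $\mu$, $\sigma$ the naive sample mean
and SD over $\Omega$ — the estimate is deliberately not robustified, and
sample SD with denominator $n-1$ is used since the choice is conventional
and immaterial at brain voxel counts). Connected components (26-connectivity)
whose boundary faces (6-neighborhood) are more than 50% adjacent to CSF are
then deleted — the rule that removes septum and choroid plexus. Bias-field
correction is out of scope; synthetic volumes are generated bias-free.

### Statistics

Wall nodes split into a WMH group (nodes of wall faces overlapping WMH
elements) and an adjacent group (nodes of faces within two edge-adjacency
rings of the WMH faces, excluding the first group); nodes beyond the second
ring belong to neither group. For maximum principal strain, thinning ratio
and mean curvature the package reports group means and SDs, a pooled
two-sample t statistic with integer degrees of freedom $n_1 + n_2 - 2$
(Welch's test is available by flag), the two-sided p value, and the percent
elevation $(\bar x_\mathrm{WMH}/\bar x_\mathrm{adj} - 1)\cdot 100$. No
multiple-testing correction is applied across the three markers, matching
the analysis convention this reproduces; the caveat that wall nodes are
spatially autocorrelated (so the t test treats correlated samples as
independent) is reproduced deliberately rather than "fixed", and is noted in
the report.

## The synthetic phantom

The phantom is an idealized "ventricle-in-brain": an ellipsoidal cavity
(default semi-axes 9, 6, 5 mm) with `n_horns = 2` Gaussian-profile horn
protrusions (length 5 mm, tip radius 2 mm — the highest-curvature wall
features by construction), surrounded by a white-matter shell, a 4 mm
gray-matter shell and a 3 mm ultrasoft subarachnoid shell inside a 30 mm
outer sphere. This is a scaled-down domain (about half linear scale of an
adult head) chosen so the full pipeline — roughly 7,700 nodes and 42,000
tetrahedra at the default two-zone resolution of 1.2 mm at the wall and
2.4 mm in the parenchyma — solves in about a minute on one CPU; all
geometric and statistical checks are scale-free or compare against oracles
on the same domain.

Meshing extrudes a subdivided icosphere radially in conforming prism layers
(each prism split into three tetrahedra by the minimum-vertex-index diagonal
rule, which guarantees watertight conformity), with layer thicknesses graded
fine-to-coarse away from the wall. A constrained-Delaunay mesher would be
the conventional alternative; the radial extrusion was chosen because it is
deterministic, dependency-free, yields smooth closed tagged surfaces (every
wall triangle borders exactly one white-matter tet), and supports the exact
two-zone sizing. The construction is star-shaped about the origin, which is
the main geometric restriction: bilateral anatomy, septum and choroid
plexus are out of scope.

All randomness (horn direction/amplitude jitter, random WMH patches, FLAIR
noise) flows from one integer seed through a scoped generator; the same
spec always produces byte-identical meshes.

WMH labels (`at_horns` mode) relabel white-matter elements whose centroid
lies within the cap thickness (3 mm) of a top-decile-curvature wall node;
`random_patches` places seeded random patches instead. FLAIR-like volumes
rasterize the element labels at $3^3$ sub-voxel resolution (point-in-tet at
sample centers, majority-aggregated), then assign brain voxels Gaussian
noise whose sub-voxel level is `background_sd` — so voxel-level noise is
reduced by the block averaging, as in an acquisition that integrates over
the voxel — and shift lesion voxels up by `lesion_contrast` (default 4)
times `background_sd`. Lesion contamination inflates the naive $\sigma$
estimate, which is precisely why the $k = 2.5$ threshold keeps background
false positives negligible on lesioned volumes while the lesion-free
false-positive rate matches the Gaussian tail $1 - \Phi(k)$; both regimes
are tested. The voxels are isotropic (1.5 mm) rather than the anisotropic
$0.7 \times 0.7 \times 4$ mm of a clinical FLAIR; whether anisotropy changes
the threshold-rule behavior is untested here.

## What the phantom does and does not show

On the loaded default phantom the three mechanomarkers are all
significantly elevated (pooled t, $p < 0.05$) in WMH-covered wall regions
versus the adjacent wall, across seeds — the qualitative colocalization
finding this analysis exists to probe — and maximum principal strain and
thinning rank-correlate strongly across wall nodes (Spearman $\rho > 0.5$).
Mean curvature maxima (about 1.2 mm$^{-1}$) and maximum displacement (about
0.54 mm) fall in the physiologically reported ranges.

The absolute stretch *magnitudes*, however, are smaller than on real
anatomy, and the wall sits in net compression: with near-balanced loads
(300/290 Pa) on closed surfaces, every material point is immersed in an
almost hydrostatic ~295 Pa stress state, tissue compresses volumetrically
by roughly $p/\kappa \approx 4\%$, and deviatoric response is bounded by
the 10 Pa differential times the geometric concentration factor. A smooth
idealized cavity concentrates far less than real ventricular anatomy
(razor-sharp horns, thin septa, walls abutting CSF fissures), so on the
phantom $\lambda_{t,\max}$ stays slightly below 1 and the maximum principal
strain slightly below 0, whereas subject-specific models reach
$\lambda_{t,\max} \approx 1.05$ and visible positive strain at their
sharpest features. The *contrast* between high-curvature (WMH) and adjacent
wall — the quantity the statistics test — survives this difference and is
what passing tests demonstrate; passing tests do not demonstrate
subject-level stretch magnitudes, inter-subject variability, or anything
about real FLAIR artifacts (bias fields, anisotropic voxels, partial
volume at the septum).

Under the atrophy variant (`apply_isotropic_shrinkage`, which shrinks the
stress-free configuration of white and gray matter by a factor $g$ found by
bisection until the cavity volume gain matches a target such as 20%), wall
loading is markedly higher than under hemodynamic pressure alone, consistent
with atrophy-driven ventricular expansion being the larger chronic load.

## Numerical choices and degenerate inputs

- Unit system mm–kPa (pressures in Pa are converted; 300 Pa = 0.3 kPa) for
  stiffness-matrix conditioning at millimeter mesh scale.
- Newton convergence: residual norm below $10^{-8}$ times the external
  force norm (or $10^{-10}$ absolute for unloaded states); a step that
  inverts an element is halved up to 12 times; non-convergence returns the
  last converged increment with `converged = FALSE` rather than an error.
- Inverted elements during assembly raise an error naming the element and
  increment.
- The tangential eigen-stretch tie (umbilic points) is harmless: the
  eigenvalues are returned sorted and only their set enters the markers.
- Rank-deficient curvature fits (after 2-ring extension) are flagged and
  propagate as `NA` rather than fabricated values.
- Zero pooled variance (e.g. zero-pressure runs) aborts the t test with an
  explicit error; the pipeline reports the statistics stage as skipped.
- `wmh_cap_thickness` of zero (no candidate elements) and constant-intensity
  volumes (zero $\sigma$) are rejected with explicit errors.
- Bisection for the atrophy factor brackets $g \in [0.85, 1]$ and errors
  with a suggestion to widen the bracket if the target gain is outside it.

## Problem sizes used by the test suite

The suite runs entirely on generated geometry: the default phantom
(~42,000 tets) for the end-to-end statistics over five seeds, a coarse
variant (~6,000 tets) for solver-heavy unit tests, spherical shells at
icosphere levels 1–3 for the thick-sphere and harmonic-field oracles, and
small structured slabs for patch, thickness and segmentation fixtures.
These sizes were chosen so the complete suite exercises every stage at
meaningful resolution while remaining runnable on a laptop core.
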