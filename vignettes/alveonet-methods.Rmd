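---
title: "Modelling alveolar wall destruction and the decline of tissue stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling alveolar wall destruction and the decline of tissue stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alveonet)
```

## The model

Emphysema progressively destroys alveolar walls; airspaces enlarge and the
lung loses elastic recoil. `alveonet` represents a small cuboidal block of
parenchyma as a space-filling tessellation of polyhedral cells, one cell per
idealized alveolus, in two geometries:

* **cubic** — `n^3` cubes; 8 cells per side gives the standard block of
  512 cells, 1728 faces and 8856 springs;
* **tetrakaidecahedral (14-hedron)** — truncated octahedra on a body-centered
  lattice (`n^3` whole cells plus `(n+1)^3` corner-sublattice cells that are
  geometrically clipped by the box planes), the classic idealization of
  alveolar geometry. Interior cells have 6 square and 8 regular hexagonal
  faces.

Each wall (face) carries springs from its center to every vertex, and every
distinct geometric edge carries one *shared* edge spring representing the
junction line of septal walls; this sharing is what makes the spring count
of the 512-cell block come out at `4 * 1728 + 1944 = 8856`. Springs are
**tension-only**: the force is `k * eps` (or the stiffening power law
`A*eps + B*eps^p`) for engineering strain `eps > 0` and exactly zero in
compression — thin tissue walls buckle rather than push back. Because a
slack network is unstable, the block is **pre-strained**: all positions are
scaled about the box center by an expansion factor (default 1.2, i.e. 20%
linear strain) and the outer boundary is then held fixed.

Wall destruction is simulated by removing internal faces — never boundary
faces, so the exterior surface stays watertight — under three policies:
uniformly **random** (enzymatic digestion independent of mechanics),
**force-based** (the walls carrying the highest load break, as
enzymatically weakened fibers fail under breathing stresses), and **mixed**
(a fraction `r` per step by force, the rest at random). The first step of
every run is random: some initial insult must seed the process before load
concentration can act. When the last wall adjoining an edge disappears, its
edge spring is broken too. After each step the network is re-equilibrated
and measured.

## Mechanics and numerics

The equilibrium configuration minimizes the total energy: the sum of spring
energies, minus the work of external loads (constant nodal forces, or a
pressure acting on the fan-triangulated exterior facets). The energy
surface of this tension-only network was checked to be effectively convex —
simulated annealing from different temperatures reaches the gradient-descent
minimum (the package keeps `anneal()` as an independent cross-check and
tests agreement to 1e-4 relative on damaged 2^3 blocks).

The minimizer is gradient-based with analytic gradients: limited-memory
BFGS directions with Armijo backtracking, falling back to steepest descent
whenever the quasi-Newton direction fails to descend. The backtracking
guarantees a monotone energy sequence, and only the minimum matters
physically; the quasi-Newton directions merely reach it orders of magnitude
faster than plain descent on these stiff, ill-conditioned surfaces (floppy
cavity modes coexist with taut walls). Equilibrium is
declared when **both** force criteria hold: the maximum and the mean
resultant-force magnitude over the free, still-connected nodes fall below
`1e-6` and `1e-7` (in units of `k * cell_size`). The maximum criterion is
the stricter one for local rearrangements around damage; the mean criterion
is stricter for nearly-uniform deformation modes. Nodes that lose all their
springs (the centers of removed walls) are frozen in place and excluded
from the criteria. Under a pressure boundary the facet forces follow the
geometry, so an outer loop recomputes them after each inner minimization
until the free energy changes by less than `1e-10` (relative) between
passes.

Two spring-energy conventions are supported because the quadratic form can
be written per unit extension or per unit strain (they differ by a factor
of the rest length `L0`): the default is the extension form
`(k/2)(L - L0)^2`. Normalized outputs — `K/K0` and the moment trajectories
— are insensitive to this global prefactor, which is why the choice is a
config switch rather than a modelling commitment.

### Measuring the bulk modulus

`bulk_modulus()` follows the pressure-probe protocol. Starting from a
fixed-boundary equilibrium, each boundary node receives a constant external
force equal and opposite to the resultant spring force acting on it; the
boundary is then released (the state is still an equilibrium, now under
dead loads). A small distending pressure increment `delta_P` — by default
1% of the recoil-pressure scale `k * eps0 / cell_size` — is superposed on
the exterior facets, the network re-equilibrates, and
`K = delta_P / (dV/V0)` from the enclosed volumes before and after. The
probe is side-effect-free and, in the linear-response regime, insensitive
to `delta_P` (halving it moves K by under 0.1% on the intact 6^3 block).

For the intact cubic lattice the response is closed-form:
`analytic_bulk_modulus()` evaluates `K = rho_m * f'(eps0) / (9 * lambda0)`
from the interior spring density `rho_m` — for linear springs and default
units simply `K = k / (lambda0 * cell_size)`. This is the bulk (interior)
value; the measured K of a finite block approaches it from below as the
softer boundary layer becomes negligible, and agrees within 1% by 6 cells
per side. That finite-size softening is also why the uniform-expansion
energy of the *whole finite block* (which counts boundary springs at full
weight) would overestimate K, and why the density is read off an interior
cell.

### Airspace volumes

Cells merged by removed walls form **airspace clusters** (union-find over
the cell adjacency of removed faces); the volume signal of the simulation
is the distribution of cluster volumes. Under the fixed boundary the total
volume is exactly conserved, and the per-cell count is fixed, so
*per-original-cell* volumes could never show the rising mean that
characterizes emphysematous airspace enlargement — merged clusters are the
only reading in which mean airspace size grows, and the one this package
implements. Volumes come from the divergence theorem: every face is
fan-triangulated through its center node and each cluster's remaining
faces, oriented outward, contribute signed tetrahedron volumes (apex at the
origin). This is exact for the non-convex shapes that damaged airspaces
assume, and translation-invariant because the surfaces are closed; the
shared wall between two cells of one cluster cancels pairwise, so cluster
volumes can be accumulated per cell without constructing cluster surfaces.

The first four moments of the cluster-volume distribution — mean `mu` and
central moments `m2, m3, m4` of volumes normalized by the initial
single-cell volume — are recorded at every step, together with `K/K0`.
(Standardized moments of orders 3-4, i.e. skewness/kurtosis, are available
behind a switch in `volume_moments()`.)

## The structure-function estimator

`structfn()` implements the Karhunen-Loeve (PCA) reduction: pooled moment
rows from one or more runs are column-centered, the covariance matrix
(plain covariance, not correlation — the columns are deliberately left on
their natural, dimensionless scales) is eigendecomposed, and the first two
eigenvectors define the structure variables `P1, P2`. Eigenvector signs are
fixed deterministically (largest-magnitude component positive) so
projections are reproducible. The decline in stiffness is then fit by least
squares as the plane `K/K0 = a*P1 + b*P2 + c`; `predict()` projects *new*
runs onto the *fixed* basis — using the basis's own centering means, which
is essential for generalization experiments — and evaluates the plane.
`estimation_error()` reports `100*|Khat - K|/K` per step, and
`crossfit_evaluation()` packages the whole generalization experiment:
fit on a base set of runs, evaluate every scenario, summarize per-run
error quartiles.

Why could one plane describe different destruction patterns at all? Each
run's four moments are strongly mutually correlated, so a trajectory is
close to a one-dimensional path in moment space; two patterns give two
different directions, and the plane spanned by them can capture both *if*
each trajectory's (P1, P2, K/K0) path is itself planar and the two paths
are mutually consistent. The pooled eigenvalue spectrum is extremely
top-heavy (the higher moments grow by orders of magnitude as large
clusters form, and they grow together), so the first two components carry
essentially all the variance — the explained-variance condition is easy to
meet. Whether the *plane fit* is accurate is a much stronger condition;
see the limitations below for how it fares in this model.

## The simulation ensemble

`destruction_ensemble()` packages the study conditions: three random and
three force-based base runs on the 6^3 cubic lattice (pre-strain 1.2,
4 faces removed per step, run until `K/K0` reaches 0.3), plus the held-out
scenarios used to probe generalization — force-based and random runs at
1.5x higher pre-strain (strain 0.3), a mixed run with `r = 0.1`, a
force-based run on a 14-hedral lattice, a force-based run on a 128-cell
(4 x 4 x 8) block, and a force-based run with stiffening nonlinear springs.
Problem sizes (6^3 base; 5^3, 91-cell 14-hedral and 128-cell held-out
blocks) were chosen
as the smallest lattices that separate the destruction patterns cleanly
while keeping a full ensemble re-runnable in minutes on one CPU; the
qualitative contrasts are stable from 4^3 upward.

Parameters that the underlying experiment leaves open are fixed once here:
`Nf = 4` faces per step (a small fixed quantum of damage relative to the
540 internal walls of the base block), pre-strain 1.2 (a physiological
20% linear stretch; the "1.5x higher" variant is strain 0.3), `delta_P` at
1% of the recoil scale, and the power-law coefficients `A = k`, `p = 3`,
with `B` chosen so the tangent stiffness doubles at 30% strain. The
force-ranked cutting order depends only on the load *ranking*, so any
monotone stiffening law selects the same walls.

## What the generator emulates — and what it does not

The synthetic networks emulate the fiber skeleton of alveolar septa in a
small parenchymal block far from airways: space-filling polyhedral
airspaces, tension-only walls, parenchymal interdependence (removing one
wall loads its neighbours — in this model the load concentrates on the
remaining walls of the two cells that lost the partition, so cavities
inflate and grow from their surface), and conservation of total volume
under a fixed boundary. They do **not** model surface tension and
surfactant, alveolar ducts or the axial fiber system, viscoelasticity,
chest-wall coupling (the boundary is a rigid box, not a compliant pleura),
or any biochemical kinetics of enzyme activity; destruction is purely
geometric/mechanical. Passing tests therefore demonstrate the internal
consistency of this idealized mechanism — that destruction *pattern* links
microstructure to stiffness decline — not agreement with animal or human
morphometry.

## Numerical choices and degenerate inputs

* Strain is engineering strain `(L - L0)/L0`; rest lengths are the
  as-built lengths, so the pre-strain factor is also the uniform spring
  strain plus one.
* Face polygons are stored once with a consistent outward orientation per
  adjacent cell (the second cell uses the reversed cycle), so signed
  volumes never need runtime orientation tests; assembly asserts every
  cell's volume is positive.
* Ties in the force ranking are broken by the run's seeded RNG, making
  force-based runs exactly reproducible.
* A face whose springs are all slack carries zero load; a network whose
  eligible walls are exhausted raises a dedicated condition; removing a
  boundary wall or re-removing a wall is an error.
* `kl_basis()` accepts rank-deficient input (zero eigenvalues are kept);
  `structfn()` refuses a degenerate design in which the first two scores
  are collinear.
* The 14-hedral corner cells are true geometric clippings (half, quarter,
  eighth cells with their polygonal caps), so the block is exactly
  space-filling; their volumes enter the initial distribution, which is
  why a 14-hedral run starts with a small nonzero variance.

## Known limitations

* The bulk-modulus closed form is exact only for the cubic lattice
  (uniform expansion is not an equilibrium of the finite 14-hedral block);
  for the 14-hedral lattice K is measured, not derived.
* **The single-plane estimator is not accurate in this model.** The
  cross-fit evaluation in the test suite and acceptance script computes
  maximum relative errors of order 100% and per-run medians of order 20%,
  far above the few-percent regime one would want from a useful
  structure-function surrogate. The cause is a genuine many-to-one
  violation: the two destruction patterns reach the *same* moment values
  at very *different* stiffness. Force-based cutting concentrates damage
  into one growing cavity, so the block softens early while the volume
  moments are still small, and the cavity's volumetric compliance then
  saturates while the moments explode; random cutting percolates — on the
  cubic cell-adjacency lattice a giant merged airspace must appear once
  roughly a quarter of the internal walls are gone — driving the variance
  far above the force runs' values while the block is still stiff. No
  reparameterization of the four moments (standardized, k-th-root,
  mean-normalized, log, cell-weighted) repairs this, and the pressure
  probe itself passes all of its independent oracles, so the failure is a
  property of the model at these block sizes, not of the numerics. The
  within-pattern relation does become more nearly planar as the block
  grows (per-run median errors of a few percent at 512 cells), but the
  cross-pattern merge onto a single plane does not. The qualitative
  structure-function conclusions — the destruction pattern, not just the
  amount of tissue lost, sets the rate of stiffness decline; force-based
  cutting needs about half the walls for the same 60% stiffness drop; the
  variability of airspace sizes rises early and steeply only under
  force-based cutting — are exactly the contrasts the acceptance tests
  verify, and they are robust.
* Random destruction of a small block merges all airspaces well before the
  walls are exhausted; the last steps of a random run carry a degenerate
  (single-cluster) volume distribution.
* Quasi-static only: no inertia, no viscoelasticity, no rupture dynamics.
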