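---
title: "The wall-force model of ball-milling activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The wall-force model of ball-milling activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ballmill)
```

## The model

Ball milling drives reactions with repeated, randomly oriented compressive
impacts. `ballmill` estimates how much of that mechanical energy is
available to a specific reaction step: given the geometry of the reactant
(or pre-reactive adduct) $Q_{min}$ and of the transition state $Q_{TS}$,
and an impact pressure $P$, it predicts the change in activation energy
caused by the compression, direction by direction, and its isotropic
average.

One collision is idealised as two rigid parallel walls squeezing the
molecule along a direction $\hat n(\theta,\phi)$. The model rests on four
assumptions:

1. some fraction of the reactants is already arranged in the reactive
   geometry (for bimolecular steps, the pre-reactive adduct);
2. the potential energy surface itself is unchanged — forces only add or
   remove work along the existing path, they do not create or destroy
   stationary points;
3. the ball radius is much larger than the molecule, so the contact can be
   treated as two flat walls;
4. the force is constant during the (fast) reactive event, with magnitude
   set by the average impact pressure.

The computation proceeds in four stages.

**Alignment.** Both geometries are translated so their mass-weighted
centroids sit at the origin, and the transition state is rotated onto the
reactant by a mass-weighted Kabsch superposition restricted to proper
rotations (covariance $\sum_i m_i\, r_i^{TS} r_i^{min\,\top}$, reflections
removed by the determinant correction — a reflection is not a physical
rigid motion). The residual per-atom displacement field
$\Delta r_i = r_i^{TS} - r_i^{min}$ then satisfies
$\sum_i m_i \Delta r_i = 0$ and $\sum_i m_i\, r_i \times \Delta r_i = 0$:
it contains only the intrinsic deformation of the step. Both residual
norms are stored on the `aligned_path` object and shown by
`summary()` so any numerical leakage of rotation into $\Delta Q$ is
visible.

**Cross-section and total force.** The molecule is enclosed in a
reference sphere. Two readings of its radius are supported
(`radius_mode`):

* `"global"`: $R = \max_i(\lVert r_i\rVert + \delta_i)$, one radius for
  all directions;
* `"directional"` (default): $R(\theta,\phi) = \max_i\bigl(\lVert r_i -
  (r_i\cdot\hat n)\hat n\rVert + \delta_i\bigr)$, the radius of the
  cross-section the molecule actually presents to the walls, which tracks
  its nonspherical shape.

The per-atom padding $\delta_i$ (`delta_mode`) is the van der Waals
radius by default, a constant, or zero. The total force is
$F_{mec}(\theta,\phi) = P\,\pi R(\theta,\phi)^2$, with
$1\,\mathrm{GPa\,\mathring A^2} = 0.01\,\mathrm{nN}$. At $P = 1$ GPa a
molecule with $R \approx 6.7\,\mathring A$ feels $\approx 1.4$ nN.

**Wall forces and work.** The plane through the origin perpendicular to
$\hat n$ splits the atoms into a forward ($r_i \cdot \hat n \ge 0$; ties
assigned forward by convention) and a backward hemisphere. Each atom
receives $F_i = \alpha_i F_{mec} \hat n_i$ with $\hat n_i = -\hat n$
(forward) or $+\hat n$ (backward) — both walls push toward the plane. Only
the uniform weighting $\alpha_i = 1/N_{atoms}$ is implemented; the
configuration object carries the scheme name so alternative weightings
(distance-based, impact-surface) can be added without changing the
interface. Because the forces are constant along the path (assumption 4,
built once from the reactant frame), the work line integral collapses to

$$W_{mec}(\theta,\phi) = \sum_i F_i \cdot \Delta r_i, \qquad
  \Delta E_{a,mec} = -W_{mec},$$

evaluated in nN Å and converted with
$1\,\mathrm{nN\,\mathring A} = 14.3933$ kcal/mol (CODATA Avogadro
constant over the thermochemical calorie; a single named constant,
`nn_angstrom_to_kcal_mol`). Positive work lowers the barrier; with a
user-supplied baseline $E_a$ the modified barrier is
$E_{a,mec} = E_a + \langle\Delta E_{a,mec}\rangle$. The baseline is
metadata from electronic-structure calculations — the package never
computes electronic energies.

**Directional averaging.** Random impact orientations are emulated by a
uniform angular grid: $N$ polar times $2N$ azimuthal nodes with equal
steps $\Delta\theta = \Delta\phi = \pi/N$, and the quadrature

$$\langle\Delta E_{a,mec}\rangle = \frac{1}{4\pi}
  \sum_{\theta,\phi} \Delta E_{a,mec}(\theta,\phi)\,
  \sin\theta\,\Delta\theta\,\Delta\phi.$$

Nodes are cell-centered, $\theta_k = (k+\tfrac12)\pi/N$,
$\phi_l = (l+\tfrac12)\pi/N$: midpoint placement avoids the poles (where
$\sin\theta = 0$ contributes nothing but costs work), avoids the
duplicated $\phi = 0 \equiv 2\pi$ seam, and makes the grid exactly closed
under the antipodal map $(\theta,\phi)\mapsto(\pi-\theta,\phi+\pi)$ —
which the physics requires, since compressing from $\hat n$ and from
$-\hat n$ is the same experiment.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `pressure` | 1 | GPa | average impact pressure; typical milling impacts are a few GPa, case studies use 1–2 GPa |
| `grid_n` | 100 | – | polar grid size; $2N^2$ directions; averages are stable at $N = 100$ |
| `delta_mode` | `"vdw"` | – | padding added to the molecular radius (vdW radii / constant / none) |
| `radius_mode` | `"directional"` | – | cross-section definition, see above |
| `ea` | none | kcal/mol | baseline activation energy, user-supplied |

The van der Waals table shipped with the package combines the Bondi
(1964) compilation with the Mantina et al. (2009) main-group extensions;
d- and f-block elements absent from both carry the RDKit periodic-table
values. The table is a plain-text TSV (`inst/extdata/element_data.tsv`)
and can be replaced per call (`element_table(path)`) or globally
(`options(ballmill.element_table = ...)`): swapping compilations shifts
$R$ by $\lesssim 0.2$ Å and is the cheapest sensitivity check on the
cross-section. Masses are standard atomic weights; isotopes are ignored
because masses only enter the alignment weighting.

Atom correspondence between the two XYZ files is positional: atom $i$ of
the reactant must be atom $i$ of the transition state. No graph-based
atom mapping is attempted — the displacement is a per-index difference,
and silently remapping atoms would be worse than failing loudly on a
mismatched element sequence.

## Design choices in ambiguous corners

* **Directional radius.** The global bound
  $\max_i(\lVert r_i\rVert+\delta_i)$ is direction independent, yet the
  total force is written as a function of direction because the
  cross-section of a nonspherical molecule is not constant. The package
  takes the maximal padded distance from the compression axis as that
  directional cross-section radius and keeps the global bound available
  behind `radius_mode = "global"`, so both readings are reproducible and
  comparable on the same inputs.
* **Hemisphere ties.** Atoms exactly on the dividing plane are assigned
  forward ($\ge 0$). This breaks exact antipodal symmetry only on the
  measure-zero set of directions whose plane contains an atom; the
  midpoint grid makes hitting one numerically unlikely.
* **Superposition direction.** The transition state is mapped onto the
  reactant, and every geometric construction (radius, partition) uses the
  centered reactant frame, consistent with forces being built once and
  held constant along the path.
* **Degenerate inputs.** Identical endpoints give an identically zero
  map; an all-coincident geometry (zero covariance) falls back to the
  identity rotation with a warning; `pressure = 0` gives exactly zero
  everywhere.
* **Determinism.** The main computation has no randomness; CLI runs with
  identical inputs are byte-identical (no timestamps in outputs).
  Fixture generators take explicit seeds and restore the caller's RNG
  state.

## What the synthetic fixtures do and do not show

The package ships generators, not data files:

* `make_axial_pair()` — atoms mirror-paired across $z = 0$, each moved a
  distance $d$ toward the plane. For compression along $z$ the work has
  the closed form $W = F_{mec}\, d$ (the uniform per-atom forces
  telescope), and the mirror pairing keeps the Kabsch rotation at the
  identity, so the fixture tests the full pipeline against an analytic
  value.
* `make_contraction_pair()` — isotropic scaling toward the centroid. A
  contraction moves every atom toward every dividing plane, so
  $\Delta E_{a,mec} < 0$ in *all* directions; an expansion (`factor > 1`,
  requested explicitly) gives the opposite sign everywhere. This pins the
  sign convention end to end.
* `apply_rigid_decoy()` — a random rotation/translation of the transition
  state that the alignment must remove exactly.

These fixtures have analytically known mechanical responses, which is
precisely why they are *not* realistic chemistry: real reaction
displacements are anisotropic and localised, real molecules have mixed
elements and nontrivial shapes, and real barriers come from
electronic-structure theory. Passing the fixture suite demonstrates that
the geometry, force construction, work integral, units and quadrature are
correct — it does not validate the model's physical assumptions (rigid
walls, constant force, uniform weighting) against experiments. Applying
the package to real systems additionally requires reactant/TS geometries
from quantum chemistry, and the quality of the prediction inherits the
quality of those inputs.

## Numerical behaviour and problem sizes

A sweep is vectorised over the whole grid; at the default $N = 100$
(20 000 directions) a fit on a 20-atom system takes well under a second,
so grid refinement is cheap. The test suite exercises $N$ up to 200 and
checks that (i) the quadrature reproduces constant, $\cos\theta$ and
$\cos^2\theta$ fields to their analytic integrals within $10^{-3}$ at
$N = 100$, (ii) the map is antipodally symmetric to $10^{-9}$, (iii) a
joint rigid rotation of both endpoints moves the average only at the
grid-refinement-error scale, decaying with $N$ — the average is frame
invariant up to quadrature error, as it must be for a quantity averaged
over all directions. Routine unit tests run on $N$ between 5 and 50 and
molecules of 2–20 atoms; those sizes keep the whole suite in a few
seconds while leaving every property at asserting strength.

Worth knowing when interpreting fine grids: the integrand is continuous
but only piecewise smooth in $(\theta,\phi)$ — the hemisphere assignment
and the argmax in $R(\theta,\phi)$ both switch along curves on the
sphere — so quadrature convergence is fast but not the textbook
$O(N^{-2})$ of smooth midpoint rules, and refinement is not perfectly
monotone between neighbouring $N$.

## Limitations

* No shear or torsional forces, no time-dependent impact profile, no
  ball-curvature or ball-surface (catalytic) effects.
* The potential energy surface is assumed rigid (assumption 2): systems
  where force creates new intermediates or transition states are outside
  the model.
* Only the uniform force-weighting scheme is shipped.
* The straight-line displacement between endpoints stands in for the
  reaction path; no IRC following or path interpolation is performed.
* The baseline barrier, and any dielectric or curvature corrections, are
  external inputs; the package computes only the mechanical-work term,
  which is additive with such corrections because it depends only on the
  endpoint geometries.

## A complete example

```{r example}
ep <- make_contraction_pair(n_atoms = 12, factor = 0.9, seed = 1)
fit <- mill(ep$reactant, ep$transition, pressure = 1, grid_n = 50,
            ea = 20, label = "toy contraction")
summary(fit)
predict(fit, pressure = c(1, 2, 4))
```

```{r plot, fig.width = 6, fig.height = 3.2}
plot(fit)
```

Two pathways computed under the same configuration can be compared with
`compare_pathways()`, and `pressure_scan()` recomputes full maps over a
pressure series (sharing one alignment). The command-line interface in
`inst/cli/ballmill.R` exposes `run`, `compare`, `scan` and `fixtures`
subcommands over the same functions.
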