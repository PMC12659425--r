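---
title: "Methods: cavity construction, conductor screening, and outlying-charge correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cavity construction, conductor screening, and outlying-charge correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmosol)
```

This vignette records how the engine works, which numerical choices were
made where the method leaves them open, and what the built-in synthetic
solutes do and do not demonstrate about real calculations.

## The conductor model

COSMO replaces the dielectric solvent by a scaled perfect conductor. The
solute sits in a molecularly shaped cavity whose surface is discretized
into $m$ segments; segment $i$ carries a uniform charge density
$\sigma_i$, i.e. a point charge $q_i = s_i \sigma_i$ at its center. The
conductor boundary condition of vanishing total potential yields the
linear system

$$0 = \Phi + A q,$$

where $\Phi$ is the solute potential on the segment centers and $A$ the
symmetric segment–segment Coulomb matrix. Finite permittivities are
handled *a posteriori* by the scaling $q_\varepsilon = f_\varepsilon q$
with $f_\varepsilon = 1$ (ideal conductor),
$(\varepsilon-1)/(\varepsilon+0.5)$ (Klamt–Schüürmann) or
$(\varepsilon-1)/\varepsilon$ (Stefanovich–Truong).

All electrostatics is carried out in Hartree atomic units; geometry and
all file formats are in Ångström. The single conversion constant
(1 Bohr = 0.52917721092 Å) lives in one place, `cosmo_constants()`.

## Tessellation

Each sphere carries a pentakisdodecahedron mesh: the regular dodecahedron
with every pentagonal face apexed at its radially projected center. The
solid is generated as the dual of a regular icosahedron, which fixes the
connectivity (V = 32, E = 90, F = 60) without hard-coding coordinates;
the orientation of the mesh in space is implementation-defined, so no
consumer may rely on absolute tessera positions (tests compare
rotation-invariant summaries and exact translation equivariance instead).
Refinement is a midpoint 4-split with radial projection: 60, 240 and 960
faces for `coarse`, `fine` (the default) and `xfine`.

Tessera **centers** are radially projected planar centroids, and tessera
**areas** are exact spherical-triangle areas (l'Huilier's theorem) rather
than flat-triangle areas. This makes the partition identity
$\sum_i s_i = 4\pi R^2$ exact at every level, which in turn makes the
cavity volume of a lone sphere — from the divergence theorem
$V = \tfrac13 \sum_i s_i\, c_i\!\cdot\! n_i$ — exact as well.

## Cavity construction

**van der Waals cavities.** Every sphere is tessellated and tesserae
buried inside another sphere are removed (strict inequality: a center
exactly on a neighbouring surface is kept, which stabilizes tangent
spheres). Tesserae that straddle a sphere–sphere boundary are subdivided
once more, and exposed children are kept as independent segments. The
classical GEPOL step of regrouping children back into their 60 parents is
deliberately skipped: the finer boundary resolution benefits the
surface-charge solve.

**SES cavities.** The approximate solvent-excluding surface augments the
atomic spheres with auxiliary filler spheres wherever a probe of radius
`rsolv` (default 1.3 Å) cannot pass. A sphere pair is a candidate when
the probe is blocked ($d < R_A + R_B + 2 r_{solv}$), neither sphere
engulfs the other, and — for intersecting pairs — the overlap does not
exceed the `ofac` threshold ($d > R_A + R_B - 2\,\mathrm{ofac}\,
\min(R_A,R_B)$). The new sphere sits on the pair axis at the mid-gap
point, with radius fixed by tangency to the probe resting on both
spheres; candidates below `rmin` (0.5 Å), engulfed by an existing sphere,
or centered inside a third sphere (the gap is already filled) are
discarded, and the scan repeats over newly created spheres. `ofac = 0.8`
and `rmin = 0.5` Å are the conventional GEPOL values and remain
configurable. The probe determines accessibility only — it adds no
thickness to the surface.

On overlapping, alkane-like sphere chains the SES exposes less area than
the vdW surface of the same spheres, as expected. For two *separated*
spheres bridged by filler spheres the SES area can slightly exceed the
vdW area; the exact reentrant construction shows the same behaviour
there (the torus patch adds more area than the buried caps remove), so
this is a property of the geometry, not an artifact.

## Segment merging

Surface discretization can leave segment centers arbitrarily close along
sphere–sphere seams. In the point-charge (KS) matrix this produces
near-singular off-diagonals and, with them, abnormally large charge
densities. The engine therefore merges, during cavity construction, any
segments closer than

$$d_{\min} = \mathrm{mfactor} \times 0.5 \times \bar\ell(r_{solv},
\mathrm{ndiv}),$$

where $\bar\ell$ is the mean tessera edge (chord) length of a sphere of
radius `rsolv` at the chosen level. The formula is a design choice — the
method constrains only the dependencies (probe radius and tessellation
level) — and is linear in `mfactor` (default 1.0; 0 disables merging).

Merging is **greedy closest-pair**: while any two centers are closer than
$d_{\min}$, the closest pair is replaced by one segment at the
area-weighted centroid (areas summed, normals area-averaged and
renormalized), and distances are updated. A connected-component
(transitive-closure) merge was considered and rejected: seam segments
form long chains around sphere intersection circles, and collapsing a
connected ring places its centroid deep inside the cavity — on a
two-sphere test solute this produced a merged segment 0.45 Å from a
nucleus and energy artifacts of ~100 kcal/mol. Closest-pair merging keeps
merged centers near the surface, conserves total area exactly
(associativity of weighted centroids), and satisfies the post-condition
— no two output centers closer than $d_{\min}$ — by construction.
Merged centers lie slightly off the sphere surfaces, which is the price
of the centroid rule; the displacement is bounded by $d_{\min}$-scale
sagitta and is negligible at the default settings. A merged segment
inherits the parent sphere of its largest constituent.

## Coulomb matrices and the YK calibration

The KS matrix uses $A_{ij} = 1/r_{ij}$ off the diagonal and the
Klamt–Schüürmann self-interaction $A_{ii} = 1.07\sqrt{4\pi/s_i}$ (the
1.07 constant is exposed for sensitivity studies). The YK matrix smears
each segment into a spherical Gaussian with exponent $\zeta_i$:
$A_{ij} = \mathrm{erf}(\zeta_{ij} r_{ij})/r_{ij}$ with $\zeta_{ij} =
\zeta_i\zeta_j/\sqrt{\zeta_i^2+\zeta_j^2}$ and $A_{ii} =
\zeta_i\sqrt{2/\pi}$ — finite even for coincident centers, so merging is
unnecessary for YK.

The YK exponents follow the uniformity rule $\zeta_i = \bar\zeta /
\sqrt{s_i}$ (equal-area segments get equal exponents), and the per-level
scalar $\bar\zeta$ is calibrated by root-finding so the discretized
energy of a unit Born sphere equals the exact $-q^2/2R$. Because
$\zeta_i r_{ij}$ is invariant under uniform scaling of the sphere, one
calibration per tessellation level suffices for all radii; the calibrated
values (about 4.75/4.74/4.74 for coarse/fine/xfine) are cached per
session. The root is bracketed in $[0.5, 50]$ and solved to $10^{-13}$;
a bracketing failure is reported with the interval.

## Linear solvers

$A$ is symmetric positive definite for valid cavities. The dense path is
a Cholesky solve; the iterative path is conjugate gradients with Jacobi
preconditioning, relative tolerance $10^{-10}$ and at most $10m$
iterations (non-convergence reports the residual). The automatic choice
uses the dense solver up to $m = 7500$ segments and switches to the
iterative method above that. Nuclear and electronic potentials are solved
against the same factorization.

## Outlying-charge correction

Real solutes leak roughly 1% of their electron density outside any
reasonably sized cavity, so the charge rule $-Q_N = 1^T q_N$,
$-Q_e = 1^T q_e$ fails — partly from discretization, partly from genuinely
outlying charge. Two global corrections are provided.

**Scaling factors.** $f = -Q/(1^T q)$ per component, $q' = f q$. The sign
convention is deliberate: with the charge rule written $-Q = 1^T q$, the
factor that enforces it exactly and stays near $+1$ is $-Q/(1^T q)$ (a
convention written with the opposite sign is self-inconsistent with both
the rule and the near-unity expectation, and would flip every corrected
charge). The nuclear factor would be exactly 1 for perfect
discretization, since all nuclear charge is inside the cavity. Neutral
solutes are corrected the same way — outlying charge affects the
electronic component regardless of net charge.

**Lagrange multiplier.** $q'$ minimizes $\tfrac12 q^T A q + \Phi^T q$
subject to $1^T q = -Q_{tot}$, solved in closed form via
$q' = -A^{-1}(\Phi + \lambda 1)$,
$\lambda = (Q_{tot} - 1^T A^{-1}\Phi)/(1^T A^{-1} 1)$. The constraint is
applied once, to the total charge with the total potential: the method is
a single Gauss-law constraint, and splitting it per component would
over-determine the nuclear part, which carries no outlying charge. For
reporting, the correction is booked entirely against the electronic
split.

**Corrected potentials.** Either way, the potential used in energies is
rebuilt from the corrected charges, $\Phi' = -A q'$, restoring the
boundary condition for the charges actually used, and the electronic part
is $\Phi_e' = \Phi' - \Phi_N$ (the nuclear potential is unaffected by
outlying electrons). The dielectric energy is $E_{diel} = \tfrac12
\Phi'^T q'$. The legacy path (`potcorr`) keeps the corrected charges but
evaluates the energy with the uncorrected potential; it gates only the
energy expression, never the charges. On the 1%-outlying anion fixture
this inconsistency costs 0.58 kcal/mol.

**Ordering with dielectric scaling.** Scaling is applied after
correction, to the corrected charges; the potential in the energy
expression remains the conductor-consistent $\Phi' = -A q'$ of the
*unscaled* corrected charges, so $E_{diel}$ is linear in $f_\varepsilon$
(recomputing $\Phi'$ from scaled charges would square the factor, which
is not what the scaling approximation means). The distinction is moot in
the ideal-screening regime ($f_\varepsilon = 1$) where corrections are
usually compared; outside it, the ordering is a documented engine
convention.

## Synthetic solutes

Quantum-mechanical densities are replaced by classical models: point
nuclei plus spherical Gaussian electron clouds. Gaussians were chosen
over exponentials because every needed quantity — the potential
$n\,\mathrm{erf}(\sqrt\alpha r)/r$, its $r\to 0$ limit
$2n\sqrt{\alpha/\pi}$, and the enclosed-charge function — is closed-form,
so oracles are exact. The fixture catalogue fixes the study conditions:

* `born_ion` — +1 point charge centered in a 2 Å sphere; the analytic
  conductor oracle $-q^2/2R$, with zero outlying charge.
* `born_anion` — nucleus $Z=8$ plus a centered cloud of charge $-9$ whose
  exponent is solved (closed form, $10^{-12}$) so exactly 1% of the cloud
  charge lies outside the 2 Å cavity — the canonical ~1% outlying-charge
  regime, in the anion direction where defects are largest.
* `diatomic`, `water_like` — two- and three-center neutral models with
  per-atom neutralizing clouds, exercising sphere–sphere seams, merging,
  and the split nuclear/electronic solve at realistic geometry scales
  (bond lengths ~1–1.5 Å, radii from the scaled tabulated values).
* `chain9` — nine colinear overlapping 2 Å spheres at 1.5 Å spacing, an
  n-nonane-like shape for SES-versus-vdW area comparisons.

Fixtures are deterministic given the seed. What they do **not** emulate:
anisotropic (bonding) density features, charge transfer between centers,
density relaxation under the reaction field (no self-consistency loop —
the solute charge model is fixed), and heavy-element radii. Passing tests
therefore validate the *engine* — geometry, matrices, solvers,
corrections, bookkeeping — not the chemistry of any particular solute.
Note that a spherically symmetric anion makes both correction schemes
coincide by symmetry; the multi-center fixtures are what separates them,
and their agreement (well under 1 kcal/mol) mirrors the behaviour
expected of global corrections on solutes with ~1% outlying charge.

## Numerical choices and degenerate inputs

* Inside tests use strict inequality with a $10^{-12}$ Å² slack, so
  tangent spheres do not delete each other's surfaces.
* Coincident segment centers make the KS matrix singular; the builder
  detects them and directs the user to merging (`mfactor > 0`). The YK
  matrix is finite there by construction.
* Cholesky failure (non-SPD matrix) and CG non-convergence are hard
  errors with diagnostics, never silent fallbacks.
* The Monte-Carlo outside-charge estimator reports its sampling error;
  the closed form is used automatically for a centered cloud in a
  single-sphere cavity.
* Out-of-range σ values clamp into the end histogram bins with a warning
  so the σ-profile always conserves total area.
* Empty sphere lists, nonpositive radii/exponents/bin widths, unknown
  elements and malformed files raise named errors at the stage that saw
  them.
* The COSMO file writes corrected potentials in the segment block (the
  consistent choice given that corrected charges are written); the
  settings block records `f_N`/`f_e` whenever the scaling correction ran.

## Problem sizes

The test-suite and the acceptance script run entirely at desk scale:
single spheres at 60–960 segments, multi-sphere fixtures at a few hundred
post-merge segments (the nine-sphere chain peaks near a thousand), dense
solves throughout, $2\times10^5$ Monte-Carlo samples per cloud for
outside-charge estimates and $10^6$ for the volume oracle. These sizes
were chosen so every oracle comparison resolves well below its assertion
tolerance.

## Known limitations

* The SES is the GEPOL *approximate* molecular surface: filler spheres,
  not exact reentrant tori; no partially-clipped-tessera integration
  beyond one secondary subdivision; no adaptive tessellation.
* Corrections are global (one factor per component, one multiplier);
  like all such schemes they can redistribute charge with little regard
  to where the outlying density actually sits, and they perturb surface
  multipoles.
* No analytic gradients, no coupling to an electronic-structure loop,
  and no double-cavity scheme.
* The dense solver is the only exhaustively exercised path at the sizes
  used here; the CG path is validated against it on random SPD systems.
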