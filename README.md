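# cosmosol

A standalone R engine for the **conductor-like screening model (COSMO)** of
continuum solvation, with GEPOL93 cavity construction, segment merging,
outlying-charge correction with consistently corrected potentials,
Turbomole-style COSMO files and σ-profiles.

It is aimed at people who work *on* continuum-solvation machinery rather
than merely through it: developers of COSMO-RS/COSMO-SAC tooling who need
a transparent, fully testable reference for cavity discretization and
surface-charge solvers, and students of apparent-surface-charge methods.
Solutes are classical charge models (point nuclei plus spherical Gaussian
electron clouds), so every stage of the pipeline runs and is verifiable at
desk scale with no quantum-chemistry backend.

## The model

The solvent is approximated by a scaled perfect conductor. The cavity
surface is discretized into *m* segments, each carrying a uniform charge
density σᵢ and so a point charge qᵢ = sᵢσᵢ at its center. With **Φ** the
solute electrostatic potential on the segments and **A** the symmetric
segment–segment Coulomb matrix (with a self-interaction diagonal), the
vanishing-total-potential condition in a conductor gives

```
0 = Φ + A q
```

Finite dielectrics are recovered by scaling, **q**(ε) = f(ε) **q**, with
f = 1 (`screen ideal`, ε = ∞), f = (ε−1)/(ε+0.5) (`screen ks`) or
f = (ε−1)/ε (`screen st`). Two matrix variants are provided: the
Klamt–Schüürmann point-charge form (**KS**, diagonal 1.07·√(4π/sᵢ)) and
the York–Karplus smeared-Gaussian form (**YK**), whose exponents are
calibrated so the discretized Born-ion energy is exact and which is free
of the Coulomb near-singularities the KS form can suffer.

Cavities are built from scaled van der Waals spheres tessellated by a
pentakisdodecahedron mesh (60/240/960 triangles per sphere for
`coarse`/`fine`/`xfine`); the approximate solvent-excluding surface (SES)
adds GEPOL auxiliary spheres where a probe of radius `rsolv` cannot pass.
Segments closer than d_min (scaled by `mfactor`) are merged during
construction so the KS matrix stays well-conditioned.

Because part of a real solute's electron density always lies outside the
cavity, the screening charges violate Gauss's law (−Q = 1ᵀq). The engine
corrects this by per-component **scaling factors**
(f = −Q/(1ᵀq), applied separately to nuclear and electronic parts) or by a
**Lagrange multiplier** that enforces 1ᵀq = −Q while minimizing the energy
functional ½qᵀAq + Φᵀq — and, crucially, it then rebuilds the potential
from the corrected charges, Φ′ = −Aq′, so the dielectric energy

```
E_diel = ½ Φ′ᵀ q′
```

uses a mutually consistent pair. The legacy behaviour (corrected charges,
uncorrected potential) is available via `potcorr`.

## Worked example

A Born ion — a +1 point charge centered in a 2 Å sphere — has the exact
conductor solvation energy −q²/2R = −0.13229430 Hartree:

```r
library(cosmosol)
res <- run_cosmo(cosmo_config(fixture = "born_ion"))
print(res)
#> <cosmo_result> 240 segments, defect 0.00e+00 -> 0.00e+00 e
#> E_diel = -0.13229430 Hartree (-83.016 kcal/mol), correction = lagrangian, corrected potential
```

The default YK matrix reproduces the analytic value to machine precision
because its exponents are calibrated against exactly this oracle. The
`born_anion` fixture adds a Gaussian electron cloud tuned so 1% of its
charge (−0.09 e) lies outside the cavity — the outlying-charge situation
the correction schemes exist for:

```r
res <- run_cosmo(cosmo_config(fixture = "born_anion", method = "ks",
                              charge_correction = "scale"))
print(res)
#> <cosmo_result> 240 segments, defect -7.02e-03 -> -1.22e-15 e
#> E_diel = -0.13232208 Hartree (-83.033 kcal/mol), correction = scale, corrected potential
res$log$f_N; res$log$f_e
#> [1] 1.00021
#> [1] 1.000967
```

The uncorrected charges miss Gauss's law by −7×10⁻³ e; scaling restores
it to numerical precision with factors near unity. With the legacy
`potcorr = TRUE` path the same run yields −82.451 kcal/mol — a 0.58
kcal/mol error from using an inconsistent potential. File-based runs work
the same way (`xyz` + radii table, optional serialized solute model), and
`write_cosmo_file()` / `sigma_profile()` produce the COSMO file and
σ-profile consumed by COSMO-SAC-style workflows. A thin CLI wraps all of
this:

```sh
Rscript exec/cosmo --fixture born_anion --method ks \
    --charge-correction scale --cosmo-file anion.cosmo
```

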