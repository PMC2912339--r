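# trajscope

Trajectory analysis and end-state binding thermodynamics for molecular
dynamics of protein–nucleic acid assemblies — the motivating system is
the Argonaute (Ago) endonuclease bound to a guide miRNA and its target
mRNA, where collective motions of the PAZ/Mid/PIWI domains and the
energetics of the RNA-binding channel decide recognition and cleavage.
The package is for computational structural biologists who have
trajectories (multi-model PDB or a plain-text frame dump) and want the
standard post-processing battery as tested, scriptable R functions.

## What it computes

* **Superposition & fluctuations** — weighted Kabsch fits, RMSD series
  against a reference frame, RMSF with B-factors
  `B = (8π²/3)·RMSF²` and z-score–normalized B profiles
  (`kabsch()`, `rmsd_series()`, `rmsf()`).
* **Essential dynamics** — the 3N×3N positional covariance
  `C = ⟨(r−⟨r⟩)(r−⟨r⟩)ᵀ⟩` over the equilibrated frames (superposed to
  the iterated mean), its eigen-spectrum and variance fractions,
  projections `p_k(t) = V_k·(r(t)−⟨r⟩)`, and extreme conformers with
  eigenvector interpolation (`build_covariance()`, `project()`,
  `extreme_conformers()`).
* **Domain motions** — per-residue rotation-vector fields between two
  conformers, clustering into quasi-rigid domains, and screw (hinge)
  parameters: effective rotation angle, translation along the axis,
  and % closure `100·(n̂·ĉ)²` against the closure axis
  (`local_rotation_field()`, `partition_domains()`,
  `hinge_parameters()`).
* **Contacts** — hydrogen-bond occupancy series (heavy-atom 3.5 Å
  default, 3.0 Å preset, optional D–H–A angle mode), signed base-pair
  dihedrals, hydration sites with molecule-resolved residence episodes,
  ion coordination geometry (mean ± sd distances, angle sums,
  out-of-plane), channel centroid distance and projected entrance area.
* **Energetics** — single-trajectory MM-GBSA ledger
  `ΔG_bind = ΔH − TΔS`, `ΔH = ΔE_ele + ΔE_vdw + ΔG_np + ΔG_polar`, with
  interface Coulomb (k = 332.0636, no cutoff), Lennard-Jones,
  `ΔG_np = γ·SASA + β` (γ = 0.00542 kcal/Å²·mol, β = 0.92 kcal/mol,
  1.4 Å probe, deterministic Shrake–Rupley lattice), generalized-Born
  polar term (HCT pairwise descreening, Born-ion exact limit),
  quasiharmonic/normal-mode entropy, per-residue decomposition with
  fractional-threshold flags, and `RT·ln(Kd)`
  (`mmgbsa_binding()`, `decompose_per_residue()`, `experimental_dg()`).
* **Synthetic fixtures** — seeded generators planting hinge motions,
  H-bond/hydration schedules and charged complexes with manifest ground
  truth (`hinge_spec()`, `make_hinge_trajectory()`, ...), used by the
  test suite for parameter-recovery checks.
* **Pipeline** — a YAML-configured runner wiring superpose → PCA →
  extremes → domains plus the contact/energy stages, with deterministic,
  byte-reproducible tables (`validate_config()`, `run_pipeline()`), and
  a thin CLI wrapper in `inst/cli/trajscope.R`.

## Worked example

Plant a 25° hinge between two 100/80-residue lobes with 0.2 Å thermal
jitter, then recover it end to end:

```r
library(trajscope)

spec  <- hinge_spec(amplitude = 25, noise_sigma = 0.2,
                    n_frames = 200, seed = 7)
chain <- make_two_domain_chain(spec)
traj  <- make_hinge_trajectory(chain, spec)

model <- build_covariance(traj, equilibration_drop = 0)
model
#> covariance model: 180 atoms (3N = 540), 200 frames
#> top eigenvalues (A^2): 130.8, 0.3541, 0.2695, 0.2658, 0.2585
#> variance captured by 2 modes: 86.1%

ser  <- project(traj, model, 1:2)
ext  <- extreme_conformers(ser, traj, model, 1, average = 10)
field <- local_rotation_field(ext$min_structure, ext$max_structure)
part  <- partition_domains(field, cluster_radius = 8)
part
#> domain partition: fixed 97 residues; 1 moving domain(s)
#>   moving 1: 79 residues, hinge at [98-101]
hinge_parameters(ext$min_structure, ext$max_structure, part, 1)
#> hinge: rotation 24.92 deg, translation 0.02 A, closure 99.6%
```

The dominant eigenvalue (130.8 Å² against a ~0.3 Å² jitter floor) is
the planted hinge mode; the partition recovers the two lobes with the
hinge at residues 98–101 (planted pivot: residue 100); the screw fit
returns the planted 25° rotation within a tenth of a degree, and a
closure near 100% because the planted axis is perpendicular to the
interdomain direction.

The same fixtures exercise the energy ledger:

```r
cx  <- make_charged_complex(10, 5, seed = 1)
tr2 <- trajectory(cx$top, rbind(as.numeric(t(cx$coords)),
                                as.numeric(t(cx$coords + 0.02))),
                  times = c(0, 2))
mmgbsa_binding(tr2, cx$receptor, cx$ligand)
#> binding free energy report (2 snapshots, T = 300 K)
#>        component       mean       sd
#>           dE_ele     -64.97     0.00
#>           dE_vdw      -0.08     0.00
#>            dG_np      -1.01     0.00
#>         dG_polar      65.04     0.00
#>  dE_ele+dG_polar       0.06         
#>               dH      -1.03         
#>              TdS     -17.63         
#>          dG_bind      16.60
```

The rows satisfy the ledger identities exactly
(`dH = ele + vdw + np + polar`, `dG_bind = dH − TdS`); the large
opposing electrostatic and polar-solvation terms nearly cancelling is
the usual signature of charged-interface binding.

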