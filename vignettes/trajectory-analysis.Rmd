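---
title: "Essential dynamics, hinge motions and MM-GBSA thermodynamics with trajscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essential dynamics, hinge motions and MM-GBSA thermodynamics with trajscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscope)
```

trajscope analyzes molecular-dynamics trajectories of protein-nucleic
acid assemblies -- the motivating system is the Argonaute (Ago)
endonuclease bound to a guide miRNA and a target mRNA -- through the
standard post-processing pipeline of structural molecular modelling:
superposition and fluctuation statistics, essential-dynamics principal
component analysis (PCA), quasi-rigid domain decomposition, geometric
interaction analyses, and single-trajectory end-state (MM-GBSA) binding
thermodynamics. This vignette explains the models behind each stage,
the tunable parameters, the design choices made where conventions in the
field genuinely vary, and what the synthetic validation fixtures do and
do not demonstrate.

Units are fixed globally: Angstrom, picoseconds, kcal/mol, degrees,
kelvin. Residue numbering is 1-based PDB numbering in every user-facing
report.

## Superposition and fluctuation statistics

All comparative statistics rest on weighted least-squares rigid
superposition (`kabsch()`), computed by SVD of the weighted
cross-covariance with the determinant correction that rejects
reflections. `rmsd_series()` superposes every frame onto a reference
frame on the analyzed selection before measuring RMSD, so rigid-body
drift never contributes.

`rmsf()` measures per-atom root-mean-square fluctuations about the
*iterated mean structure*: frames are fit to a running mean until the
mean moves less than 1e-9 A between rounds (bounded at 200 rounds;
fixtures converge in a handful). The B-factor is the isotropic
conversion B = (8 pi^2 / 3) RMSF^2, and the "normalized B" is the
z-score (B - mean(B)) / sd(B) over the reported selection. Z-scoring is
one of several published normalizations; it is chosen here because it
places profiles of different systems (free enzyme, binary and ternary
complexes, crystallographic B) on one dimensionless axis, which is how
such profiles are overlaid in practice. The equilibration drop defaults
to the first 25% of frames wherever a "stable portion" is required and
is configurable everywhere.

## Essential dynamics

`build_covariance()` forms the 3N x 3N positional covariance
C = <(r - <r>)(r - <r>)^T> of the selected atoms (C-alpha by convention
for proteins) over the retained frames, after superposing them onto the
iterated mean -- fitting to the mean rather than to frame 1 keeps
rigid-body motion from leaking into the low modes. The sample
(denominator M-1) convention is used so that the variance of a
projection series equals its eigenvalue exactly. Eigenvalues are sorted
descending; round-off negatives above -1e-8 A^2 are clipped to zero;
each eigenvector's largest-magnitude component is made positive, a sign
convention that makes projections reproducible across platforms and
runs, which in turn makes whole-pipeline reruns byte-identical.

`project()` gives p_k(t) = V_k . (r(t) - <r>); `variance_captured()`
the cumulative spectrum fraction; `extreme_conformers()` the frames at
the projection extremes together with structures interpolated along the
eigenvector. The `average` option replaces each extreme frame by the
mean of the k most extreme-projection frames (superposed to the model
mean). Averaging suppresses uncorrelated thermal jitter roughly as
1/sqrt(k) at the cost of shrinking the extreme amplitude slightly
(for a sinusoidal schedule of 200 frames, k = 10 biases a planted
amplitude by about 1-2%); it is off (k = 1) by default and switched on
when a downstream consumer needs denoised conformers -- notably domain
decomposition of noisy trajectories.

## Domain decomposition and hinge parameters

Given two conformers (in the pipeline: the PC-extreme structures),
`local_rotation_field()` fits a rigid transform over a sliding window of
residues (odd length, default 5) and records each residue's rotation
vector (unit axis times angle in degrees). `partition_domains()`
clusters those vectors hierarchically with a merge radius in
rotation-vector space (default 5 degrees) and keeps clusters of at
least `min_domain` residues (default 20) as quasi-rigid domains, the
largest being the fixed domain. Complete linkage is the default
deliberately: the hinge residues themselves produce a bridge of
intermediate rotation vectors (their windows straddle the pivot) spaced
roughly amplitude/(window-1) apart, and single linkage chains the two
genuine domains together through that bridge whenever the amplitude is
within a few window-lengths of the radius -- which is exactly the
regime of 5-12 degree hinges. Single linkage remains available via
`linkage = "single"`. Residues stranded between two domain runs along
the chain are reported as hinge residues; their median localizes the
pivot to within about +/-2 residues on planted fixtures.

`hinge_parameters()` expresses the moving domain's transform in the
fixed domain's frame (by first superposing the two conformers on the
fixed domain) and decomposes it into a screw: effective rotation angle
(0-180 degrees), signed translation along the right-hand-oriented axis,
and a percent closure. Closure is defined here, concretely and
unit-tested, as 100 (n . c)^2 with n the unit rotation axis and c the
closure axis -- the unit vector (g - p) x d, where g is the moving
centroid, p its projection point on the screw axis and d the unit
interdomain centroid direction. This is the axis direction that
maximally changes the interdomain separation under an infinitesimal
rotation, so a pure closure motion scores 100, a pure twist about the
centroid line scores 0, and the two sum to ~100 for a shared geometry.
When the lever arm (g - p) is parallel to d the construction
degenerates and the fallback 100 (1 - (n . d)^2) is used. Rotations
below 0.1 degree report closure as missing. The whole decomposition is
invariant under a global rigid transform of both conformers, which the
suite checks with random transforms.

## Geometric interaction analyses

* `hbond_scan()` defaults to the distance-only heavy-atom criterion at
  3.5 A -- stricter 3.0 A (the seed base-pair convention) is one
  argument away -- because published base-pair distance series reason in
  heavy-atom distances; the optional `distance+angle` mode adds a
  donor-H-acceptor angle cutoff (default 120 degrees) with hydrogens
  located by proximity in the first frame.
* `pair_dihedral()` is the standard signed torsion in (-180, 180],
  verified against an independent implementation; frames with a
  collinear central bond report NA.
* `hydration_sites()` histograms water-oxygen positions on a cubic grid
  (default 1.0 A) inside a spherical region, keeps voxels whose
  occupancy exceeds 0.40 (chosen so that ~50%-occupied sites, the
  weakest sites typically reported, are retained), merges maxima within
  1.5 A, and re-measures site occupancy as the fraction of frames with
  any water oxygen within the merge radius of the centroid. Residence
  episodes are tracked per water molecule, so two waters exchanging in
  a continuously occupied site yield occupancy 1.0 but two
  molecule-resolved episodes; gaps up to `gap_tolerance` frames
  (default 2) are bridged, since the gap rule behind published
  residence times is rarely stated.
* `coordination_geometry()` reports mean +/- sd center-partner
  distances, consecutive partner-center-partner angles (ordered by
  azimuth in the partners' best-fit plane, so a planar N-coordination
  sums to ~360 degrees) and the center's distance from that plane --
  the planarity diagnostic used for catalytic-triad/metal geometry.
* `channel_metrics()` returns the centroid separation of two residue
  sets and the entrance area as the convex hull of the entrance atoms
  projected perpendicular to the channel axis. A projected convex hull
  (rather than an alpha-shape or solvent-excluded section) is chosen
  because it is deterministic, parameter-free and exactly testable
  against projection geometry; it is an upper bound on tighter area
  definitions.

## End-state binding thermodynamics

The single-trajectory ledger is assembled by `mmgbsa_binding()` per
snapshot as dG_bind = dH - TdS with
dH = dE_ele + dE_vdw + dG_np + dG_polar:

* dE_ele: interface Coulomb sum k q_i q_j / (eps r), k = 332.0636
  kcal A/(mol e^2), no cutoff, interior dielectric 1;
* dE_vdw: 12-6 Lennard-Jones with Lorentz-Berthelot combining, no
  cutoff;
* dG_np = gamma SASA + beta with gamma = 0.00542 kcal/(A^2 mol),
  beta = 0.92 kcal/mol and a 1.4 A probe; in the complex - receptor -
  ligand difference beta cancels exactly once. SASA is Shrake-Rupley
  with a deterministic Fibonacci sphere lattice (no RNG; 960 points
  converge an isolated sphere to well under 2%, and doubling the
  lattice moves a 20-atom cluster total by < 1%);
* dG_polar: generalized Born with Still's interpolation
  f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / 4 R_i R_j)) and effective radii
  from Hawkins-Cramer-Truhlar pairwise descreening with a fixed
  per-element scaling table (H/O 0.85, C 0.72, N 0.79, S 0.96, P 0.86,
  else 0.80). The descreening integral is validated against numeric
  quadrature, and an isolated ion reduces exactly to the Born closed
  form -(k/2)(1/eps_in - 1/eps_out) q^2 / R with eps_in = 1 and
  eps_out = 80. A GB polar term is used rather than a finite-difference
  Poisson-Boltzmann solve: it is self-contained, differentiable,
  anchored by the Born limit, and it is the model conventionally used
  for per-residue decomposition; absolute polar energies will differ
  from PB values, which is why the shipped reference ledger is checked
  through its internal arithmetic rather than re-derived.

Entropy (`entropy_estimate()`, reported as T*S) splits into the
ideal-gas translational term (Sackur-Tetrode at 1 M standard state --
the conventional standard concentration), the classical rigid-rotor
term from the principal moments of inertia, and a harmonic-oscillator
vibrational sum. Quasiharmonic frequencies omega_k = sqrt(kB T /
lambda_k) come from the mass-weighted covariance of superposed
snapshots (rigid-body modes have lambda ~ 0 and drop out); the
normal-mode alternative truncates the system to residues within 9 A of
the ligand's mass center, minimizes a Coulomb(eps = 4r) + Lennard-Jones
energy to gradient RMS < 5e-5 kcal/mol/A, mass-weights the numeric
Hessian and discards the near-zero rigid modes by eigenvalue threshold
(so linear molecules shed five, not six). Normal mode is restricted to
<= 500 atoms; quasiharmonic is the default for ensemble use. Snapshot
conventions default to the usual protocol: every energy snapshot, every
5th snapshot for entropy, T = 300 K.

`decompose_per_residue()` attributes the snapshot-averaged *interface*
energy (Coulomb + Lennard-Jones + GB cross terms evaluated with the
complex's effective radii; entropy omitted for its small and noisy
per-residue share) to residues on one side. Contributions sum exactly
to the decomposed total, and residues whose |fraction| exceeds a
threshold (1.4% by default, 1.5% being the ternary-complex convention)
are flagged -- the rule that surfaces the arginine-rich binding channel
in Ago-type systems. `experimental_dg()` converts a dissociation
constant via RT ln(Kd) with R = 1.9872e-3 kcal/(mol K).

## Synthetic fixtures: what they do and do not show

The generators in `synthetic_data` are kinematic, not physical: a
two-lobe C-alpha chain (uniform-ball lobes, centroids three lobe radii
apart) hinging about a planted axis with Gaussian jitter; an atom pair
switching between 2.8 A and 6.0 A on a Bernoulli or explicit schedule
with a water parked in or out of a site; and randomly packed charged
complexes whose manifest carries independently computed double-loop
reference energies. Every generator is a pure function of its spec and
seed (the global RNG stream is saved and restored), and every planted
parameter is recoverable from the manifest, so the suites test
parameter *recovery*, not merely self-consistency.

Fixture scales are chosen to keep the full suite fast while leaving no
statistical ambiguity: 180-residue chains, 200-frame trajectories for
hinge recovery, 2000 frames for occupancy and jitter calibration
(3-sigma binomial bands), 50-frame/6-atom fixtures for eigen-oracles.
What passing these suites shows: the estimators are correct on inputs
whose ground truth is known exactly, at noise amplitudes (sigma = 0.3 A)
typical of thermal fluctuation. What they do not show: force-field
realism, water physics, sequence effects, or the absolute values of
trajectory-dependent published quantities (RMSD bands, variance
percentages, hinge tables, absolute energy components), which require
the original trajectories. The one published quantity that *is*
reproducible at desk scale -- the internal arithmetic of the binding
ledger (enthalpy sum, electrostatic balance, dG = dH - TdS, and
RT ln(Kd)) -- is checked from the shipped component table; printed
inputs rounded to 0.01 kcal/mol propagate up to k x 0.005 drift into a
k-term sum, which is the tolerance the checks use.

## Numerical choices and degenerate inputs

Collinear point sets make the Kabsch rotation undefined and are
rejected; near-180-degree rotations take the axis from the symmetric
part of the rotation matrix. The screw-axis point is solved in the
plane perpendicular to the axis (the axis-parallel null space is pinned
by an outer-product augmentation). Torsions with a collinear central
bond are NA per frame. Coulomb/LJ refuse atom pairs closer than 1e-3 A
(overlap), GB refuses nonpositive intrinsic radii, SASA requires at
least 60 lattice points. Hierarchical clustering, eigen-decomposition,
the sphere lattice and the grid histogram are all deterministic, so the
pipeline's tables are byte-identical across reruns; the only RNG in the
package lives in the seeded generators.

## Known limitations

Trajectory formats are multi-model PDB and a plain-text frame dump
(binary formats are out of scope); topology is label-based with no bond
perception; the GB flavor is a single fixed descreening scheme; PB salt
effects, anisotropic B tensors, nonlinear dimensionality reduction and
alpha-shape areas are not implemented; normal-mode entropy is
intentionally limited to small truncated systems because the Hessian is
assembled by finite differences of the analytic gradient.
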