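---
title: "Methods: conformational trajectory analysis and MM/GBSA in trajlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational trajectory analysis and MM/GBSA in trajlens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajlens)
```

`trajlens` implements the standard analysis chain for comparative MD studies
of proteins — superposition-based RMSD/RMSF, functional mode analysis,
RMSD-based hierarchical clustering with quantitative cluster-count
selection, and single-trajectory MM/GBSA binding energetics — together with
synthetic-data generators that plant exactly known answers. This vignette is
the package's account of the underlying models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic tests do and
do not demonstrate about real simulation data.

Units throughout: Angstrom for coordinates and fluctuations, ns for frame
times, amu for masses, elementary charges, and kcal/mol for energies. Atom
indices are 1-based (R convention); residue ids are taken verbatim from the
input file, so reports can be read against the source numbering.

## Superposition, RMSD and RMSF

`superpose()` solves the weighted orthogonal Procrustes problem (Kabsch,
via SVD of the weighted cross-covariance, with the determinant corrected so
only proper rotations are returned). Weights default to atomic masses
everywhere, matching common practice in MD post-processing; every function
takes `massWeighted = FALSE` to disable this. The reported RMSD is computed
from the actual rotated residuals rather than the trace identity — the
closed-form expression loses half the available precision to cancellation
when the motion is nearly exactly rigid, and the residual form keeps the
rigid-motion invariance checks meaningful at the 1e-9 A level. Inputs with
fewer than three atoms or (near-)collinear point sets are rejected as
ill-conditioned rather than silently returning an arbitrary rotation about
the degenerate axis.

`rmsdSeries()` fits one selection and reports over another (fit on the
backbone, report on a loop, say), because the fit selection defines the
frame of reference while the report selection defines the question.
`rmsfPerResidue()` aligns all frames, by default to the post-alignment
time-mean structure: frames are first aligned to frame 1, averaged, and
realigned once to that mean. Fluctuations about the time mean are the
standard definition and are what the isotropic-noise closed form
(RMSF = sqrt(3)*sigma per coordinate sd sigma) tests against; `alignTo =
"first-frame"` is available for comparison with tools that report
deviations from the starting structure. Per-residue values are the
mass-weighted mean of the residue's per-atom RMSF.

A practical caveat the tests quantify: superposition removes six rigid-body
degrees of freedom, so even for perfectly isotropic noise the measured RMSF
sits slightly below sqrt(3)*sigma — about 1% for a compact 100-atom system,
within the 2% band the test suite asserts. Smaller systems show a larger
deficit; this is a property of the estimator, not an implementation error.

`detectEquilibration()` formalises the usual by-eye plateau call: it slides
a window (default 5% of the trajectory, at least 2 frames) and returns the
first frame from which every window mean stays within `tolerance` (default
0.3 A) of the final-window mean. The defaults are package choices —
plateau-calling conventions vary — and both knobs are exposed. If no
earlier window qualifies, the start of the final window is returned with a
warning, so a never-plateauing trajectory is flagged rather than silently
accepted.

## PCA and functional mode analysis

`fitPCA()` diagonalises the covariance of mass-weight-scaled displacement
vectors (coordinates flattened atom-major) after aligning frames to their
time-mean structure. Eigenvalues are clamped at zero and sorted descending;
at most `min(3n, F - 1)` are non-zero. Because alignment is a Kabsch fit,
each aligned displacement is exactly orthogonal to the rigid-body
generators at the mean — which is what makes mode filtering and re-fitting
exactly rank-one (see below).

Functional mode analysis regresses a scalar functional quantity `f` (for a
binding-loop study, the loop RMSD after a global fit, via
`functionalRmsd()`) on the projections of the leading modes. For a linear
model, maximising the Pearson correlation and ordinary least squares
coincide, so `fitFMA()` uses `lm.fit` with an intercept. Two collective
vectors are reported: `MCM ∝ Σ βᵢeᵢ`, the coefficient-weighted direction,
and `ewMCM ∝ Σ βᵢλᵢeᵢ`, which weights each mode by its ensemble variance.
The distinction matters: for a planted signal `f = a_t` carried by one
direction of the ensemble, the OLS coefficients on *all* modes scale as
`cov(f, p_k)/λ_k`, so the unweighted MCM amplifies low-variance noise modes
while the eigenvalue weighting restores exactly the planted direction —
`ewMCM` is therefore the vector the recovery tests compare against.

Open choices were resolved as follows and are all overridable:

* **Cross-validation split** — first half train, second half validate
  (`splitFraction = 0.5`). Consecutive-block splitting respects the serial
  correlation of MD frames better than random interleaving, which would
  leak information between splits.
* **Retained modes** — the smallest count explaining 90% of total variance.
  A fixed fraction is auditable and scales with the system; the exact value
  is a convention, exposed as `nComponents`.
* **Mode filtering** — `filterOnMode()` reconstructs each frame as
  `mean + (projection)·mode`, removing all orthogonal variance. Re-fitting
  PCA on a filtered trajectory yields exactly one non-zero eigenvalue
  (relative 1e-8 in the tests) because the filtered displacements are
  orthogonal to the rigid-body generators, so the realignment inside
  `fitPCA()` is the identity up to numerical noise.
* `modeRmsf()` of the ewMCM-filtered trajectory is the per-residue map of
  participation in the functional motion — the device used to read off
  which regions move together with a region of interest.

## RMSD clustering and cluster-count selection

`rmsdMatrix()` computes all pairwise superposition-minimised mass-weighted
RMSDs (each pair fitted independently, so the triangle inequality is not
assumed anywhere downstream); the condensed matrix feeds
`hierarchicalCluster()`, which delegates the agglomerative merging to
`stats::hclust` — average linkage by default, complete and centroid
provided (centroid via the Lance-Williams update on squared
dissimilarities). Merging order for tied dissimilarities follows hclust's
deterministic convention, so clustering is reproducible run to run.

The quality metrics need care: an ANOVA-style decomposition
(SSR + SSE = SST) is exact only in a single fixed coordinate frame, while
the merge tree lives in pairwise-RMSD space. `clusterMetrics()` therefore
superposes all frames once to a common mean structure and computes SST,
SSE, SSR, SSR/SST and the pseudo-F statistic
`(SSR/(K−1))/(SSE/(F′−K))` in that fixed mass-weighted space; the
Davies-Bouldin index uses the mean member distance to the cluster mean
(S_i) and distances between cluster means (M_ij) on the same RMSD-like
scale. Medoid centroids (`extractCentroids()`) remain genuinely
pairwise-RMSD objects: the member with the smallest summed RMSD to the rest
of its cluster. An exact brute-force reimplementation of all three metrics
(aligned through an independent quaternion superposition) pins the
arithmetic on instances up to 12 frames.

`selectClusterCount()` encodes the usual visual rule: the chosen K is a
local DBI minimum whose relative SSR/SST gain to K+1 falls below
`plateauTol` (default 0.05 — the plateau criterion is stated qualitatively
in the literature, so the threshold is a package choice); among candidates
the largest pseudo-F wins, and if nothing qualifies (e.g. a single-basin
ensemble) the global DBI argmin is returned with a warning. The default
stride targets roughly 1200 retained frames, a typical frame count for
clustering an equilibrated window.

On the generator's four-state ensembles (occupancies 0.55/0.36/0.06/0.03,
1200 frames, state separation about 27 times the within-state noise) the
rule recovers K = 4 in at least 95% of seeds — the acceptance suite runs
20. The 3%-occupancy state contributes only ~36 frames, so occasional
misses at K = 3 are expected behaviour of the rule, not a defect.

## Single-trajectory MM/GBSA

Binding energies follow the thermodynamic cycle
`ΔΔG = G(complex) − G(receptor) − G(ligand)` evaluated per frame with all
three species' coordinates extracted from the same complex frame. Two
structural consequences are asserted rather than computed: internal
(bond/angle/dihedral) terms cancel identically, so `e_internal` is exactly
zero; and the elec/vdW differences reduce to receptor-ligand cross
interactions, which is how they are evaluated. Conformational entropy is
treated as constant (the usual assumption when ranking rather than
predicting absolute affinities) and no entropy field exists in any result.

Term by term:

* **Electrostatics** — Coulomb sum with `k = 332.0636 kcal·A/(mol·e²)` and
  interior dielectric `ε_in = 1`.
* **van der Waals** — 12-6 Lennard-Jones in rmin/epsilon form with
  Lorentz-Berthelot combination.
* **Polar solvation** — generalized Born in the Hawkins-Cramer-Truhlar
  pairwise-descreening variant: effective radii from the analytic
  Coulomb-field integral over scaled neighbour spheres (an isolated atom's
  effective radius equals its intrinsic radius exactly; the inverse radius
  is clamped away from zero for deeply buried atoms), combined through
  Still's `f_GB = sqrt(r² + αᵢαⱼ·exp(−r²/4αᵢαⱼ))` with self terms included,
  `ε_solv = 78.5`, no salt screening. HCT is the canonical pairwise GB and
  78.5 the usual aqueous dielectric near physiological temperature; both
  dielectrics are arguments. A quadrature oracle integrates the descreening
  integrand numerically and agrees with the analytic form to 1e-6.
* **Nonpolar solvation** — `γ·SASA + β` with γ = 0.005 kcal/mol/A²,
  β = 0, probe 1.4 A, 960 Shrake-Rupley points (all standard defaults, all
  exposed). SASA uses a deterministic spiral point set evaluated in a
  canonical molecule-fixed frame — centroid plus two landmark atoms
  (farthest from the centroid, then farthest from that axis) — chosen over
  principal axes because landmarks stay exactly rotation-equivariant even
  when the inertia tensor is degenerate (helical or linear molecules).
  Inside the binding-energy engine the receptor and ligand areas are
  computed in the *complex's* canonical frame, so at large separation the
  species areas cancel the complex areas point for point and the SASA term
  vanishes exactly.
* **Per-residue decomposition** — each cross pair term is split half/half
  between the partner atoms' residues; GB self and pair terms and per-atom
  SASA differences are attributed to the owning atom's residue. The
  decomposition is conservative by construction (sums to the total within
  1e-6 kcal/mol per frame, asserted per frame in the tests). The reporting
  filter keeps residues with |mean| above 1 kcal/mol by default, the
  conventional cutoff for decomposition plots.
* **Averaging** — mean and *population* standard deviation over the scored
  (equilibrated, strided) frames; the SD describes frame-to-frame spread,
  not a standard error.

One separability subtlety: for net-charged species the screened monopole
interaction `k·q₁q₂/(ε_solv·r)` still amounts to ~1e-2 kcal/mol at 500 A,
so "all terms vanish at large separation" is only meaningful below
1e-6 kcal/mol for net-neutral partners. The separability check therefore
uses the helix-pair toy complex, whose chains are alternating-charge and
individually neutral; the two-ion complex is kept for the closed-form
assembly oracle where every term is evaluated by hand.

No cutoffs are applied anywhere (all-pairs sums): the package targets
desk-scale systems where exactness is affordable and testable.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, seed-deterministic package code:

* `generatePlantedModeTrajectory()` — Gaussian amplitudes along one
  collective direction plus isotropic coordinate noise. The planted
  direction is projected onto the orthogonal complement of the rigid-body
  generators (in the mass-weighted basis) before use: a planted motion with
  a rigid component would be partially absorbed by superposition and the
  ground truth would no longer be recoverable even in principle. Defaults
  (amplitude sd 1 A, noise sd 0.1 A per coordinate) give the mode about 8%
  of total weighted variance on the default chain — a clearly planted but
  not dominant signal. The generator returns the true amplitude series,
  which is the functional quantity the FMA tests regress; coupling a
  sub-region's RMSD linearly to the amplitude is not emulated, because the
  RMSD of a centred fluctuation is magnitude-like rather than linear in it.
* `generateMultistateTrajectory()` — frames drawn from displaced copies of
  a reference per stated occupancies (default 0.55/0.36/0.06/0.03 over
  1200 frames: a four-state ensemble dominated by two conformations, the
  population structure typical of an equilibrated MD clustering) with
  within-state isotropic noise (0.3 A) and between-state RMSD 8 A.
* `generateToyComplex()` — two-ion (closed forms), helix-pair (neutral
  chains, multi-residue decomposition, clean separability) and
  random-packed (irregular geometry) complexes with Amber-flavoured
  per-element radii, LJ parameters and HCT screening factors.

What passing these tests shows: the estimators recover planted collective
modes, state partitions, populations and energy identities under their own
statistical assumptions, and every arithmetic pathway agrees with an
independent oracle. What it does not show: behaviour on real force-field
ensembles — anharmonic basins, correlated (non-isotropic) noise, solvent
memory, conformational exchange broader than discrete states — nor any
claim about absolute binding energies, which depend on force-field
parameters and sampling outside the package's scope. The headline numbers
of comparative protein-DNA studies (tens of kcal/mol with order-10 SDs)
arise from microsecond explicit-solvent trajectories; this package supplies
the analysis layer one would run on such data, verified where verification
is possible.

## Numerical conventions and problem sizes

Tolerances asserted in the test suite are part of the package contract:
rigid-motion invariance of superposition and of all energy terms to 1e-9;
single-ion GB to the Born formula at 1e-10 relative; HCT radii to the
quadrature at 1e-6; decomposition conservation at 1e-6 kcal/mol;
SSR/SST monotonicity to 1e-12; unit-mode normalisation at 1e-9. The
brute-force superposition comparison uses a ~108k-point Euler grid and is
asserted within the grid's displacement resolution. Test problem sizes
(50,000-frame noise trajectories over 100 atoms; 20 seeds of 2000-frame FMA
recoveries; 20 seeds of 1200-frame clustering; 12-frame exact-arithmetic
instances) were chosen so each statistical bound has comfortable margin
while the whole suite stays interactive; the pairwise-RMSD and alignment
kernels are RcppArmadillo C++ for exactly this reason.

Degenerate inputs are errors, not guesses: empty selections, fewer than
three atoms or collinear point sets for superposition, single-frame RMSF,
constant functional series, overlapping receptor/ligand selections, empty
clusters, zero-length frame windows and non-positive tolerances all raise
immediately with a message naming the offending object.
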