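---
title: "Motif-guided FFT docking of peptide fragments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-guided FFT docking of peptide fragments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdock)
```

# The problem and the modeling idea

A large fraction of transient protein interactions involve a protein
domain recognizing a short linear motif — a sequence pattern such as
`RXL`, where fixed positions (R, L) carry the specificity and `X` is any
residue. Peptides are too flexible for classical rigid-body docking, but
motif regions in their *bound* state occupy a narrow ensemble of backbone
conformations, and close analogues of the bound conformation already exist
in solved structures of unrelated proteins. `fragdock` therefore replaces
conformational search with retrieval: harvest backbone fragments at motif
matches in a structure database, and dock each fragment rigidly. Rigid
docking over all translations of a rotated ligand can be scored
simultaneously with FFTs, which is what makes the global search cheap.

# Stage 1: fragment library

**Identity exclusion.** To avoid rediscovering the target's own structure,
database chains with more than 30% sequence identity to any supplied
target sequence are removed first. Identity here is the number of
identical aligned positions in a global alignment (match +1, mismatch 0,
linear gap −1) divided by the shorter length. This scheme is deliberately
simple and fully deterministic; on unrelated random protein sequences it
yields ~5–10% identity, far below the 30% cutoff, while duplicates score
1.0. The traceback prefers the diagonal, so the reported match count is
unique.

**Padding and size control.** Motifs shorter than 5 residues are padded
with wildcards; wildcards are added in pairs, C-terminal side first
(`RXL` becomes `RXLXX`). The match count over the filtered database is
then steered into the 100–1000 window:

* too few matches → **generalize**: convert a fixed position to a
  wildcard. Positions added by restriction are undone first (outermost
  first, C side before N side); after that the original fixed position
  whose residue is least frequent in the database is sacrificed, but never
  below two fixed positions — the motif's anchor residues are preserved
  longest.
* too many matches → **restrict**: extend the pattern by one fixed
  residue copied from the peptide's real flanking sequence, alternating
  C-terminal then N-terminal. This requires the caller to supply the
  peptide context; without it no restriction move is available and the
  loop stops.

Each iteration is recorded in a history table (pattern, match count). The
loop stops in-window, when no move is available, or after `max_iter`
iterations; zero matches after exhausting generalization raises a typed
empty-library error carrying the history.

# Stage 2: fragment clustering

Fragments are clustered greedily on pairwise superposed backbone RMSD
(all four backbone atoms per residue, optimal Kabsch superposition with
reflection correction) at a stringent 0.5 Å radius: repeatedly take the
fragment with the most neighbors within the radius (ties: lowest input
index), form a cluster, remove it. The 25 largest cluster centers proceed
to docking. Greedy removal guarantees that retained centers are pairwise
more than one radius apart.

# Stage 3: FFT docking

## Energy grids

The receptor is discretized at 1.0 Å (default) into three scalar fields:

* **Repulsive core** `rep`: 1 on voxels within 1.8 Å of any heavy atom.
* **Attractive shell** `att`: minus the *number* of receptor atoms whose
  shell (1.8–4.8 Å) covers the voxel. Using the contact count rather than
  a binary flag makes concave sites — surrounded by more atoms — score
  deeper than flat surface, which is exactly the signal that cluster-size
  ranking needs to tell a binding pocket from bulk surface; it is a
  discretized attractive van der Waals term.
* **Coulomb potential** `elec`: Σ q·(4r²)⁻¹ with the distance-dependent
  dielectric ε(r) = 4r, distances capped below at one voxel and truncated
  at 12 Å. Inside the repulsive core the field is screened to zero: that
  region is physically unreachable, and removing the 1/r² singularity
  there prevents core-penetrating poses from being rewarded for touching
  buried charges.

Charges use a residue-level unit model (Asp/Glu −1 on the carboxylate
carbon, Lys/Arg +1 on the terminal nitrogen, His +0.1, backbone neutral),
falling back to CB then CA when side-chain atoms are absent — fragments
carry only backbone coordinates, so their charges sit on the CA of charged
residue codes. No hydrogens are needed.

The total score of a ligand placement is the weighted sum
`w_rep·E_rep + w_att·E_att + w_elec·E_elec` (lower is better). The shipped
weight sets are `standard` = (50, 1, 300) and `elec-favored` =
(50, 1, 1500). The core weight is set high enough that a single-voxel
clash always outweighs any attainable shell or Coulomb gain — with a
contact-count attractive term a soft core would invite poses that trade
one clash for several extra contacts. The elec-favored set up-weights the
Coulomb term five-fold for interfaces dominated by electrostatic
attraction, where the standard set may rank near-native poses poorly.

## Correlation and pose selection

For each rotation in the set, the fragment (centered on its centroid,
rotated, deposited to nearest voxels) is scored at every integer
translation at once via FFT cross-correlation, using the circular
convention; the implementation is held to ≤ 1e-6 relative deviation from
a direct triple-loop sum in the test suite. Only translations that do not
wrap the ligand across the periodic boundary are valid. One best
translation per rotation is kept (ties: lowest linear voxel index), which
prevents a single rotation's basin from flooding the pool; the 250
lowest-energy poses per fragment are retained, each with per-term scores
recomputed by direct summation at its placement.

Grids are sized automatically: the smallest dimensions with only 2/3/5
prime factors that hold receptor extent + ligand extent + a safety pad,
with the receptor centered — so every non-wrapping placement around the
receptor is reachable.

## Rotational sampling

Rotations come from a low-discrepancy (radical-inverse) point set mapped
to unit quaternions by the subgroup (Shoemake) algorithm, giving a
quasi-uniform cover of rotation space; the seed applies a
Cranley–Patterson shift, so the set is deterministic in (n, seed) and the
identity is always first. The default of 120 rotations is a desk-scale
setting chosen so a full fixture pipeline (25 fragments) runs in about a
minute; production-scale docking would use orders of magnitude more. The
nearest-neighbor angle distribution of the default sets has a coefficient
of variation below 0.5, which the suite asserts.

# Stage 4: selection and evaluation

Pooled poses are clustered with the same greedy rule but on **receptor-
frame RMSD without re-superposition** — superposing would erase the
binding-site location, which is precisely what pose clustering must
distinguish. The 3.5 Å radius represents the resolution of basins of
attraction. The cluster representative is its lowest-energy member;
clusters are ranked by member count (a breadth-of-basin proxy), ties by
representative energy. Whether the original protocol clusters with or
without superposition is not documented; the receptor-frame choice is a
deliberate, configurable policy here.

Clusters whose representative comes within 5.0 Å (any backbone atom to
any atom) of user-declared interface residues are removed — these mark
faces where other domains attach, where a peptide prediction would be an
artifact. Filtering runs on the full cluster list *before* truncation to
the reported top 20, then survivors are re-ranked consecutively. A
refinement hook (`refine_representatives`) sits where a force-field
minimizer could relax representatives; the default is an explicit
pass-through.

With a native complex supplied, the model receptor is superposed onto the
native receptor on CA atoms matched by author residue numbering, that
transform is applied to each prediction, and the peptide backbone RMSD to
the native peptide (no further superposition) decides acceptability at
the 4.0 Å CAPRI peptide threshold.

# The synthetic study system

All development and testing runs on fixtures that are pure functions of a
seed:

* **Toy receptor** (`make_toy_receptor`): a solid three-layer slab of
  idealized residues (3.5 Å along strands, 2.4 Å between strands, 3 Å
  between layers — spacings chosen so no interior void exceeds the 1.8 Å
  core radius; a porous interior would let single atoms thread the slab
  and create spurious minima). Two wall rows raised flush with the slab's
  long edges form a groove ~4.8 Å wide and ~3 Å deep along the top face,
  the slab's only concave feature, geometrically complementary to an
  extended 5-residue peptide. An aspartate with a buried carboxylate under
  the groove floor gives the pocket an electrostatic signature that is
  asymmetric along the groove, so the correct peptide direction is
  energetically distinguished from the reversed one.
* **Planted complex** (`make_planted_complex`): the peptide realizing the
  padded motif (wildcards as alanine) laid in the groove with its arginine
  over the aspartate. The construction is *verified*, not assumed: the
  suite exhaustively scores every valid identity-rotation translation by
  direct summation and asserts the planted placement is the global
  optimum, and the docking tests assert the planted pose is recovered at
  rank 1 within voxel rounding (spacing·√3). The slab's bottom layer is
  returned as the declared other-domain interface; the groove sits > 8 Å
  above it, safely outside the 5 Å removal cutoff.
* **Fragment database** (`make_fragment_database`): background sequences
  are drawn from the full amino-acid alphabet minus the motif's first
  fixed residue, so matches occur exactly where planted (the achieved
  count is re-verified with `find_matches` before returning) while
  random-pair identity stays near 7%, below the exclusion threshold.
  Planted windows realize the motif with random neutral wildcard fills at
  jittered positions, and carry the native backbone jittered by Gaussian
  noise (σ = 0.25 Å by default — small enough that copies of one
  conformer co-cluster at the 0.5 Å radius, large enough to populate
  multiple clusters). Scenario builders (`make_library_fixture`) engineer
  databases with 50 / 150 / 1200 initial matches to exercise the
  generalize, in-range and restrict paths of the size-control loop.

What the fixtures do *not* emulate: real side chains, Ramachandran-
distributed backbones, crystallographic disorder, or the size and
redundancy of a real structure database. Passing tests therefore
demonstrate the correctness and determinism of the machinery — match
counting, clustering, FFT scoring, ranking, evaluation — under controlled
geometry, not benchmark-level docking accuracy on real complexes, which
requires a full structure database and production-scale rotational
sampling.

# Numerical choices and degenerate inputs

* All tie-breaks are by lowest index (greedy centers, pose sorting,
  translation minima), making every stage rerun-stable; tables are
  written with fixed-width formatting so identical runs are byte-identical.
* Kabsch superposition corrects the SVD sign so reflections are never
  returned; fewer than 3 points is a validation error.
* Alternate locations in PDB input: the conformer whose first atom has
  the highest occupancy wins, ties to file order. Waters and HETATM are
  excluded; nonstandard residues render as "X".
* "Unstructured" terminal residues (no definition exists in the
  protocol's description) are taken as backbone-incomplete or above the
  chain's 90th percentile of per-residue B-factors, removed only in
  terminal runs capped at `max_tail` per terminus; `max_tail = 0`
  disables trimming.
* Empty results are typed conditions (`empty_structure_error`,
  `empty_library_error`, `grid_fit_error`, …) rather than sentinel
  values; the CLI maps them to exit codes (0 ok, 2 user error, 3 empty
  result).

# Problem sizes

The default study conditions — 30 database chains, 150 planted matches,
25 fragment clusters, 120 rotations, 250 poses kept per fragment — give a
complete pipeline run of roughly a minute on one CPU and are the sizes
used throughout the test suite and the acceptance script. The constants
fixed by the protocol itself (0.5 Å and 3.5 Å clustering radii, top 25
fragments, top 250 poses, 30% identity, 100–1000 library window, minimum
motif length 5, 4.0 Å acceptance) are shipped as validated configuration
defaults and audited by a test.

# Known limitations

* The energy model has three linear correlation terms; the pairwise
  statistical potentials used by production FFT docking engines are out
  of scope, though the weighted-sum architecture leaves a slot for more
  terms.
* Receptors are docked as given (plus optional tail trimming); no
  decomposition into independent binding units is attempted.
* Local force-field minimization of representatives is a pass-through
  hook.
* Fragment RMSD clustering is O(n²) in library size with an SVD per pair;
  libraries at the 1000-fragment cap take a few minutes to cluster.
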