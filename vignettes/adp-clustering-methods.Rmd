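---
title: "Methods: paired-state ADP metrics, differential statistics and Ward clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-state ADP metrics, differential statistics and Ward clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpcluster)
```

## The data model

Anisotropic refinement of a high-resolution crystal structure assigns every
atom a symmetric 3×3 displacement tensor **U** (the ADP), deposited in PDB
ANISOU records as the six unique elements ×10⁴ in Å², in the orthogonal-Å
basis. When diffraction frames are split into two interleaved series — an
"odd" series recorded with an external stimulus on and an "even" series with
it off — and each series is refined independently, every atom in every
crystal carries a *pair* of tensors. `adpcluster` works on three layers of
that data:

1. **Per-tensor metrics.** Diagonalisation
   U = P·diag(E₁,E₂,E₃)·P⁻¹ gives the thermal-ellipsoid axes. Two scalar
   summaries are used throughout: the equivalent isotropic B-factor
   B_eq = 8π²·tr(U)/3 (overall displacement magnitude, Å²) and the
   anisotropy ANISO = min(E)/max(E), which is 1 for a perfect sphere and
   approaches 0 for an extreme ellipsoid.
2. **Paired differences.** For each atom, metric(odd) − metric(even),
   pooled per amino-acid type or per residue across all crystals of one
   condition, reported as means with 95% confidence intervals.
3. **Clustering.** Each (crystal, atom) observation is a 12-dimensional
   vector — the six unique elements of the odd tensor followed by the six
   of the even tensor, in raw Å² — clustered agglomeratively with Ward's
   minimum-variance method under the Euclidean distance.

## Tensor metrics and their numerical conventions

`tensor_eigen()` uses the symmetric eigensolver, returns eigenvalues in
descending order and fixes each eigenvector's sign so its leading component
(first with magnitude above 10⁻¹²) is positive. This makes decompositions
deterministic across platforms; neither B_eq (a trace) nor ANISO (an
eigenvalue ratio) is affected by ties or sign choices. B_eq and ANISO are
invariant under rotations of the tensor and ANISO under positive scaling;
the test suite verifies both to 10⁻¹⁰ on random tensors.

Deposited tensors are occasionally **non-positive definite** (NPD) — a
refinement artifact in which the smallest eigenvalue is ≤ 0 and the thermal
ellipsoid is not a real ellipsoid. The package computes metrics for such
tensors (ANISO then comes out ≤ 0) but flags them, excludes them from paired
differences and, by default, from clustering (`include_npd = TRUE`
overrides). A tensor whose *largest* eigenvalue is ≤ 0 has no meaningful
shape at all and raises an error. Hydrogens are dropped at parse time:
riding hydrogens carry no independently refined ADPs.

Alternate conformations are kept as distinct atom identities (the altloc is
part of the matching key) and every atom of a residue with any altloc is
flagged `res_has_alt`, so analyses that should only compare singly-modelled
residues can filter on it (`assemble_pool(..., exclude_altloc = TRUE)`).
Occupancy is carried through but never used as a weight.

## Pairing and the observation pool

Atoms are matched between the two states of a crystal on exact identity:
chain, residue number, insertion code, residue name, atom name, altloc.
Only atoms with a tensor in *both* states become observations; everything
else lands in an exclusion report with a reason ("unmatched in even",
"tensor missing in odd", ...). The pipeline checks conservation: every
parsed non-hydrogen atom is accounted for as pooled, excluded, or filtered.
Pool assembly defaults to *all* tensor-bearing atom pairs, including
heteroatoms and waters, with `polymer_only` and `exclude_altloc` switches —
the selection that applies to a given study is a property of that study, so
it is exposed rather than hard-coded.

## Differential statistics

Group summaries pool the per-atom differences of all crystals of one
condition as independent observations and report the mean with a Student-t
95% interval (n−1 degrees of freedom). The t interval was chosen over the
normal because it is exact under the Gaussian working model and
indistinguishable from the normal interval at the group sizes that arise in
practice (tens to hundreds of atoms); a single-atom group reports its mean
with the interval marked missing rather than a degenerate zero-width one.
Atoms of the same residue are treated as independent when pooled per type —
a simplification; displacement noise is correlated within a residue, so
per-type intervals are, if anything, slightly anticonservative. No
multiple-testing adjustment is applied: the output is descriptive.

Per-residue and per-type profiles (mean B_eq, mean ANISO over all equivalent
atoms of the selected crystals and states) support two comparisons: Pearson
correlation against external per-residue predictions, supplied as a plain
two-column table so normal-mode or molecular-dynamics output from any code
can be compared without running simulations here; and crystal-vs-crystal
correlation matrices as a self-consistency check. Pearson's coefficient is
used precisely because it ignores the absolute scale, which simulated
displacements notoriously miss.

## Clustering

The feature space is deliberately the **unmodified** tensor elements — no
centering, scaling or whitening — so that displacement magnitude, ellipsoid
shape and orientation all contribute to similarity on their natural Å²
scale. The distance is plain Euclidean in the 12 coordinates. Ward's method
is run in its classical minimum-variance form (the `ward.D2` criterion on
Euclidean distances): at each step the merge is chosen that least increases
the total within-cluster sum of squares, and merge heights equal
√(2·ΔSS), which is monotone. The test suite checks the whole merge
sequence against an exhaustive minimum-variance-increase oracle on small
pools, and permutation invariance of the height multiset on larger ones.
Equal-cost merges are resolved by the deterministic order of the underlying
agglomeration; for continuous tensor data exact ties have probability zero,
and output is reproducible for a fixed input ordering either way.

The distance definition is pluggable in principle — any dissimilarity that
vanishes between identical tensor pairs ranks near-identical atoms
similarly — but the Euclidean form is the only shipped and tested default,
because Ward's variance criterion presupposes a Euclidean embedding.

"Branch" queries need a definition the dendrogram itself does not supply:
`branch_composition()` reports, for an atom observed m times across
crystals, the *minimal subtree* containing each count j ≤ m of its
observations, with subtree size and purity; for a condition query it scores
every subtree by condition purity and recall. This minimal-covering-subtree
notion is this package's operationalisation of visually inspecting branch
tips, and the output labels it as such.

## The synthetic ensemble generator

`generate_ensemble()` produces the multi-crystal, two-state PDB fixtures on
which everything is validated without any external data: per-atom tensors
are drawn from k well-separated SPD **archetypes** (random rotations of
random eigenvalue triples) plus element-wise Gaussian noise,
eigenvalue-clipped at 10⁻⁴ Å² to stay positive definite; in treated
crystals' odd state the smallest eigenvalue is multiplied by an effect
factor < 1, making atoms more anisotropic under "irradiation" — the
qualitative direction the paired statistics should recover. Noise perturbs
tensor *elements*, not eigenvalues, so it also rotates ellipsoids, as
refinement noise does. Atoms sit on a self-avoiding 3.8 Å random walk in
five-atom alanine-like residues; coordinates exercise the file format and
key matching but enter no metric. Residue names encode archetypes, so
per-type statistics have a planted truth.

Default conditions (fixed once): 6 crystals (3 treated, 3 reference), 200
atoms each, 4 archetypes with eigenvalues uniform in 0.02–0.20 Å²
(B_eq ≈ 5–50 Å², typical of a cryo-cooled high-resolution structure),
minimum archetype separation 0.06 Å² in the 12-D feature metric, noise sd
= separation/20 = 0.003 Å² per element, effect factor 0.8 (a modest 20%
contraction of the smallest eigenvalue — real stimulus effects are reported
as directions, not magnitudes, so this is a free parameter chosen to be
detectable but not dominant), seed 1. Recovery is scored with the adjusted
Rand index against the planted archetype labels; at the default noise the
k = 4 cut recovers the archetypes with ARI ≥ 0.99, and recovery degrades
monotonically as noise grows.

One geometric subtlety the generator exposed: when an archetype's two
smallest eigenvalues are nearly degenerate, the "smallest eigenvector" along
which the treated-state contraction acts is selected by noise per atom, so
treated observations spread over a ring of orientations instead of forming
one tight branch. The paired ANISO statistics are unaffected (the
eigenvalue *ratio* shifts identically), but single-branch recovery of the
treated set is only guaranteed for a coherent contraction direction — the
branch-query test plants one explicitly.

## What the synthetic tests do and do not show

The generator reproduces the statistical skeleton of a paired-state ADP
study: archetype structure, paired tensors, condition-dependent anisotropy
shifts, ANISOU quantisation (10⁻⁴ Å²). It does **not** emulate refinement
restraints (which correlate neighbouring atoms' ADPs), TLS-like rigid-body
structure, resolution-dependent noise, series-termination artifacts, or
chemically realistic geometry. Passing the planted-truth tests therefore
demonstrates that the arithmetic and the clustering recover structure that
is present at realistic noise; it does not demonstrate that real deposited
structures contain such structure — that is what the method is *for*.

## Problem sizes and runtime choices

Validation runs use 6 crystals × 200 atoms (1200 observations, ~1 s to
cluster), coverage simulations 500 replicates of n = 1000, and exhaustive
Ward oracles pools of ≤ 8 — sizes at which the oracles are exact and the
whole suite runs in well under a minute. Full-scale pools of ~16000
observations cluster in a few seconds; memory for the dissimilarity matrix
(~1 GB at n = 16000) is the practical ceiling of the dense implementation.

## Known limitations

- Tensors are taken in the Cartesian orthogonal-Å basis exactly as
  deposited; no conversion from crystallographic bases and no symmetry
  expansion is attempted.
- mmCIF input is not parsed; PDB ANISOU is the contract format.
- Condition-cluster recall depends on the coherence of the planted (or
  real) effect direction, as described above.
- Per-type confidence intervals assume atom-level independence.
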