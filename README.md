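# adpcluster

Differential analysis and hierarchical clustering of anisotropic atomic
displacement parameters (ADPs) in paired-state macromolecular crystal
structures.

## The problem

Anisotropic refinement of a high-resolution crystal structure describes each
atom's positional spread with a symmetric 3×3 tensor **U** (deposited as PDB
ANISOU records, the six unique elements ×10⁴ in Å²). When diffraction frames
are recorded in two interleaved series — for example with an external
stimulus alternately on ("odd" frames) and off ("even" frames) — and each
series is refined separately, every atom in every crystal carries a *pair*
of tensors. Two questions follow:

1. **Did the stimulus change the displacements?** Per atom, compare the two
   states through the equivalent isotropic B-factor

   B_eq = 8π² · tr(**U**)/3

   and the anisotropy of the thermal ellipsoid

   ANISO = min(E₁,E₂,E₃) / max(E₁,E₂,E₃),

   where E₁…E₃ are the eigenvalues of **U** (ANISO = 1 is a perfect sphere;
   → 0 an extreme ellipsoid). Differences B_eq,odd − B_eq,even and
   ANISO_odd − ANISO_even are pooled per amino-acid type or per residue
   across crystals of one condition and reported with 95% confidence
   intervals of the mean.

2. **Which atoms move alike?** Every (crystal, atom) observation becomes a
   12-dimensional feature vector — the six unique elements of its odd-state
   tensor followed by the six of its even-state tensor, unscaled, in Å² —
   and the whole pool is clustered with Ward's minimum-variance method
   under the Euclidean distance

   d(u,v) = √Σₖ (uₖ − vₖ)², k = 1…12.

   Atoms with similar ellipsoid size, shape *and* orientation end up on the
   same branch, so repeated observations of chemically equivalent atoms
   across crystals can be found with branch queries.

The package is aimed at crystallographers and structural biophysicists with
sets of anisotropically refined (crystal × state) structure pairs, and ships
a synthetic multi-crystal ensemble generator with planted tensor archetypes
so the whole pipeline is testable without any deposited data.

## Worked example

Six synthetic crystals (3 "treated", 3 reference), 200 atoms each, tensors
drawn from 4 planted archetypes; treated crystals get a 20% contraction of
the smallest eigenvalue in the odd state (more anisotropic under the
stimulus):

```r
library(adpcluster)

dir  <- tempfile()
res  <- generate_ensemble(synthetic_spec(), dir)
pool <- assemble_pool(file.path(dir, "manifest.csv"))
pool
#> ADP observation pool: 1200 paired atoms from 6 crystals
#>   exclusions: 0; filtered: 0

diffs <- paired_differences(pool)
subset(group_summary(diffs, metric = "aniso", by = "type"),
       condition == "treated")
#>   group condition   n    mean     sd ci_half
#> 5   ALA   treated 150 -0.1104 0.0381 0.00615
#> 6   CYS   treated 150 -0.1399 0.0320 0.00516
#> 7   SER   treated 150 -0.0625 0.0322 0.00520
#> 8   THR   treated 150 -0.0944 0.0375 0.00605
```

Every treated amino-acid type shows a negative mean ANISO_odd − ANISO_even
whose 95% CI excludes zero — the atoms became more anisotropic in the
stimulus-on state — while the reference crystals' means sit within their
CIs of zero (first four rows, not shown). Clustering recovers the planted
archetypes perfectly at this noise level:

```r
tree <- adp_ward(pool)
tree
#> ADP Ward tree: 1200 observations, 1199 merges, max height 2.946

labels <- cut_adp_tree(tree, k = 4)
recovery_score(labels, res$truth$archetype)   # adjusted Rand index vs truth
#> [1] 1
```

`branch_composition(tree, list(resno = 135L, elety = "NE2"))` reports the
minimal subtrees holding an atom's repeated observations (size, purity,
members); `branch_composition(tree, "treated")` scores every subtree by
condition enrichment. `run_pipeline(run_config(manifest, out_dir))` executes
the whole chain — parse, pair, metrics, group summaries, crystal-vs-crystal
correlation matrices, linkage export, branch report — into an auditable
output directory, and `inst/exec/adpcluster` wraps `simulate`/`run` for the
shell.

Real data enter the same way: a manifest CSV with columns
`crystal, condition, odd, even` pointing at anisotropically refined PDB
files (e.g. the odd/even depositions of a paired-state experiment), plus
optional `polymer_only` / `exclude_altloc` filters. External per-residue
displacement predictions (normal-mode or MD output) are compared with
`compare_prediction()`, which matches a two-column table against a
`residue_profile()` and returns the Pearson correlation.

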