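---
title: "Dynamics similarity scoring: model, parameters and design choices"
author: "dssalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics similarity scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dssalign)
```

## The problem

Proteins with nearly identical folds can differ markedly in their collective
dynamics, and functional states of the same protein — the tense (T), relaxed
(R) and fully liganded (R2) quaternary states of tetrameric hemoglobin being
the canonical example — are often better separated by how they move than by
how far their coordinates deviate. dssalign quantifies this with a *dynamics
similarity score* (DSS) built from the slowest normal modes of the
Anisotropic Network Model (ANM), and clusters datasets of structures by that
score.

## The model

### Coarse-grained network

Each residue is a single node at its C-alpha; each heme group contributes
four pseudo-nodes at its methine carbons (CHA, CHB, CHC, CHD). Nodes closer
than a cutoff (default 15 Angstrom) are joined by identical harmonic
springs. The 3N x 3N Hessian has off-diagonal super-elements

$$H_{ij} = -\frac{\gamma}{d_{ij}^2}\, r_{ij} r_{ij}^T, \qquad d_{ij} \le r_c,$$

with diagonal super-elements cancelling each row sum. A connected network
has exactly six zero eigenvalues (rigid translations and rotations); the
eigenvectors of the smallest non-zero eigenvalues are the slow modes
$\vec U_{ik}$ (the deformation 3-vector of node $i$ in mode $k$). Modes are
computed for the *entire assembly as provided* even when a single chain is
compared: the quaternary context shapes a chain's intrinsic motions, and
restricting the mode vectors to one chain afterwards retains that context.
The spring constant $\gamma$ (default 1, arbitrary units) cancels from all
cosine-based scores; it is fixed only so that eigenvalue tests have a
defined convention.

### Mode alignment and the DSS

Given two structures superposed in one frame, the cell score for residue
$i$ of protein A (mode $k$) against residue $j$ of protein B (mode $l$) is

$$S_{ij} = \frac{\vec U_{ik} \cdot \vec V_{jl}}{|\vec U_{ik}||\vec V_{jl}|} - C,$$

positive exactly when the cosine between the two deformation vectors
exceeds the threshold $C$. With the distance constraint enabled (the
default, appropriate for homologous proteins), $S_{ij} = -1$ whenever the
superposed nodes are further apart than $R_c$.

For each of the $n \times n$ combinations of the $n$ slowest modes a score
matrix is built and its best non-overlapping gapless diagonal segments of
length at least `min_len` are extracted greedily (the local-alignment idea
without gaps: a match pairs consecutive residues of both proteins). Because
a normal mode's overall sign is arbitrary, each combination is aligned
twice — second mode as-is and negated — and the variant with the better
best match is kept. All matches are pooled; the top $2n$ by total score are
selected. Each residue then keeps, per mode combination, its single best
selected cell score; the per-residue profile is the sum of these best
scores (uncovered residues contribute 0) and

$$\mathrm{DSS} = \tfrac12\left(\overline{r^{(1)}} + \overline{r^{(2)}}\right),$$

the average of the two profile means. For a protein against itself every
diagonal (k, k) match is perfect, which gives the useful calibration floor
$\mathrm{DSS}(A,A) \ge n\,(1 - C)$ (3.6 at defaults).

### Superposition

Pairs are placed in a common frame before scoring. The built-in routine
seeds a residue correspondence by global sequence alignment (match 1,
mismatch 0, gap -0.5 on one-letter codes — an identity-dominated seed is
sufficient for the homologous inputs the method targets), then iterates a
Kabsch least-squares fit while re-filtering the seed pairs under a distance
cutoff shrinking linearly from 8 to 4 Angstrom over 20 iterations, and
returns the transform with the best TM-score. TM-scores are normalized by
the shorter structure's C-alpha count, making the single reported scalar
symmetric in its inputs. Matrices produced by external structure-alignment
tools can be imported instead (`load_external_superposition()`). Mode
computation and superposition commute: the eigenvectors of a rigidly
rotated network are the rotated eigenvectors, so modes are computed once in
the deposited frame and their vectors rotated per pair.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `C` | 0.7 | cosine (unitless) | similarity threshold; vectors within ~45 degrees score positively |
| `Rc` | 10 | Angstrom | distance constraint on superposed node pairs |
| `n` | 12 | modes | slowest modes aligned; `2n` matches selected |
| `min_len` | 7 | residues | minimal gapless match length |
| `max_matches` | 200 | matches | cap per mode-pair matrix |
| `cutoff` | 15 | Angstrom | ANM contact cutoff |
| `gamma` | 1 | arbitrary | uniform spring constant (cancels in DSS) |

`C` is applied in cosine units: the score subtracts it from a cosine and
the admissible range is [0, 1], so a threshold of 0.7 corresponds to an
angular tolerance of roughly 45 degrees. The mode count `n = 12` is where
the score ranking stabilises: `modecount_scan()` computes the Pearson
correlation between the upper-triangle DSS vectors of successive mode
counts, and on our synthetic datasets (as in the hemoglobin application
that motivated the method) the correlation plateaus near twelve modes.
Raising `Rc` admits comparisons between more divergent structures at the
cost of spatial specificity; disabling the constraint altogether
(`use_distance_constraint = FALSE`) is possible but leaves the score free
to pair spatially unrelated regions.

## Numerical choices

* **Eigensolver.** The slowest `n_keep + 6` eigenpairs are obtained by
  shift-invert Lanczos (ARPACK, via igraph) applied to a sparse Cholesky
  factor of $H + \sigma I$ with $\sigma$ a small multiple (1e-6, escalated
  if factorization fails) of the largest Hessian diagonal; eigenvalues are
  then polished as Rayleigh quotients. A dense full eigendecomposition is
  available (`method = "dense"`) and serves as an independent cross-check
  in the test suite; on connected fixtures the two agree to machine
  precision. Exactly six eigenvalues must fall below 1e-8 times the
  largest computed one — more indicates a disconnected or degenerate
  network (the dominant real-data failure mode) and raises an error rather
  than a silent bad answer.
* **Mode sign and scale.** Eigenvector signs are fixed deterministically
  (largest-magnitude component positive) for reproducibility, but every
  score is invariant to sign flips and rescaling of stored modes by
  construction, and the tests assert this to 1e-9.
* **Greedy segment extraction.** Per round, the best segment per diagonal
  is found with prefix sums and a running prefix minimum (O(length) per
  run); ties go to the smallest `(i0, j0)` lexicographically, and equal
  prefix minima keep the earliest start, so the tie-break is well defined.
  Only segments with strictly positive total score qualify; negative cells
  inside a qualifying segment are kept as-is, so per-residue contributions
  can in principle be negative. The compiled implementation is checked
  against an exhaustive R enumeration of every segment on random matrices.
* **Tie-breaking and symmetry.** Pooled matches are ordered by score, then
  `(k, l, i0, j0)`. Under transposition of the comparison these keys swap,
  so exact score ties between distinct segments could in principle break
  symmetry; for continuous inputs such ties have probability zero, and
  segment sums accumulate in the same order along a diagonal under
  transposition, so DSS(A, B) and DSS(B, A) agree bit-for-bit in practice
  (asserted to 1e-9 across random pairs).
* **Degenerate inputs.** Coincident nodes, disconnected networks,
  correspondences below three pairs, collinear point sets and zero-length
  deformation vectors each raise a specific error (or, for zero vectors, an
  unalignable score of -1) instead of propagating NaNs.
* **Distance transform.** Clustering uses $d = \max(\mathrm{DSS}) -
  \mathrm{DSS}$: affine, rank-reversing and non-negative. The alternative
  $1/(1+\mathrm{DSS})$ is available behind an argument. Pairs whose
  superposition fails are imputed at the maximum distance with a warning so
  that one bad pair does not abort a large run.

## The synthetic generator, and what the tests do and do not show

Real structure datasets are hundreds of downloaded PDB entries; the package
instead ships a deterministic generator whose outputs exercise every stage:
ideal helical C-alpha traces (canonical 1.5 Angstrom rise, 100 degree
twist, 2.3 Angstrom radius, giving the familiar 3.8 Angstrom consecutive
C-alpha spacing), anti-parallel helix bundles as a compact globular-fold
surrogate, rigid multimers built by assembly transforms, Gaussian
coordinate noise (seeded, RNG-state preserving) and heme decoration. The
planted-structure clustering testbed — monomeric bundles versus the same
bundle dimerized, compared chain-against-chain with modes from the full
assembly, at 0.3 Angstrom coordinate noise — is the quaternary-structure
effect in miniature: the two families have near-identical chain folds but
different assembly dynamics, and complete-linkage clustering of the DSS
distance matrix separates them on every tested seed.

These fixtures are idealised: no side chains, no sequence variation, no
loops or disorder, and noise that is isotropic and independent per node.
Passing tests therefore demonstrate the correctness of the machinery —
scores, eigenproblems, alignment, bookkeeping — and the in-principle
sensitivity of the DSS to quaternary context, not the biological
classification performance on real crystal structures, which depends on
dataset curation and structure quality.

Problem sizes were chosen so the full suite runs comfortably on one CPU:
bundles of 30-60 nodes for scoring tests, a 300-node dimer for the
eigensolver cross-check, 12-entry datasets over 10 seeds for clustering
recovery, and 20x20 matrices for the extraction oracle.

## Design decisions that were genuinely open

* **"Non-overlapping" matches** are enforced by masking both the rows and
  the columns of an accepted segment within its mode-pair matrix, so a
  residue of either protein appears in at most one match per matrix. This
  makes "the best $S_{ij}$ per residue per mode combination" well defined.
* **"Top 2n" selection** is read as one global pool across all $n^2$ mode
  combinations (sign already resolved per pair), not a per-combination
  quota; the tie-break is documented above.
* **Sign choice** compares the best single match of the two variants
  (`sign_rule = "best_match"`); comparing summed match scores is available
  as `sign_rule = "total"`.
* **Chain scope of hemes.** When a comparison is restricted to one chain,
  heme pseudo-nodes carrying that chain's identifier are included — they
  are ordinary network nodes, and excluding them is possible by subsetting
  the node model.
* **The 200-match cap** applies per mode-pair matrix.
* **Biological units** are taken as given: `apply_assembly()` expands
  explicit (e.g. BIOMT) transforms, but nothing is fetched or inferred, so
  the assembly requirement becomes a documented input contract and the
  whole package runs offline.

## Limitations

The method presupposes superposable structures: dissimilar folds make the
seed correspondence collapse (an error, by design) and the distance
constraint then suppresses most of the score. Harmonicity limits the
dynamics description to the neighbourhood of the energy minimum. Mode
degeneracy (common in idealised symmetric fixtures, rare in real
structures) makes individual eigenvectors ill-defined within a degenerate
subspace; the eigensolver cross-check therefore compares only
non-degenerate modes, and scores computed from degenerate modes depend on
the returned basis.

## A worked example

```{r example, eval = FALSE}
unit  <- make_bundle(3, 12)                       # 36-residue helix bundle
dimer <- make_multimer(unit, 2)                   # its dimeric assembly

# chain A of the dimer, with modes from the whole assembly,
# against the isolated monomer:
r <- dss(dimer, unit, scopeA = "A", labels = c("dimer:A", "mono"))
print(r)
summary(r)

# a small planted dataset and its dendrogram
entries <- c(
  lapply(1:3, function(s) list(structure = perturb(unit, 0.3, s),
                               scope = NULL, label = paste0("mono_", s))),
  lapply(1:3, function(s) list(structure = perturb(dimer, 0.3, 10 + s),
                               scope = "A", label = paste0("dimer_", s))))
m <- dss_matrix(dataset_spec(entries))
tree <- hierarchical_cluster(to_distance(m))
write_newick(tree)
```
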