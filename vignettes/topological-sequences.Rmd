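---
title: "Topological sequences for protein-ligand complexes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological sequences for protein-ligand complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pthl)
```

This vignette documents how `pthl` converts a 3D protein-ligand complex into
a sequence of multiscale topological descriptors, the assumptions behind each
stage, and the numerical and design choices a maintainer should know about.

## 1. From structure to region

Inputs are heavy-atom structures: a protein (PDB) and a ligand (SDF or
MOL2). Hydrogens are dropped on loading — the descriptors are defined over
heavy atoms only, and most crystallographic inputs in this field do not
resolve hydrogens anyway. Waters are removed, the first alternate location
is kept, and only the first model of multi-model files is read. `HETATM`
records survive when their element is one of the protein-scheme elements
(C, N, O, S), so chemically modified residues contribute while ions and
exotic cofactors do not.

The interaction region keeps every ligand heavy atom and exactly those
protein atoms whose minimum Euclidean distance to *any* ligand atom is
`<= cutoff` (a closed threshold, matching the closed filtration convention
below). The cutoff is measured atom-to-atom rather than to the ligand
centroid: that is the convention under which region membership is monotone
and idempotent, both of which are property-tested. Two presets exist:

| preset | cutoff | filtration grid | sequence length |
|--------|--------|-----------------|-----------------|
| large  | 20 Å   | 0 → 10 Å, step 0.1 Å | 100 |
| small  | 12 Å   | 2 → 12 Å, step 0.2 Å | 50  |

The grid follows the half-open convention `(start, stop]` — values
`start + i * step`, `i = 1..N`. This is the only convention that yields the
stated lengths 100 and 50 without dropping the far endpoint, and it avoids
the degenerate all-disconnected snapshot at `d = 0`; which end is excluded
is our choice and is recorded here rather than asserted of anyone else.

## 2. Hyperdigraphs, Omega chain spaces and Laplacians

A *k-directed hyperedge* is an ordered tuple of `k+1` distinct vertices;
a hyperdigraph is a graded collection of such tuples. The Vietoris-Rips
hyperdigraph at scale `eta` contains one tuple for every vertex subset
whose **diameter** (max pairwise distance) is `<= eta`, oriented by a rule.
Two conventions deserve a note:

* **Weight.** Simplex weight is the diameter by default; a `radius` option
  halves the threshold (a simplex enters at radius `r` when its diameter is
  `<= 2r`). Diameter is the convention under which a 1-edge appears exactly
  at the interatomic distance, which is how the filtration axis is read
  throughout (an edge at `d = 3 Å` for a 3 Å pair).
* **Orientation.** The default rule sorts tuple vertices by descending
  Pauling electronegativity, ties broken by ascending vertex index, so that
  directions encode element differences. The source theory states that
  orientations carry physico-chemical information but fixes no formula; we
  chose one deterministic, total rule and verified (and property-test) that
  the dimension-0 Laplacian spectrum — the only spectrum entering the
  embedding — is invariant to it.

The boundary operator uses the standard alternating sign,
`∂(x_0,…,x_k) = Σ_i (−1)^i (x_0,…,x̂_i,…,x_k)`. A uniform-sign variant
(all terms weighted `(−1)^k`) breaks `∂∘∂ = 0` and with it every Betti and
persistence statement, so the alternating form is the only consistent
reading; the chain-complex identity is enforced to `1e-10` in the tests.

The Omega chain space `Ω_k = {x ∈ span(F_k) : ∂x ∈ span(F_{k−1})}` is
computed as the null space of the boundary composed with the projection off
`span(F_{k−1})`, with a relative singular-value tolerance of `1e-8`. For
face-closed inputs — every VR hyperdigraph — `Ω_k` is all of `span(F_k)`
and the standard edge basis is used, so boundary matrices are exact signed
incidence matrices. Coefficients are real; all eigenproblems use dense
symmetric solvers, which is appropriate because element-specific blocks are
small (at most the region size).

Spectra snap eigenvalues below `1e-8 · max(1, λ_max)` to zero (eigensolver
noise scales with the spectral radius) and clamp the tiny negative residue
of PSD matrices. The six summary statistics are the zero multiplicity and
the mean, **population** standard deviation, minimum, maximum and sum of
the strictly positive eigenvalues. Two edge conventions: an empty positive
set reports all five positive statistics as 0 (keeping sparse combinations
finite — they dominate early filtration steps), and "minimum" means the
smallest *positive* eigenvalue (the spectral gap), not the global minimum,
which would always be 0.

One spectral bound deserves care: the classic degree bound
`λ_max ≤ 2 d` is a *graph* Laplacian fact and holds here for `L_0` with
`d_0` the maximum vertex degree. For `k ≥ 1` the analogous inequality with
`d_k` (the maximum number of `(k+1)`-simplices sharing a `k`-simplex) is
not satisfied by the full Laplacian, whose down part inherits the
`(k−1)`-level spectrum; the bound that does hold, and that the acceptance
suite asserts, is `λ_max(L_k) ≤ max((k+2) d_k, (k+1) d_{k−1})`.

The persistent Laplacian `Δ_k^{a,b}` for nested hyperdigraphs `a ⊆ b`
restricts the scale-`b` boundary to the chains whose boundary lands in
`Ω_k^a` (another null-space computation at the same tolerance). Its kernel
dimension is the persistent Betti number, which the tests compare against
an independent rank-nullity oracle (`rank[Z^a B^b] − rank B^b`) on
randomized nested pairs.

## 3. The element-specific embedding

Interactions are encoded per element combination: 11 protein sets over
{C, N, O, S} (4 singletons, 6 pairs, the full set) times 13 ligand sets
over the 9 ligand heavy elements, protein-major order, 143 combinations.
The printed source list for the ligand side is corrupted in our extraction
(brace structure lost, 12 sets discernible where 13 are stated); the
scheme shipped here completes it with the phosphorus/halogen group
{P, F, Cl, Br, I}, its union with nitrogen, and the full 9-element set,
which preserves the stated count of 13 and exactly 5 carbon-containing
sets per side. The scheme carries a version string
(`pthl-es-11x13-1`) in every feature file so a future correction is an
explicit format change, not a silent one.

For each combination, atoms whose element is in the active set on their
side enter a masked distance matrix: protein-ligand pairs carry their
Euclidean distance, same-origin pairs and the diagonal are `+Inf`. Only
cross interactions can therefore create topology. At each grid value `d`
the threshold graph (the dimension-≤1 VR hyperdigraph of the masked
matrix) yields `L_0 = D − A`, whose six statistics fill one row of the
`(T, 143, 6)` tensor. Per-snapshot Laplacians feed the sequence — the
multiscale character comes from the grid; persistent pairs remain
available through `persistent_laplacian()` as an optional extra channel
but are not part of the default tensor. Only `L_0` statistics enter the
embedding; higher-`k` spectra are exposed through the API.

Feature files are JSON containers with full-precision (17-significant-
digit) values, so save/load round-trips are bit-exact; a CSV flattening
(one row per step × combination) is provided for interoperability.

## 4. The sequence model

The transformer is implemented natively in R with analytic
backpropagation (verified against central finite differences in the test
suite). Architecture: each step's 143×6 matrix is flattened and passed
through a 1×1 convolutional (per-step linear) projection with a
nonlinearity, added to a trainable multiscale (positional) embedding;
encoder blocks apply multi-head scaled dot-product attention
(`softmax(QKᵀ/√d_k)V`, rows summing to 1) and a ReLU feed-forward layer,
each with a residual connection; the decoder is the same block type but
deliberately shallower (asymmetric, in the masked-autoencoder spirit),
followed by a linear reconstruction head. Layer normalization is omitted:
at the scales this implementation targets, Adam with small initializations
trains stably without it, and its absence keeps the gradient path fully
transparent.

Pretraining masks a random fraction of filtration steps (default ratio
0.5 — the source cites a masked-autoencoder design without stating a
ratio) with a learned mask token and minimizes reconstruction error over
all positions. The loss is MSE; the source text labels its reconstruction
loss "mean square error (MAE)", an internally contradictory phrase we read
as MSE with a typo, and a `loss = "mae"` switch exists for the other
reading. Fine-tuning regresses a scalar affinity from the encoder output
at the first position. Two presets exist: `paper` (512-dimensional, depths
as placeholders pending the reference supplementary settings, which are
not in the text available to us) and `tiny` (32-dimensional, 2+1 layers)
used throughout the tests; all tests and the acceptance script further
shrink `seq_len` to keep runs in seconds. Training, masking and batching
draw from the config seed only, so runs are bit-reproducible.

Interpretability read-outs: `attention_score()` averages attention
weights over all encoder layers, heads and query positions into a
distribution over filtration steps (its argmax is the dominant interaction
scale); `saliency()` returns the absolute input gradient of the scalar
output, shape `(T, 143, 6)`. For a linear surrogate configuration the
saliency equals the coefficient magnitudes exactly, which anchors the
implementation test.

## 5. Evaluation metrics

Scoring reports PCC and RMSE, plus RMSE after multiplying both vectors by
1.3633 (the -log K to kcal/mol conversion). Ranking power over uniform
clusters: high-level success requires the exact experimental order,
low-level only the top complex; experimental ties count as high-level
failures by default (configurable to drop tied clusters). Docking success
is the fraction of ligands whose top-scored pose has RMSD strictly below
2 Å, with deterministic pose-id tie-breaks; RMSD is computed in the shared
receptor frame without superposition. Screening ranks candidates by
S = S1·S2, selects `ceiling(α·n)` compounds (so at least one is always
selected), and reports the success rate (best true binder — by experimental
affinity when available — in the top set) and the enrichment factor
`(#binders in top) / (#binders · α)` averaged over targets; exact
supplementary formulas were not available to us, so these are the standard
CASF definitions, flagged in the output metadata. Consensus averaging
repeatedly samples model subsets without replacement and scores the
averaged predictions.

## 6. Synthetic data: what it does and does not emulate

The generators make every stage testable offline and define the study
conditions for the acceptance checks:

* `canonical_shape()` — analytic point sets (pairs, paths, triangles, an
  8-point circle, a tetrahedron skeleton, two separated clusters) with
  known Betti numbers at stated thresholds; these are topology oracles,
  not molecules.
* `synthetic_complex()` — uniformly placed heavy atoms in a box (ligand
  centered so a binding region always exists) with elements sampled from
  the scheme alphabets, written to minimal PDB/SDF that the readers
  round-trip exactly. It emulates geometry, composition and file dialects —
  not conformational realism, sterics, or binding physics. Passing tests
  therefore demonstrate correctness of the featurization pipeline, not
  predictive power on real complexes.
* `benchmark_tables()` — clusters, scored poses (one sub-2 Å native pose
  per ligand) and screening candidates with known ground truth plus
  tunable Gaussian prediction noise, so every metric has a computable
  expected value (all powers are 1 at zero noise; enrichment of random
  rankings averages 1).

All generators are bit-deterministic in their integer seeds.

## 7. Problem sizes and limitations

The randomized suites use point clouds of up to 12 points (dimensions
0-2, 200 clouds), 50+ nested pairs for persistence, and tiny transformer
configurations (16-32 dimensions, sequence lengths 5-16, tens of
optimization steps); the acceptance script mirrors these sizes. These are
the package's chosen verification scales: large enough to exercise every
code path and statistical property, small enough to run anywhere.

Known limitations: alpha (Delaunay-restricted) hyperdigraphs are not
implemented (the VR construction is the only filtration; the API leaves
room for others); bond perception, protonation and charges are out of
scope; the VR enumerator is exponential in `max_dim` and intended for
region-sized inputs, not whole proteins; and reproducing published
benchmark numbers requires external structure sets, docking poses and
large-scale pretraining, none of which this package attempts — its tests
verify the mathematics and the mechanics, not benchmark performance.
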