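# pthl — persistent topological hyperdigraph Laplacians for protein–ligand complexes

`pthl` turns a 3D protein–ligand complex into a fixed-shape *topological
sequence* that sequence models (transformers in particular) can consume, and
provides the evaluation machinery used to judge structure-based scoring
functions. It is aimed at structural bioinformaticians and method developers
working on binding-affinity prediction, docking-pose rescoring and virtual
screening.

## The method

A complex is reduced to its heavy atoms; the binding region keeps every
ligand atom plus all protein atoms within a cutoff η of any ligand atom
(presets: 20 Å and 12 Å). On a point set, the **Vietoris–Rips hyperdigraph**
at scale d contains one *directed hyperedge* — an ordered tuple of k+1
distinct vertices — for every vertex subset of diameter ≤ d, with the order
assigned by an orientation rule (by default descending Pauling
electronegativity, ties by atom index). On the Ω chain spaces

Ω_k = { x ∈ span(F_k) : ∂_k x ∈ span(F_{k−1}) },

with the alternating-sign boundary ∂_k(x_0,…,x_k) = Σ_i (−1)^i
(x_0,…,x̂_i,…,x_k), the **combinatorial hyperdigraph Laplacian** is

L_k = B_{k+1} B_{k+1}ᵀ + B_kᵀ B_k,

a symmetric PSD matrix whose zero-eigenvalue multiplicity is the Betti
number β_k (components, loops, cavities) and whose positive (non-harmonic)
spectrum encodes geometry. For nested scales a ≤ b the **persistent
Laplacian** Δ_k^{a,b} couples the two complexes; dim ker Δ_k^{a,b} is the
persistent Betti number.

The **element-specific embedding** restricts the protein–ligand
cross-distance matrix (same-origin pairs are set to +∞) to 11 protein
element sets × 13 ligand element sets = 143 combinations. Sweeping the
filtration grid (100 steps of 0.1 Å up to 10 Å, or 50 steps of 0.2 Å from
2 to 12 Å) and recording six L₀ statistics per combination — the zero
multiplicity and the mean / population SD / min / max / sum of the positive
eigenvalues — yields a tensor of shape **(T, 143, 6)**: the topological
sequence.

On top of that the package provides a configurable-scale transformer
(per-step 1×1 convolutional projection + trainable multiscale embedding,
multi-head attention encoder, smaller decoder; masked-reconstruction
pretraining and affinity-regression fine-tuning, with attention-score and
gradient-saliency read-outs), CASF-style metrics (PCC/RMSE with the 1.3633
kcal/mol conversion, high/low ranking power, docking success at 2 Å,
screening success rate and enrichment factor on S = S1·S2, consensus
averaging), and seeded synthetic-data generators so the entire pipeline is
testable offline.

## Worked example

```r
library(pthl)

cx     <- synthetic_complex(n_protein = 40, n_ligand = 10, seed = 7)
region <- extract_region(cx, cutoff = 12)
region
#> <complex_region> synthetic-7 @ 12 A: 40 protein + 10 ligand atoms

ts <- embed_complex(region, preset("small")$schedule)
ts
#> <topo_sequence> synthetic-7: 50 steps x 143 combos x 6 stats (cutoff 12 A, pthl-es-11x13-1)

ts$tensor[25, "protein:C|ligand:C", ]
#>   n_zero mean_pos   sd_pos  min_pos  max_pos  sum_pos
#>        1        2        0        2        2        2
```

At filtration step 25 (d = 7.0 Å) the carbon–carbon interaction graph of
this complex is a single connected pair: one zero eigenvalue (one
component) and one positive eigenvalue 2 — the K₂ spectrum {0, 2}. Sparse
combinations report all-zero rows; dense ones accumulate larger positive
spectra as d grows, and the zero multiplicity can only decrease along the
filtration (components only merge).

A thin command-line wrapper ships in `exec/`:

```sh
pthl region --protein P.pdb --ligand L.sdf --cutoff 12 --out region.json
pthl embed  --protein P.pdb --ligand L.sdf --preset small --out feats.json
pthl eval   --task docking --in poses.csv
```

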