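---
title: "Predicting drug-disease treatment relations with ssgc: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-disease treatment relations with ssgc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgc)
```

## The problem

Drug repositioning asks which approved drugs might treat diseases they were
never developed for. The only direct evidence is a sparse, positive-only
label matrix `Y` (m drugs by n diseases): known treatment pairs are 1,
everything else is merely *unobserved*. The working assumption is
guilt-by-association: similar drugs tend to treat similar diseases. `ssgc`
turns that assumption into a semi-supervised ranking method with three
ingredients:

1. **Three similarity layers.** Drug-drug and disease-disease similarities
   are computed from independent data sources: the *base* layer (Tanimoto
   similarity of 2D chemical fingerprints for drugs; a phenotype similarity
   matrix for diseases), the *gene* layer (kernel-cosine similarity of
   binary gene-association profiles measured under a gene-gene kernel), and
   the *treatment* layer (an exponential kernel on shortest-path distances
   in the bipartite graph of known treatments).
2. **An implicit pair graph.** A complete weighted graph over all
   `q = m * n` drug-disease pairs, with edge weight
   `W(s, t) = S_c(i, i') * S_d(j, j')` between pairs `s = (i, j)` and
   `t = (i', j')` and no self-loops. Predicting treatments becomes a graph
   cut: separate the pair nodes into a treatment and a non-treatment group.
3. **A relaxed graph-cut objective.** With `f` the (relaxed, real-valued)
   cut indicator over pairs,

   `Loss(f) = 1/2 f' Lbar f + mu/2 ||L f - y||^2 + xi/2 ||U f - p||^2`

   where `Lbar` is the symmetric-normalized pair-graph Laplacian, `L`/`U`
   select labeled/unlabeled pairs, `y` is the flattened label matrix and
   `p` a mechanistic prior (below). `mu > xi > 0` encodes that contradicting
   an observed treatment costs more than deviating from the prior.

The minimizer satisfies a linear system; the package solves it by the
fixed-point iteration

`f^(k+1) = alpha [ (mu - xi) U + S ] f^(k) + (1 - alpha) y_hat`

with `alpha = 1/(1 + mu)`, `y_hat = y + (xi/mu) p`, `f^(0) = y_hat`, and
`S` the normalized pair-graph adjacency. Because `S` has spectral radius at
most 1 and the unlabeled correction adds at most `mu - xi`, the iteration
map has spectral radius at most `(1 + mu - xi)/(1 + mu) < 1` whenever
`xi > 0`: convergence is guaranteed, and the map is non-negative, so all
scores stay non-negative.

## Never materializing the pair graph

`S` is `q x q`; at the scale of real registries (say 1186 drugs and 449
diseases, `q` above 500,000) it cannot be stored densely. But `W` is the
Kronecker product of `S_c` and `S_d` minus its diagonal, so with `F` the
m-by-n field view of `f` and `a_s = sum_i' S_c(i,i') sum_j' S_d(j,j') - 1`
the pair-node degrees, the operator application collapses to

`(S f) = S_c (F / A_hat) S_d / A_hat - F / A_tilde`,

where `A_hat` is the elementwise square root of the degree field and
`A_tilde = A_hat^2`. This is `apply_S()`: two registry-sized matrix
products, space `O(max(m^2, n^2))`. `dense_pair_operator()` and
`closed_form_solve()` build the explicit operator for small instances; the
test suite verifies the implicit and dense routes agree to 1e-10 and that
the iterative fixed point matches the dense linear solve.

The flattening convention is fixed once: pair `s` (0-based) is
`i0 * n + j0`, i.e. row-major over the drugs-by-diseases field, which is
exactly the indexing `kronecker(Sc, Sd)` realizes. Keeping a single
documented convention is what prevents off-by-one drift between the vector
and matrix views.

## The mechanistic prior

For an unlabeled pair the prior `P_ij` is the kernel-cosine similarity of
the drug's and disease's gene profiles under the gene-gene kernel: a drug
hitting genes associated with a disease is a plausible candidate even
before any propagation. Labeled pairs get prior 0 — the prior only speaks
where the data are silent. Entities with empty profiles get 0 (the
kernel-cosine is 0/0 there; zero is the conservative completion).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| gene kernel `a`, `b` | 0.3, 1.0 | amplitude/decay of `a*exp(-b*d)` on gene-graph hop distances |
| treatment kernel `a`, `b` | 0.9, 1.0 | same kernel on bipartite treatment-graph distances |
| thresholds | 0.1 / 0.01 / 0.14 / 0.01 / 0 / 0 | drug-structure, drug-gene-profile, phenotype, disease-gene-profile, treatment-layer cutoffs; sub-threshold similarities are mostly noise and are zeroed (entries *at* the threshold survive; the boundary rule must be fixed somewhere and keeping boundary mass is the less destructive choice) |
| fusion weights | `"auto"` | inverse-mean rule: each layer's weight is proportional to the reciprocal of its mean off-diagonal similarity, so `weight * mean` is equal across layers and no layer dominates just because its scores run large. The diagonal is excluded from the means because it is identically 1 and carries no layer information |
| `mu`, `xi` | 4, 0.67 | label-fit and prior-fit penalties; `mu > xi > 0` required |
| `tol`, `max_iter` | 1e-6, 1000 | convergence is declared when the max-abs update falls below `tol` (no criterion is canonical for this iteration; max-abs change is scale-free in the score units) |
| `degree_floor` | 1e-12 | isolated pair nodes (possible after aggressive thresholding) get their degree floored, with a warning, instead of aborting the run |
| `k_neighbors` | 5 | treatment-layer projection neighbourhood (below) |

Two deliberate non-interventions: the relaxation `f in [0,1]` is *not*
re-imposed by clipping — the fixed point of the unconstrained relaxed
problem is reported as-is, and can exceed 1 on pathological inputs; and the
final scores are not renormalized. Rankings are the primary output; a hard
cut at a score threshold is available via `cut_pairs()` but is not used by
any evaluation.

## Treatment-layer projection

The treatment layer only covers drugs and diseases with at least one known
treatment. To extend it to the full registries, an uncovered entity is
placed through its `k_neighbors` nearest covered neighbours in a reference
similarity space — here the raw base-layer matrix — taking the
reference-similarity-weighted average of the neighbours' treatment-layer
rows (pairs of uncovered entities use the double-weighted average). This
k-NN scheme is a documented, replaceable strategy: the idea of projecting
into a unified similarity space is standard, but no canonical construction
exists, so the package's choice is the simplest one that is exact on
covered entities and degrades gracefully (an entity with zero reference
similarity to every covered entity gets zero similarity to everything but
itself).

## The HGBI reduction

Setting `p = 0`, `mu = xi`, and keeping self-loops in the pair-graph
weights (so `W_ss = 1`, degrees keep the full Kronecker row sum, and the
operator drops its identity correction) turns the iteration into
HGBI-style propagation on the normalized Kronecker similarity network.
`hgbi_mode_solve()` exposes this as a named mode, which makes the ablation
claim — the graph-cut method differs from plain propagation exactly by the
prior and the self-loop removal — directly testable; the suite checks the
mode against an independently coded dense propagation.

## Positive-unlabeled evaluation

With only positive labels, the ROC construction treats observed pairs
above a score threshold as true positives and unobserved pairs above it as
false positives; thresholds sweep all unique score values and AUC is the
trapezoidal integral. On untied scores this equals the Mann-Whitney
ranking probability, which the tests verify by brute force. Reported
alongside: the count of held-out positives retrieved in the top percentile
of the ranking (ties broken lexicographically by drug then disease id, the
same rule the score writer uses), and the confusion matrix at a fixed 0.05
threshold for parity with single-threshold reporting conventions.

Cross-validation folds partition the known positives. Per fold, the
held-out positives are zeroed in the training labels, and everything
label-dependent — treatment-layer similarities, fusion weights, the prior
— is recomputed from training labels only; the base and gene layers do not
depend on labels and are fold-invariant. Not recomputing the treatment
layer would leak held-out labels through the similarity matrices; the
suite contains an explicit leakage test. Held-out positives are evaluated
against all never-observed pairs; training positives are excluded from the
ranking. Both pooled-over-folds and per-fold AUCs are reported, since
either convention is defensible.

## The synthetic benchmark

`generate_network()` plants a latent group structure ("therapeutic areas")
shared by drugs, diseases and genes: a stochastic-block-model gene graph,
gene profiles sampled preferentially from the own group, fingerprints
sharing group-owned bits, a phenotype matrix drawn around group-dependent
means, and treatments appearing only between group-matched pairs. All
randomness flows from one seed and the global RNG state is restored.

The defaults (60 drugs, 40 diseases, 200 genes, 4 groups) are calibrated
to emulate the regime the method is designed for, with the layers as
noisy, *complementary* views of the latent structure:

- The base layer is a deliberately weak group detector (64 fingerprint
  bits, own-group bits at rate 0.25, other bits at a quarter of that;
  phenotype means 0.35/0.15 under noise of sd 0.15). Used alone it ranks
  held-out positives at AUC near 0.79.
- The gene layer adds an independent view (association rates 0.12 within
  vs 0.01 between groups over 200 genes).
- The treatment layer is the strongest: group-matched drugs share treated
  diseases, so training labels make within-group drug pairs two hops apart.
- Treatment labels are sampled among group-matched pairs with probability
  increasing in the pair's gene-profile overlap (weight `0.1 + cosine`,
  marginal rate kept at `treat_rate = 0.3`). Treatments following target
  genes is the mechanistic rationale; methodologically it is what makes
  the prior informative *within* groups, so that adding the prior improves
  the ranking instead of merely adding noise — mirroring its role in the
  method. An earlier uniform-sampling design made every layer a detector
  of the same group signal, which pinned all configurations at the
  benchmark's PU-AUC ceiling (held-out positives are indistinguishable
  from group-matched unlabeled pairs under group information alone) and
  made layer fusion untestable.

Under these defaults the seed-averaged held-out AUC climbs monotonically
as layers are added — roughly 0.79 (base) to 0.84 (base+gene) to 0.90 (all
layers) to 0.92 (all layers + prior) — the qualitative pattern expected
when fusing complementary noisy evidence.

What the generator does *not* emulate: realistic pharmacology (no
chemistry behind the fingerprints), hub structure and degree heterogeneity
of real interactomes, biased ascertainment of known treatments (real label
matrices are enriched for well-studied drugs), and the sheer scale of real
registries. Passing the benchmark therefore shows the machinery is correct
and the fusion behaves as designed on data satisfying its assumptions; it
does not certify performance on any real dataset.

Problem sizes throughout the test suite (registries of tens of entities,
dense-oracle instances with `q` up to 100, ten benchmark seeds) are chosen
so the whole suite exercises every code path in seconds while the dense
oracles remain tractable.

## Numerical choices and degenerate inputs

- Similarity matrices are validated on construction: symmetric (small
  asymmetry is averaged away, large is an error), unit diagonal, values in
  [0, 1] with clipping only within 1e-9 of the bounds.
- The kernel diagonal is forced to 1 even though `a * exp(0) = a < 1`:
  self-similarity is definitional, not kernel-derived.
- Unreachable pairs have kernel similarity 0 (`exp(-Inf)`), the continuous
  limit of the kernel.
- Empty profiles and empty fingerprints yield 0 off-diagonal similarity
  and 1 self-similarity.
- Ranking ties are broken lexicographically by (drug id, disease id) in
  C-locale order, so rankings are identical across platforms and locales.
- Non-finite values during propagation abort with an error pointing at
  degenerate degrees rather than silently producing NaN rankings.

## Known limitations

- The inverse-mean fusion weights are recomputed from whatever matrices
  are being fused; with published layer means they land within a
  rounding-level distance of published weight settings but are not forced
  to match any externally printed values exactly.
- The treatment-layer projection is a stand-in for an unspecified
  construction; swapping in a different projection changes `S_tc`/`S_td`
  for uncovered entities only.
- Thresholds are applied before the layer means used for weighting are
  computed; the opposite order is defensible but not implemented.
- The dense solver refuses instances above `q = 2500` by default; it is an
  oracle, not a production path.
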