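---
title: "Inferring signaling crosstalk from multilink statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring signaling crosstalk from multilink statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Signaling pathways do not operate in isolation: a pathway can influence
another through direct molecular interactions or through transcriptional
regulation of its components. `crossmux` models both routes jointly by
stacking two kinds of networks over one gene universe as a multiplex
network:

* a **signaling layer** built from curated pathway maps (KGML) merged with a
  protein-protein interaction (PPI) scaffold, stored as eleven
  interaction-specific layers (activation, binding/association, compound,
  dephosphorylation, dissociation, indirect effect, inhibition,
  phosphorylation, ppi, state change, ubiquitination) plus one collapsed
  `KEGGPPI` layer holding every signaling/PPI edge once;
* a **regulatory layer** (`GRN`) of directed transcription factor → target
  edges, pruned to the signaling gene universe.

The unit of evidence is the **multilink**: for one node pair, the pair
`(S, R)` of edge states across the two layers, with `S ∈ [0, 11]` indexing
the signaling interaction type (0 = no signaling edge) and `R ∈ {-1, 0, 1}`
recording the regulatory edge and its direction relative to the signaling
edge. This gives `12 × 3 = 36` types, hashed to `3S + R + 1 ∈ [0, 35]` for
cheap tallying.

To read off relative direction from sparse matrices, each directed edge
fills its transposed position with `-1`; undirected edges fill both
positions with `+1`. A multilink observed as `(s, r)` at `(i, j)` and
`(-s, -r)` at `(j, i)` is one object and is counted once. Two bookkeeping
conventions follow from this signed fill:

* an undirected signaling edge coinciding with any regulatory edge
  contributes one count to `(S, +1)` *and* one to `(S, -1)` — the two
  equivalent representations stay exactly equal;
* an undirected signaling edge with no regulatory partner is corrected for
  double counting and contributes a single `(S, 0)` count.

Because one node pair can carry several signaling edge types, counting runs
separately per interaction-specific layer. Pure regulatory edges (`S = 0`)
are counted once against the collapsed `KEGGPPI` layer so they are not
multiply counted across the eleven layers; `(0, +1)` and `(0, -1)` are
indistinguishable (there is no signaling edge to orient against) and are
tallied once as `(0, 1)`. The `(0, 0)` count is obtained arithmetically
from the index-space size and occupancy, never by materializing the dense
complement.

## Null model and statistics

Observed counts are compared to a **degree-preserving null**: each layer is
randomized independently by pairwise edge swaps that exactly conserve in-
and out-degree sequences (the degree sequence for undirected edges), with
self-loops and duplicate edges rejected. Layers mix directed and
undirected edges (PPI edges are folded into every interaction-specific
layer to widen the rewiring space), so the two classes are rewired within
themselves against a shared per-pair occupancy set, preserving each edge's
directedness. The swap budget counts *attempts* (`Q` per edge of each
class, default 10 — a standard burn-in for swap-based randomization);
rejected attempts are not retried, so swap-poor layers such as stars pass
through unchanged rather than looping forever.

An ensemble stores `n_instances` randomized copies of every layer, built
from per-(layer, instance) child seeds derived from one master seed. Null
draws pair a signaling-layer instance with a regulatory-layer instance
through a deterministic allocation: draw `k` for context `c` maps to the
`(h(c) + k)`-th cell of the `n²` pairing grid, with `h` a stable string
hash. The same `(i_k, j_k)` index pair is used for every layer within one
draw, so each null observation comes from one coherent randomized
multilayer. Everything downstream is therefore exactly reproducible from
the master seed.

For each multilink type, with actual count `c_a` and null counts `c_r`:

* `z = (c_a - ⟨c_r⟩) / σ(c_r)`;
* `p_emp = #(c_r ≥ c_a) / N_rand` when `z > 0`, `#(c_r ≤ c_a) / N_rand`
  when `z < 0` (the tail is selected by the sign of `z`; although such
  p-values are often labeled two-tailed, the computed quantity is the
  sign-matched single tail, and we implement it as printed).

Edge cases are fixed as follows: `z = 0` exactly gives `p = 1` and is never
significant; a degenerate null (`σ = 0`) flags `sigma_zero`, with
`z = ±Inf` carrying the sign of `c_a - ⟨c_r⟩` (or undefined when `c_a`
equals every null count, in which case `p = 1`). No `1/N_rand` floor is
applied; `p = 0` is reportable and means "below the resolution of the
ensemble". `N_rand = 100` by default and is user-adjustable; z-scores are
invariant under common rescaling of the counts, so the undirected
double-count bookkeeping cannot bias them.

## From multilinks to crosstalk

For an ordered pathway pair (A, B), coincident signaling/regulatory edges
between the two pathways — multilinks of type `(S, ±1)` — are the crosstalk
proxies. Two candidate-position constructions are provided:

* **between**: all ordered positions `(a, b)` with `a` exclusive to A and
  `b` exclusive to B, plus transposes. Within-pathway edges and edges
  touching genes common to both pathways are excluded by construction, so
  shared components cannot masquerade as crosstalk.
* **shortest**: edges on shortest directed paths over the collapsed
  signaling layer from each exclusive gene of A to each exclusive gene of
  B, where only *intermediary* nodes (outside A ∪ B) may appear inside a
  path. The search runs on a restricted graph view in which source-side
  exclusive genes cannot be entered and target-side exclusive genes cannot
  be left, so every returned path is intermediary by construction (and tie
  resolution among equal-length paths cannot leak a within-pathway node).
  The `sp` threshold caps the number of intermediary nodes per path
  (`sp = 1` keeps `a → x → b` only; `NULL` places no cap); candidate sets
  grow monotonically with `sp`. For the null, candidate positions are
  re-derived on each randomized collapsed-layer instance, so the null
  experiences the same operations as the data.

A type is significantly over-represented when `p_emp ≤ 0.05` (boundary
inclusive) and `z > 0`. Pure regulatory `(0, 1)` multilinks count as
proxies by default (they are significant regulatory edges connecting the
pair) and can be excluded via `include_zero = FALSE`. Each pair is
summarized by `n_sig` (number of significant `(S, ±1)` types), `p̃` (best
p-value) and `z̃` (best finite z), taken independently over the types with
nonzero counts, and combined into

```
score = 1000 · n_sig − log10(p̃ + 0.001) · z̃       (σ ≠ 0 for the best type)
score = 1000 · n_sig − log10(p̃ + 0.001)            (σ = 0 for the best type)
```

The `1000` weight makes `n_sig` dominate whenever `|log10(p̃ + 0.001)·z̃| <
1000`, encoding the three-key priority (most significant types, then lowest
p, then highest z); the `0.001` offset keeps the logarithm finite at
`p = 0`. Pairs with no `(S, ±1)` multilink on their candidate positions are
*undetected*: they carry no score and are listed after all ranked pairs,
with exact score ties broken lexicographically for determinism. A
leave-one-layer-out analysis re-scores pairs ignoring one signaling layer's
types; the PPI layer is not eligible because its edges underlie every
interaction-specific layer and the shortest-path connectivity.

## Baselines and evaluation

Four comparison rankings are included: node overlap and edge overlap
(two-tailed Fisher exact tests with Benjamini-Hochberg adjustment, ranked
by FDR; the edge universe defaults to the `N(N−1)` ordered positions over
the union gene set, configurable to unordered), direct inter-pathway edge
counts against the same rewired ensemble, and a receptor→TF K-shortest-path
statistic (Yen's algorithm with deterministic length-then-lexicographic
ordering). The path statistic `chi_fn` is a plug-in; the shipped default
simply counts paths and is deliberately labeled a stand-in, not a
literature formula. Overlap tests are symmetric, so both orderings of a
pair receive the same value and all methods rank the same ordered-pair
universe.

Rankings are scored against truth labels with ROC and precision-recall
areas. AUROC is computed as the Mann-Whitney concordance of the ranking;
AUPRC as average precision. Deterministic mode uses only detected labeled
pairs; stochastic mode covers the full universe by assigning undetected
pairs random distinct ranks below the last detected rank, repeating the
shuffle (default 1000 times, seeded) and reporting mean ± sd. With no
undetected pairs the stochastic areas collapse to the deterministic values
with zero standard deviation.

## Synthetic data: what it emulates and what it does not

All tests and the acceptance script run on generated data; nothing is
downloaded. The generator (`gen_multilayer()`) emulates the statistical
shape of the real inputs:

* pathways are random recursive trees over partially overlapping gene sets
  (guaranteeing connectedness) decorated with extra typed arcs — curated
  pathway maps are sparse and connected, so default per-type densities stay
  at or below 0.015;
* the PPI scaffold is an undirected G(n, p) over the whole universe;
* the regulatory layer is a directed bipartite sample with 10% of genes
  designated TFs.

Defaults define the study conditions used throughout: 200 genes, 5
pathways of 20–30 genes, 10% adjacent-pathway overlap, PPI and regulatory
densities of 0.01, seedable end to end. `plant_crosstalk()` inserts known
signal: coincident signaling/regulatory edge pairs between genes exclusive
to one pathway pair (and to no other pathway, keeping the planting local),
on positions previously free of edges so subset counts rise by exactly the
planted number.

The generator does **not** reproduce empirical degree distributions, hub
structure, TF autoregulation, or the biases of literature curation.
Passing tests therefore demonstrate the correctness and calibration of the
machinery — exact counting, exact degree preservation, planted-signal
recovery, near-nominal false-positive rates — not biological performance
on real KEGG/PPI/GRN inputs, which depends on data properties the
synthetic model deliberately omits.

One consequence of the modular synthetic structure is worth noting: the
degree-preserving null *spreads* the dense within-pathway edges across the
whole network, so raw between-pathway edge counts on unplanted data tend to
sit below their null expectation. Multilink statistics are unaffected
(they measure cross-layer coincidence, and the layers are randomized
independently), but the direct-edge baseline needs a planted surplus large
enough to clear that baseline — visible in its tests.

## Numerical and design choices

* **Reciprocal directed edges** of one type on one pair cannot be
  represented by the `{-1, 0, +1}` signed fill; they collapse to the
  symmetric `+1/+1` representation, preserving presence at the cost of
  orientation.
* **within_group edges** (complete graphs over disaggregated KGML gene
  groups) map to the binding/association layer by default — group
  co-membership is a physical-association statement — via the configurable
  `type_index`.
* **KGML dialect**: relations with several subtypes yield one record per
  subtype; compound-mediated relations are typed `compound` and treated as
  directed; subtype-less or unrecognized relations become `unknown` and are
  dropped at refinement; multi-identifier entry names use their first
  token; relations referencing a group expand to all members.
* **Supersession**: where a pathway interaction and a PPI edge coincide on
  one pair, the typed pathway edge wins and no `ppi` record is added;
  refinement is idempotent.
* **Empty subsets** (no exclusive genes, no retained paths, all-zero
  counts) mark a pair undetected rather than erroring, and undetected pairs
  are excluded from deterministic ranking.
* **Problem sizes** in the test suite and acceptance script (10 ensemble
  instances giving the 100 pairings consumed at `N_rand = 100`; 20
  replicates for power and calibration; 100-seed oracle sweeps at up to 12
  nodes) were chosen as the smallest sizes at which each property is
  meaningfully exercised; ensemble size and `N_rand` are user parameters.

## Limitations

* The signed-fill representation cannot distinguish reciprocal directed
  edges from undirected ones; direction-of-influence claims rest only on
  the `R` sign convention.
* Significance is ensemble-based only; no parametric null is offered, and
  p-values are quantized at `1/N_rand`.
* The shortest method takes one shortest path per ordered gene pair (the
  restricted-search construction makes its edge set deterministic), not
  all co-optimal paths.
* The χ-style path statistic is a plug-in contract with a trivial default;
  users wanting a specific literature statistic must supply it.
* Identifier handling is opaque-string: no symbol/ID conversion is
  performed or validated.
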