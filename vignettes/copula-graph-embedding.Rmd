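---
title: "Copula cell graphs and graph-convolutional embeddings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copula cell graphs and graph-convolutional embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scCopulaGCN)
```

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, what the simulator does and does
not emulate, the numerical conventions, and the design decisions that were
genuinely open.

## The model, stage by stage

### Preprocessing

The raw input is a cells x genes count matrix. Cells expressing strictly
more than `min_genes_per_cell` genes are kept; then genes whose count
exceeds `min_count` in at least `min_cell_frac` of the retained cells are
kept (cells first, so gene frequencies refer to the cells that will
actually be analysed; the filters are idempotent). Counts are rescaled to
the median library size and log2(1 + x) transformed.

Two things are deliberate here. First, the strict/inclusive reading of the
thresholds ("more than", "greater than", "at least") is part of the
contract and is what the tests pin down. Second, normalization is a plain
median-library-size scaling: the downstream dependence measure uses ranks
only, so any per-cell monotone transform gives identical results, and an
elaborate variance-stabilizing transform would change nothing but the
k-means geometry at the very end. Externally normalized matrices can be
passed through with `method = "none"`.

The defaults (`min_genes_per_cell = 1000`, `min_count = 5`,
`min_cell_frac = 0.10`) are calibrated for whole-transcriptome data with
~20k genes. On a 2000-gene simulated panel the same fractions of the gene
space correspond to far smaller absolute thresholds; the end-to-end tests
therefore run with `min_genes_per_cell = 100`, `min_count = 1`,
`min_cell_frac = 0.05`, chosen once so that a clear majority of the panel
(> 2^10 genes) survives and hashing at the default 10 bits stays valid.

### LSH gene sampling

Genes are points in cell space. Each of `n_bits` (default 10) random
standard-normal hyperplanes contributes one sign bit, so two genes collide
in a bucket with probability `(1 - angle/pi)^n_bits` — a cosine-similarity
filter. Within each bucket every gene finds its `n_neighbors = 5` nearest
co-members by cosine distance; a greedy sweep in original gene order then
keeps a visited gene and discards its neighbours (a gene that was already
discarded is skipped but still discards its own neighbours). One pass
(`iterations = 1` by default) removes near-duplicate genes while touching
every region of the correlation structure; passes can be repeated
recursively, and each later selection is a subset of the earlier one.

Design notes:

- The hash family is a single table of `n_bits` sign bits. We read the
  requirement "more genes than 2^bits" as defining bits-per-code (at most
  1024 buckets at the default), not a bucket count; multi-table or
  multi-probe LSH is out of scope.
- Tie-breaks in the within-bucket kNN are by ascending gene index, which
  makes the whole sampler deterministic given the seed.
- All-zero gene profiles have no direction; they are treated as maximally
  distant (cosine distance 1) and reported.
- The bucket geometry only helps when correlated genes actually co-hash.
  With very small buckets (many bits relative to the gene count) the
  greedy step degenerates to "one gene per bucket" and coverage of the
  gene modules suffers; this is why `n_bits` must be chosen against the
  panel size, and why `sample_features()` refuses to hash when the gene
  count does not exceed `2^n_bits`.

### The copula correlation (Ccor)

Dependence between two cells over the sampled genes is Kendall `tau_b`:
the probability of concordance minus discordance, with tie corrections.
Working through ranks makes the measure a property of the pair's copula
alone — any strictly monotone per-cell transform leaves it unchanged. The
Clayton family supplies the parametric backbone: generator
`phi(x) = (x^-theta - 1)/theta` on `theta in [-1, inf) \ {0}`, CDF
`C(u,v) = max(u^-theta + v^-theta - 1, 0)^(-1/theta)`, and the closed-form
relation `tau = theta/(theta + 2)` (verified in the tests against numeric
evaluation of the concordance integral `4 E[C(U,V)] - 1`).

One modelling point deserves honesty: with a single *fixed* Clayton
parameter (e.g. `theta = -0.5`), the copula-implied tau is a
data-independent constant (-1/3), which cannot rank cell pairs. The
package therefore uses the *empirical* tau of each pair as the Ccor score
(`mode = "empirical_tau"`, the default), and offers `mode = "clayton"` as
a diagnostic that round-trips each pairwise tau through the Clayton
parameter (`theta = 2 tau/(1 - tau)`) and back — a parity check of the
copula model on the Clayton-attainable range `tau in (-1/3, 1)`, not a
different estimator.

The fast tau path is Knight's merge-sort algorithm (O(n log n), compiled);
an O(n^2) brute-force reference (`kendall_tau_ref()`) ships in the package
and the suite requires exact agreement between the two on hundreds of
random tied inputs.

### The cell graph

Each cell ranks all others by descending Ccor (ties by ascending index)
and keeps the top `graph_k = 5`; the undirected union of these directed
choices is the graph. Union graphs of this kind have between `k n / 2` and
`k n` edges; at `k = 5` real cell graphs sit near 5 edges per node, random
similarity matrices near 3. `k = 5` is the default because it matches the
edge/node ratios observed on real single-cell networks of this
construction (≈ 4.9–5.1).

### The graph autoencoder

Encoder: three propagation steps
`H^(l+1) = sigma(D^-1/2 (A + I) D^-1/2 H^(l) W^(l))` with ReLU after
layers 1 and 2 and a linear third layer; output dims 256, 128, 128. The
symmetric normalization keeps the propagation operator's spectrum in
[-1, 1] (checked spectrally in the tests); the self-loop guarantees
isolated nodes a degree. Node features are the identity, so the first
weight matrix acts as a free per-node embedding and the n x n input is
never materialized. Two nodes with identical neighbourhoods and features
receive identical embeddings; the encoder is permutation-equivariant.

Decoder and loss: `P(edge) = sigmoid(z_i' z_j)` against the training
adjacency plus self-loops, every entry of the n x n matrix contributing,
with the positive class reweighted by `(n^2 - 2|E|)/(2|E|)` and the whole
loss scaled by `n^2/(2(n^2 - 2|E|))` (the usual graph-autoencoder
convention). Optimization is full-batch Adam, `lr = 0.001`, 50 epochs,
dropout 0.1 on hidden activations, no early stopping. Gradients are
hand-derived and verified against central differences to 1e-10 in the
development tests; the loss trajectory is bitwise reproducible given the
seed.

Edge split: 8:1:1 train/validation/test on the undirected edges, drawing
held-out edges only where removal leaves both endpoints another edge, so
every node stays in the training graph. Negatives for the ROC/AP reports
are uniform non-edges, disjoint between validation and test. The embedding
used downstream is the evaluation-mode (dropout-off) output of the third
layer — the second and third layers are both 128-d, and the third is the
one the decoder was trained on.

### Clustering and evaluation

- `kmeans_cluster()`: k-means++ seeding, Lloyd iterations, best total
  within-cluster sum of squares over 10 restarts. K comes from the known
  class count in benchmarks; without labels a silhouette-maximizing sweep
  over K in 2..15 is used.
- `ari()`: pair-counting adjusted Rand index (hand impl., cross-checked).
- `silhouette_width()`: mean silhouette via the `cluster` package.
- `topology_kl()`: the k-NN graph of the original space is the ground
  truth P over all cell pairs; the k-NN graph of the embedding is the
  prediction Q. We use the exact-match convention: pairs on which the two
  graphs agree contribute zero, every mismatched pair contributes
  `log(1/epsilon)` (`epsilon = 1e-4`), so the score is zero precisely when
  the graphs coincide and otherwise counts disagreements on a log scale.
  (The alternative of epsilon-smoothing *all* pairs adds a constant
  `~ epsilon x n^2/2` floor that obscures the zero point; we prefer the
  convention under which "KL = 0 iff identical" is exact.) For n > 2000
  the non-edges are uniformly subsampled and the negative term rescaled.
- `distance_preservation_tau()`: Kendall tau between the upper triangles
  of the two Euclidean distance matrices; exactly 1 for any rigid
  transform plus uniform scaling. By default distances in the original
  space use all post-filter genes.
- `find_markers()`: per cluster, two-sided Wilcoxon rank-sum
  (cluster-vs-rest) per gene via the tie-corrected normal approximation
  without continuity correction, raw p < 0.05, ranked by the signed z
  statistic, top 50. Benjamini–Hochberg is available (`adjust = "BH"`)
  but off by default to match the common marker-calling convention.

## The simulator

`simulate_counts()` draws: gene baseline means from Gamma(0.6, 0.3)
(splatter-like defaults); per-group DE gene sets of proportion `de_prop`
with log fold-changes of magnitude LogNormal(log(de_logfc_scale), 0.4) and
random sign; per-cell library factors LogNormal(0, 0.25) (a relative
multiplier — the pipeline normalizes library size away, so an absolute
scale would add nothing); Poisson counts around the scaled means; and
technical dropout as independent Bernoulli zeroing with probability
logistic in -log(mean), whose midpoint is solved by bisection so that the
*excess* zero fraction equals `dropout_rate` in expectation. The
benchmark series (`simulate_dataset_series()`) fixes the four standard
designs: 500/2, 1000/3, 1500/4, 2000/5 cells/groups at 2000 genes, equal
group probabilities, 40% DE, 0.2 dropout.

What the simulator does *not* emulate: negative-binomial overdispersion
beyond the lognormal-mixed Poisson, batch effects, trajectories,
cell-cycle structure, gene-gene co-expression within groups beyond the
planted DE signal, and realistic gene-mean/dropout coupling estimated from
real data. Passing tests on these simulations therefore demonstrates the
pipeline's mechanics and its ability to recover clean planted structure,
not performance on any real tissue.

Problem sizes in the tests — 500 cells x 2000 genes for the end-to-end
benchmark (5 seeds), 200-node graphs for link prediction, 1e4 draws for
the copula sampling check — were chosen as the smallest sizes at which the
respective statistics are stable.

## Numerical conventions

- Neighbour ranking ties (Ccor, cosine kNN, k-NN graphs): ascending index.
- Constant vectors make tau undefined: the functions warn and return 0.
- `clayton_cdf()` clamps `u^-theta + v^-theta - 1` at zero (the
  pseudo-inverse of the generator), which matters for `theta < 0`;
  `theta = 0` returns the independence copula `uv`.
- The Clayton sampler inverts the conditional CDF,
  `v = ((w^(-theta/(1+theta)) - 1) u^-theta + 1)^(-1/theta)`.
- A single pipeline seed fans out per-stage (`seed + 1000 x stage`), so
  one integer reproduces every artifact byte-identically.
- Training aborts with the epoch and learning rate if the loss becomes
  non-finite.

## Known limitations

- **Graph embeddings are not metric embeddings.** The autoencoder sees
  only the 5-NN graph; it is trained to reconstruct adjacency, and with
  strong cluster structure it contracts each cluster towards a point.
  Consequently its distance-matrix Kendall tau against the original space
  is moderate (~0.3 on the clean two-group benchmark), and a plain random
  Gaussian projection to the same 128 dimensions — a near-isometry by the
  Johnson–Lindenstrauss lemma, tau ~0.7 — preserves *distances* better,
  while being useless for denoising or clustering. Distance preservation
  and cluster recovery are different objectives; this package optimizes
  the latter and reports both scores.
- **Link-prediction ROC is ceiling-limited by the graph's information
  content.** On a two-block partition with within/between edge densities
  0.3/0.02, held-out edges are statistically exchangeable with the 40% of
  non-edges that lie within blocks, capping any predictor's test ROC near
  0.76 — and the trained model sits at that ceiling, matching the ROC of
  an oracle given the true blocks. Denser or more locally structured
  graphs (e.g. the near-clique neighbourhoods of real cell graphs, or the
  pipeline's own Ccor graphs, where held-out edges have strong
  common-neighbour signal) support ROC well above 0.85.
- The topology score counts k-NN disagreements; within-cluster neighbour
  identity is largely arbitrary once clusters collapse, so the score
  mostly reflects cluster-level agreement at small k.
- Exact O(n^2) pair enumeration in `ccor_matrix()` and `topology_kl()` is
  practical to a few thousand cells on one core; beyond that, subsample
  negatives (`negative_subsample`) and expect the Ccor stage to dominate
  runtime.
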