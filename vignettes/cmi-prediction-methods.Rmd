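---
title: "Predicting circRNA-miRNA interactions: models, choices and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting circRNA-miRNA interactions: models, choices and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circular RNAs (circRNAs) act as miRNA "sponges": by presenting binding sites
complementary to a miRNA's seed region they sequester it and de-repress its
downstream targets. Catalogues of experimentally supported circRNA-miRNA
interactions (CMIs) are sparse — a few thousand pairs over thousands of
molecules — so computational ranking of candidate pairs is used to prioritize
wet-lab validation. `cmipred` implements a multi-modal link-prediction
pipeline for this task: sequence-derived features, network-derived features,
learned attention-based fusion, and a neural link classifier, together with
the evaluation machinery (negative sampling, stratified cross-validation,
class-imbalance stress tests) and a fully synthetic, mechanistically grounded
benchmark generator.

## Pipeline overview

Given circRNA records, miRNA records and a positive pair table, the pipeline
forms the binary association matrix $A \in \{0,1\}^{n_c \times n_m}$ and
computes, for every candidate pair $(c, m)$:

1. **Sequence codes.** Each sequence is decomposed into overlapping $k$-mers
   (default $k = 3$) and a shared token-embedding space is trained over the
   union of circRNA and miRNA token streams by skip-gram with negative
   sampling: for each (center, context) token pair within a window of radius
   $c$, maximize $\log \sigma(\langle v'_{ctx}, v_{cen}\rangle) + \sum_{i=1}^{k_{neg}}
   \mathbb{E}_{w \sim P_n}[\log \sigma(-\langle v'_w, v_{cen}\rangle)]$, with
   $P_n$ the unigram distribution raised to 0.75. A sequence's embedding is
   the mean of the input vectors of its first $\min(T, P)$ tokens
   ($P = 64$). Each molecule class's pooled embeddings are then compressed by
   its own stacked autoencoder (sigmoid funnel 256-128-64 with tied decoder
   weights, greedy layer-wise training, mean-squared reconstruction loss) to
   a 64-dimensional code.
2. **Structural embeddings.** The bipartite graph
   $S = \begin{bmatrix}0 & A\\ A^\top & 0\end{bmatrix}$ is embedded with
   GraRep: for orders $k = 1..K$ compute the $k$-step transition matrix
   $A_g^k$ ($A_g = D^{-1}S$), the shifted positive log matrix
   $X^k = \max\!\big(\log\frac{A_g^k(i,j)}{\Gamma_k(j)} - \log\frac{\lambda}{|E|},\, 0\big)$
   with $\Gamma_k(j)$ the $j$-th **column** sum, then a rank-$d_k$ truncated
   SVD $X^k \approx U \Sigma V^\top$ and node factors $H^k = U\Sigma^{1/2}$.
   The per-node embedding is the concatenation $[H^1, \dots, H^K]$ of
   dimension $H = K \cdot d_k$ (default $4 \times 16 = 64$).
3. **Attention fusion.** Stage-1 attention re-weights each molecule's
   sequence code with per-sample softmax weights
   $a = \mathrm{softmax}(xW + b)$ over feature positions ($\sum_j a_j = 1$);
   the attended code is concatenated with the molecule's structural vector;
   stage-2 attention re-weights each concatenation; the two branches join
   into the pair vector of dimension $2(64 + H)$, which is z-scored with
   statistics frozen on the training pairs.
4. **Classification.** A one-hidden-layer MLP (100 ReLU units, sigmoid
   output) is trained jointly with the four attention stages by Adam on
   binary cross-entropy plus $10^{-4}$ L2 on all weight matrices.

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `k` | 3 | k-mer length; 64-token vocabulary keeps co-occurrence dense at desk scale |
| `dim` (D) | 64 | token/sequence embedding width, matching the downstream 64-d codes |
| `window`, `k_neg` | 5, 5 | standard skip-gram context radius and negative-sample count |
| `P` | 64 | pooling cap: tokens averaged per sequence |
| `sae_sizes` | 256,128,64 | published funnel; bottleneck feeds fusion |
| `sae_epochs`, `sae_lr` | 20, 1e-3 | published SAE budget (see the capacity note below) |
| `K`, `d_k` | 4, 16 | GraRep orders and rank; $H = 64$ aligns with the fusion dimension hints |
| `lambda_neg` | 1 | shift constant in the positive log matrix (standard choice) |
| `hidden`, `l2` | 100, 1e-4 | published classifier width and regularization |
| `iterations` | 5000 | optimizer steps; read as mini-batch steps of 128 (the batch size the method fixes); full-batch available via `batch_size = Inf` |
| `negative_ratio` | 1 | sampled negatives per positive |
| `leakage_safe` | TRUE | drop each fold's test positives from the embedding graph |

## The synthetic benchmark

`generate_cmi_dataset()` emulates the sponge mechanism directly: miRNAs are
uniform random RNA (20-24 nt); circRNAs are uniform random backbones
(300-1500 nt); positive cells are drawn at `target_density` (default 0.05);
each positive's circRNA receives the reverse complement of its partner
miRNA's seed (positions 2-8) at a random position, with motifs for the same
circRNA placed in disjoint windows; labels are then flipped with probability
`label_noise`. At zero noise a pair is positive iff the motif was planted;
chance 7-mer occurrences (rate $\approx 1-(1-4^{-7})^{L-6}$, about 5% for a
900-nt backbone) are deliberately left in as realistic label ambiguity, and
`motif_oracle()` measures the resulting Bayes ceiling. The generator emits
exactly the FASTA/TSV formats the ingestion functions consume.

What it does *not* emulate: thermodynamics and secondary structure of
binding, non-seed pairing, expression context, and the heavy-tailed degree
distributions of curated interaction databases. Passing the benchmark shows
the pipeline's plumbing and learning dynamics are sound, not that real-data
accuracy will match.

## Evaluation protocol and the leakage question

Cross-validation is canonical stratified 5-fold (20% test per fold); within
each training pool 1/8 (10% of all pairs) is held out for early stopping.
A three-way 80/10/10 split cannot coexist with exact 5-fold rotation, and we
chose the 5-fold reading; the validation share matches the published 10%.
Negatives are drawn uniformly from unobserved cells, disjoint from positives.

Sequence embeddings and the two autoencoders never see labels, so they are
fitted once per dataset; refitting them per fold would reproduce identical
results at five times the cost. The graph embedding *does* see the label
structure, and here a protocol choice is decisive:

* `leakage_safe = TRUE` (default) rebuilds the embedding per fold with that
  fold's test positives removed, so structural features cannot encode the
  held-out answers.
* `leakage_safe = FALSE` embeds the full matrix once — the protocol that
  published CMI pipelines of this family implicitly use.

On the synthetic benchmark the gap is dramatic and diagnostic. With the full
matrix embedded the pipeline reaches cross-validated AUC $\approx 0.94$;
with leakage control the AUC collapses to $\approx 0.53$. Both numbers are
correct answers to different questions. The planted rule is a pairwise
sequence match: one 7-mer inside a 300-1500 nt backbone shifts the pooled
$k$-mer composition by well under one standard deviation of its natural
variation, so composition-pooled sequence features carry almost no signal;
and once test edges are removed, the remaining bipartite graph is
(by construction) uniform random and carries none either. The full-matrix
protocol instead lets the factorized graph encode exactly the cells being
predicted — transductive recall of known edges, not generalization. The
package computes both numbers and reports them side by side; a
permuted-label null (labels shuffled after feature construction) sits at
AUC $\approx 0.5$ under either protocol, confirming the classifier invents
no signal on its own.

## Numerical choices

* **Shifted log normalization.** The column-sum normalization
  $\Gamma_k(j) = \sum_p A_g^k(p,j)$ is used. A row-sum in that position
  (one printed variant of the formula) is identically 1 for a row-stochastic
  matrix and would collapse the PPMI structure to
  $\log A^k_{i,j} - \log\beta$; the column sum restores the
  "surprise relative to the context's popularity" semantics of GraRep.
* **Zero cells and isolated nodes.** $A^k_{i,j}=0$ maps conceptually to
  $-\infty$ and is clamped to 0; isolated nodes get zero transition rows and
  zero embeddings with a warning, never NaN.
* **SVD determinism.** Each singular vector pair's sign is fixed by making
  the largest-magnitude component of the left vector positive, so repeated
  runs are bit-identical. On graphs smaller than the requested rank the
  factors are zero-padded so the embedding dimension is always $K d_k$.
* **Skip-gram determinism.** The trainer is single-threaded C++ with an
  internal xorshift PRNG seeded from the user seed: bitwise-reproducible,
  independent of R's RNG state. The context window is fixed (no random
  window shrinking) to keep the determinism contract simple.
* **SAE input scaling.** Features are min-max scaled to $[0,1]$ per feature
  (a sigmoid decoder cannot reconstruct unbounded values); the scaler is
  part of the model. The decoder bias starts at the logit of each feature's
  mean so the initial reconstruction is already the per-feature-mean
  baseline. With the published budget (20 epochs at lr $10^{-3}$) the SAE is
  a mild compressor rather than a converged one; the capacity test in the
  acceptance suite trains the same architecture to convergence (100 epochs,
  patience 10) to verify the funnel can represent rank-limited data, while
  the pipeline default keeps the published budget.
* **"5000 iterations".** Read as 5000 optimizer steps on mini-batches of
  128 (the batch size fixed elsewhere in the method); with early stopping
  (patience 200 steps on the validation slice, best weights restored)
  training typically ends far earlier.
* **Standardization under joint training.** Fusion statistics are fitted
  once on the training pairs with the freshly initialized attention stages
  and then frozen, so the affine map is constant throughout optimization and
  identical across train/validation/test.
* **Undefined metrics.** Ratios with zero denominators (e.g. precision with
  no positive calls) are reported as `NA` with a warning, never silently 0.

## Design decisions on open points

* **Pooling** of token vectors into a sequence vector is unstated in the
  source method; mean pooling over at most $P$ tokens is our choice, and the
  cap is the dominant information bottleneck for long circRNAs.
* **Per-pair structural features**: the circRNA branch concatenates the
  circRNA's node vector, the miRNA branch the miRNA's, giving the
  $2(64+H)$-dimensional fused vector; Hadamard or averaged alternatives
  would change the dimension identity.
* **Separate attention parameters** for the circ and mi branches at both
  stages (four heads); sharing is not implied anywhere.
* **Attention training**: no separate attention objective exists; the stages
  receive gradients through the fused classifier loss.
* **Static-ratio fusion** (`fusion_mode = "static"`) reproduces the
  fixed-proportion baseline (e.g. 2:2:1) used in ablations: uniform stage-1
  weights and fixed stage-2 block totals.
* **SAE outputs**: only the 64-d bottleneck feeds fusion. The
  "high-order plus low-order" narrative never specifies how shallower codes
  would enter the fusion equations, whose dimensions admit a single
  sequence matrix per molecule; intermediate codes remain inspectable via
  `sae_encode(depth =)`.

## Problem sizes

The bundled study conditions are 300 circRNAs x 100 miRNAs at density 0.05
(1500 designated positives, 5% label noise, 1:1 negatives) for the
cross-validated benchmark, and a 150 x 50 version for the imbalance harness
(ratios 1:1 through 1:5), with a reduced iteration budget there since the
harness checks report shape and count arithmetic rather than accuracy. A
full benchmark run (embedding, two SAEs, five folds of GraRep + training,
plus a permutation null) completes in a few minutes on one CPU.

## Known limitations

* Transductive only: molecules absent from the training graph get no
  structural embedding, and sequence codes alone carry little signal under
  mean pooling.
* Mean pooling over the first $P$ tokens discards most of a long circRNA;
  this is faithful to the source method but is the main reason sequence
  features cannot detect a single planted site.
* The published-protocol evaluation (full-graph embedding) measures
  transductive edge recall, not prospective generalization — see the
  leakage section; for honest prospective estimates keep
  `leakage_safe = TRUE`.
* Negative sampling treats all unobserved cells as negatives; some are
  merely untested interactions.
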