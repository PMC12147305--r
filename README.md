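# cmipred

Prediction of circRNA–miRNA interactions (CMIs) from sequence and network
structure.

Circular RNAs regulate gene expression by sponging miRNAs: a circRNA that
carries sites complementary to a miRNA's seed region (positions 2–8)
sequesters that miRNA. Experimentally validated CMI catalogues are small and
sparse, so ranking candidate pairs computationally is the practical way to
prioritize bench validation. `cmipred` is for computational biologists who
want a tested, reproducible implementation of a multi-modal CMI
link-prediction pipeline — and for methodologists who want to measure how
much of such a pipeline's reported accuracy survives leakage-safe
evaluation.

## The model

For the association matrix $A \in \{0,1\}^{n_c \times n_m}$ and a candidate
pair $(c, m)$ the pipeline computes:

* **Sequence codes** — overlapping $k$-mers (default $k=3$) embedded by
  skip-gram with negative sampling over a shared circRNA+miRNA corpus
  (maximize $\log\sigma(\langle v'_{ctx}, v_{cen}\rangle)$ plus $k_{neg}$
  smoothed-unigram noise terms), mean-pooled over the first $P = 64$ tokens,
  then compressed per molecule class by a stacked autoencoder
  (sigmoid funnel 256–128–64, tied decoder weights, greedy layer-wise
  training) to 64-d codes.
* **Structural embeddings** — GraRep on the bipartite graph
  $S = [[0, A], [A^\top, 0]]$: for orders $k = 1..K$, the shifted positive
  log matrix
  $X^k_{ij} = \max(\log(A_g^k(i,j)/\Gamma_k(j)) - \log(\lambda/|E|),\ 0)$
  of the $k$-step transition matrix $A_g = D^{-1}S$ is factorized by
  truncated SVD, $H^k = U\Sigma^{1/2}$, concatenated to $H = K d_k = 64$
  dimensions per node.
* **Attention fusion** — two stages of per-sample softmax attention over
  feature positions (weights positive, summing to 1) re-weight each
  molecule's sequence code, then each [code, structure] concatenation; the
  two branches join into a $2(64+H)$-d pair vector, z-scored with
  training-set statistics.
* **Classifier** — an MLP (100 ReLU units, sigmoid output) trained jointly
  with the attention stages by Adam on binary cross-entropy + $10^{-4}$ L2.

Evaluation: uniform negative sampling from unobserved cells, stratified
5-fold cross-validation with a held-out early-stopping slice, the
Acc/Sen/Spe/Pre/F1/MCC confusion suite plus rank-based AUC and step-curve
AUPR, a 1:1…1:5 class-imbalance harness, and a permutation null. A seeded
synthetic generator plants the seed-complementarity mechanism itself
(reverse complement of each positive miRNA's seed embedded in the partner
circRNA), so every stage is testable without any download.

## Worked example

```r
library(cmipred)

ds <- generate_cmi_dataset(
  synthetic_config(n_circ = 80, n_mi = 30, target_density = 0.06,
                   label_noise = 0.05),
  seed = 42)

cfg <- cmi_config(iterations = 1500L, leakage_safe = FALSE)
cv <- cross_validate(ds, cfg, seed = 1)
round(cv$mean, 3)
#>   Acc   Sen   Spe   Pre    F1   MCC   AUC  AUPR
#> 0.882 0.900 0.864 0.871 0.885 0.765 0.942 0.932
round(cv$attention_summary, 3)
#> circ_seq   mi_seq   struct
#>    0.252    0.259    0.489
```

The report carries one row per fold plus mean and standard deviation —
`cv$folds` here spans AUC 0.904–0.977 over the five folds. The attention
summary says the trained stage-2 weights put about 49% of their mass on the
structural block, which is exactly the leakage diagnostic discussed in the
vignette: with `leakage_safe = FALSE` the graph embedding encodes the known
edges, so the model leans on it. Re-running with the default
`leakage_safe = TRUE` drops the AUC to near chance on this synthetic
benchmark — the planted single-site signal is invisible to mean-pooled
k-mer composition, and the leakage-controlled graph carries no held-out
information. Both protocols are one switch apart; see
`vignettes/cmi-prediction-methods.Rmd` for the analysis.

From the shell:

```sh
cmipred simulate --out bench --seed 7
cmipred cv --circ bench/circRNA.fasta --mi bench/miRNA.fasta \
           --pairs bench/pairs.tsv --out bench_cv --seed 1 --full-graph
```

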