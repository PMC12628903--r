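---
title: "Predicting protein–protein interactions from fused language-model embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein–protein interactions from fused language-model embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppifusion)
```

## The problem

Physical protein–protein interactions (PPIs) are expensive to establish
experimentally, while protein sequences are abundant. `ppifusion`
implements a sequence-only PPI classifier: each protein is represented
by pooled per-residue embeddings from two protein language models (a
1536-wide Ankh-style model and a 1280-wide ESM-2-style model), the two
proteins of a candidate pair are fused through self-attention and an
element-wise mean, and a deep network with a sigmoid output returns an
interaction probability. The package also implements the STRING-based
dataset construction that such models are trained on, a full
training/cross-validation loop, and the evaluation metrics used in this
field.

Pretrained language-model weights are deliberately out of scope: the
embedding step is specified as a *contract* (a function from a protein
record to per-residue matrices of fixed widths), and the package ships a
deterministic synthetic embedder satisfying that contract so every stage
downstream of the GPU-dependent step is exercisable and testable at desk
scale. Real embedder adapters can be plugged in through the same
contract.

## Dataset construction

STRING physical-links files give each protein pair an integer combined
score in [0, 1000], normalized here to [0, 1]. The pipeline applies, in
order:

1. **Parsing and canonicalization.** Pairs are stored with the
   lexicographically smaller identifier first, so (a,b) and (b,a)
   deduplicate; self-pairs are dropped.
2. **Labeling.** Scores strictly below 0.4 become non-interactions,
   strictly above 0.8 interactions. Scores in the closed gap
   [0.4, 0.8] are ambiguous and excluded — the strict readings of
   "below" and "above" mean the endpoints themselves are excluded.
3. **Length filtering.** A pair survives only if both sequences have
   50–800 residues inclusive. Very short proteins lack the structural
   context for reliable prediction; very long ones are excluded for
   embedding-memory reasons.
4. **Redundancy removal.** Proteins are clustered at 40% pairwise
   identity by a greedy, length-descending pass (the strategy of
   CD-HIT-class tools): each protein joins the first earlier
   representative at or above the threshold, otherwise founds a
   cluster. Identity is computed from a Needleman–Wunsch global
   alignment (match +1, mismatch 0, linear gap −1; Rcpp kernel) as
   identical aligned positions divided by the shorter length, with a
   fixed traceback tie-break so the value is deterministic. Only pairs
   whose both members are representatives are kept; remapping members
   onto representatives is rejected because it can create duplicate or
   self pairs.
5. **Negative subsampling.** All positives are kept and exactly
   `ratio` times as many negatives are drawn without replacement
   (default 1:10, reflecting the rarity of true interactions).
   Negatives come only from score-listed pairs below the 0.4 bound;
   random non-edges are never fabricated.

Whether clustering should precede labeling is genuinely open; the
default is after labeling (cheaper, clusters only proteins that still
matter) and the order is switchable via `cluster_stage`.

Every stage logs its survivor count, and `make_splits` produces an
8:2 train/validation split plus five balanced folds, all driven by one
integer seed.

## The model

Let $x_1, x_2 \in \mathbb{R}^{D}$ be the pooled pair features
($D = 2816$ fused, 1536 or 1280 for single-embedder profiles).

* **Shared-weight extraction.**
  $f_i = \mathrm{Dropout}(\mathrm{ReLU}(W x_i + b))$, the *same*
  $W, b$ for both proteins, giving order-independent extraction
  (default width 512, dropout 0.1).
* **Fusion.** The two extracted vectors are stacked as a 2-token
  sequence and passed through scaled dot-product self-attention
  $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$; the flattened 2-token output
  is $F_1$ (length $2d$). The element-wise mean $F_2 = (f_1+f_2)/2$ is
  order-invariant. The pair representation is $F = [F_1; F_2]$. Reading
  the fusion input as a 2-token sequence is the only interpretation
  under which concatenating $F_1$ and $F_2$ yields a fixed-length
  vector. With the default width, $F$ is 1536-long — which reconciles
  the two widths one encounters for this architecture (2816 per-protein
  input vs 1536 classifier input).
* **Prediction head.** In the MDNN profile a multi-head self-attention
  block (4 heads, residual connection) runs over the three natural
  pair-feature tokens (the two attention outputs and the mean vector)
  before the first hidden layer; the DNN ablation profile omits it.
  Then fully connected layers (512, 256, 64) with ReLU and dropout, and
  a single sigmoid unit.

The reference architecture leaves layer widths, head count and dropout
unstated, so these are package design choices, all exposed in
`model_config()`. Multi-head attention cannot operate on residues here
— residue axes are gone after mean pooling — so it operates on the
pair-feature tokens; a residue-level variant would require unpooled
matrices and is out of scope.

### Numerical choices

* Weights initialize uniformly in $\pm 1/\sqrt{\text{fan-in}}$ from the
  model seed; biases start at zero.
* Dropout is inverted (activations rescaled by $1/(1-p)$ at training
  time), so evaluation mode is deterministic with no rescaling.
  The default rate is 0.1: with the fixed 10-epoch budget below,
  heavier dropout (0.3) measurably under-converges, and early stopping
  already guards against overfitting.
* Softmax rows are max-shifted before exponentiation.
* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ inside the loss.
* The backward pass is hand-derived and verified against central-
  difference numerical gradients for every parameter tensor in both
  profiles (tolerance $10^{-5}$ at $\varepsilon = 10^{-6}$).

## Training protocol

Binary cross-entropy, Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$; elementwise update in C++), minibatch 64,
learning rate 0.001, at most 10 epochs — the protocol this architecture
is specified with. Early stopping monitors validation loss with
patience 3 (the reference protocol stops "after a pre-determined number
of epochs without improvement" without naming the metric or patience;
validation loss is the stricter, threshold-free choice) and training
returns the best-epoch weights. No class weighting is applied despite
the 1:10 imbalance — the imbalance is part of the data design and plain
BCE is the stated loss. The decision threshold for thresholded metrics
defaults to 0.5 and is exposed.

`cross_validate()` shuffles pairs once, forms `k` folds (sizes within
one of each other), and trains a fresh model per fold with a
fold-derived seed (`seed + fold`), so folds are independent yet
reproducible. Early stopping inside a fold uses a 90:10 split of the
training folds — never the held-out test fold, which is reserved for
metrics. Results are reported per fold and as mean ± sd.

## Metrics

Sensitivity TP/(TP+FN), precision TP/(TP+FP), F1, and MCC
$(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$ are
computed from confusion counts at the decision threshold (ties predict
positive). Zero denominators yield 0 by convention — and a logged
message — so fold aggregation never propagates NaN. AUC is the
rank-based Mann–Whitney statistic (ties count one half); AUPR is
step-wise average precision, not trapezoidal interpolation, which
overestimates precision–recall area. When a fold contains one class,
ranking metrics are reported as NA, never silently zero. All six
implementations are tested against brute-force loop/pair-enumeration
oracles, and AUC additionally against the pROC package.

## Synthetic fixtures: what they emulate and what they do not

### Toy STRING fixture

`make_toy_string()` writes a links file, FASTA and a YAML manifest in
which every pipeline boundary is planted: raw scores 390/400/800/850
around the strict labeling bounds, sequence lengths 49/50/800/801
around the inclusive length bounds, one duplicated-order links row, and
one exact duplicate sequence that triggers exactly one cluster merge.
The manifest's expected survivor counts are enumerated at generation
time by an independent restatement of each rule, and the pipeline audit
asserts equality stage by stage.

Two construction details keep that enumeration exact for *any* seed.
Under the gap-cheap alignment scoring used for identity, random
sequences of very different lengths look deceptively similar (a random
50-mer aligns into a random 800-mer at ~0.97 identity/shorter), so the
boundary-length proteins use low-complexity repeat motifs over disjoint
letter pairs (identity ≈ 0.05 against anything random), and the bulk
proteins live in a narrow length band (110–130) with candidate
sequences rejection-sampled until all pairwise identities stay below
0.35, a margin under the 0.40 threshold. Real proteomes are of course
not like this; the fixture emulates *rule boundaries*, not sequence
evolution, and passing the audit says the pipeline is wired correctly,
not that the thresholds are biologically optimal.

### Planted-structure embeddings

`make_planted_embeddings()` builds a learnability fixture: latent
vectors $u_i = \mu + \varepsilon_i$ ($\varepsilon_i \sim N(0, I_8)$,
$\mu = 2 \cdot \mathbf{1}$), positives are the pairs with the largest
$u_i \cdot u_j$ (top 200 of all pairs among 300 proteins by default,
with 2000 sampled negatives — the 1:10 regime), and observed features
are a fixed random linear lift into the 2816-dimensional fused layout
plus Gaussian noise (sd 0.25 against unit-variance signal).

Two design points deserve explanation:

* **The latent mean.** With zero-mean latents the top-dot-product rule
  is an almost purely *bilinear* signal: a dot-product oracle on the
  features reaches AUC ≈ 1.0 while a held-out logistic probe on
  concatenated pair features stays near 0.69 — i.e. the signal would
  not be linearly recoverable, and no amount of training at this data
  scale makes a fair test of the architecture. The shared mean $\mu$
  (interpretable as hub-like interaction propensity) makes the dominant
  term of $u_i \cdot u_j$ additive across the pair, restoring linear
  recoverability (held-out probe AUC > 0.99 at zero noise) while the
  residual $\varepsilon_i \cdot \varepsilon_j$ term still rewards
  genuine pair modeling.
* **Complementary embedder blocks.** If one random lift spans all
  latent coordinates, the 1536-wide block alone already carries the
  whole signal, and single-embedder ablations structurally *dominate*
  the fused profile (fewer parameters, same information) — the opposite
  of what fusing two complementary language models is for. The lift is
  therefore block-structured: the Ankh-sized block encodes only the
  leading 75% of latent coordinates and the ESM-sized block only the
  trailing 75%. Each single view is informative but incomplete, and
  the fused profile sees strictly more — emulating the partial
  complementarity of real embedding models.

The fixture does **not** emulate: realistic embedding geometry or
anisotropy, sequence-similarity structure between proteins, hub-degree
heterogeneity beyond the shared mean, or species transfer. Passing the
learnability bar shows the architecture, fusion and optimizer can
recover a planted, linearly-accessible-plus-bilinear pair signal at
desk scale; it does not certify performance on real STRING data.

At the defaults the five-fold cross-validated MDNN reaches mean
held-out AUC above 0.9 in a few minutes on one CPU; at `noise_sd = 1e3`
the same pipeline collapses to chance (AUC 0.5), confirming the metric
reads signal, not leakage.

## Degenerate inputs and edge behavior

* Empty links files parse to empty pair sets; a header is optional.
* Pairs referencing unknown proteins fail with the missing identifiers
  named.
* Subsampling with insufficient negatives reports available vs
  required counts rather than silently shrinking the ratio.
* Single-class evaluation sets make AUC/AUPR NA (thresholded metrics
  follow the zero conventions).
* `predict_cmd` scores pairs in canonical order, so (a,b) and (b,a)
  return identical probabilities by construction; `symmetrize = "mean"`
  instead averages both forward orders (the attention branch of the
  fusion is order-sensitive; the mean branch is not).
* All commands write a run manifest (config, seeds, input checksums)
  before any output, and inference-mode outputs are byte-identical
  across reruns.

## Problem sizes used in the shipped checks

The package's own test suite runs the dataset pipeline on 12–30-protein
toy fixtures, trains small-width models (feature dimension 64,
extractor 32) for protocol tests, and runs the full-scale learnability
check — 300 proteins, 2200 pairs, the default 2816/512 architecture,
five folds, three embedding profiles — once. These sizes give stable
AUC estimates (fold sd ≈ 0.02–0.04) while keeping the whole suite
runnable on a single CPU in well under half an hour.

## Known limitations

* The greedy identity clustering is exact-alignment based and
  quadratic in the number of proteins; it is meant for desk-scale
  datasets, not proteome-scale redundancy removal (use a dedicated
  clustering tool there and feed its representatives in).
* Identity over the shorter sequence makes highly length-mismatched
  pairs look similar; combined with gap-cheap scoring this is
  aggressive clustering behavior (see the fixture notes above).
* The model operates on pooled embeddings; residue-resolution effects
  (binding interfaces, long-range contacts) are only visible through
  whatever the pooled statistics retain.
* Output probabilities are not calibrated.
* Real-embedder adapters must choose a hidden layer; the packaged
  convention is the final hidden layer, a choice recorded rather than
  asserted.
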