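---
title: "Classifying sORF-encoded peptides with a stacked ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sORF-encoded peptides with a stacked ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepstack)
```

## The problem

Long non-coding RNAs carry many short open reading frames (sORFs), a
small fraction of which are actually translated into small peptides
(SEPs, sORF-encoded peptides). Deciding computationally whether an
sORF/peptide pair is a genuine coding pair is a binary classification
problem whose inputs are two short sequences: the nucleotide sORF
(tens to a few hundred nt) and its translation (>= 10 residues).
`sepstack` implements a three-model stacked ensemble over two
complementary views of such a pair: a wide vector of hand-crafted
composition descriptors, and a dense learned-style embedding of the
peptide.

## Feature model

Eight descriptor blocks are concatenated in a fixed canonical order into
the fused vector

$$ V_{1737} = V_{AAC} \oplus V_{APAAC} \oplus V_{PAAC} \oplus V_{QSO}
   \oplus V_{k\text{-mer}}^{aa} \oplus V_{CTD} \oplus V_{Fickett}
   \oplus V_{k\text{-mer}}^{nt} $$

with widths 20 + 26 + 23 + 46 + 841 + 30 + 1 + 750 = 1737.

**Nucleotide blocks.**

* *k-mer (750)*: frequencies of all 3-mers and 4-mers over the 5-letter
  alphabet `A,C,G,T,N` ($5^3 + 5^4 = 750$). The default denominator is
  the number of windows $L-k+1$, which makes each k-block a proper
  probability vector; an alternative `length_based` normalization
  ($L-k-1$, clamped to 1) is exposed because some tools normalize by a
  length-derived constant instead. Both are available; `windows` is the
  default because it is well defined for every $L \ge k$.
* *Fickett TESTCODE (1)*: for each base $B$, the frame counts $B_1, B_2,
  B_3$ at positions congruent to 0/1/2 mod 3 give the positional
  asymmetry statistic $B_{pos} = \max(B_i)/(\min(B_i)+1)$; together with
  the base content fraction, the eight statistics are mapped through the
  classical TESTCODE probability bins (Fickett 1982, as propagated by
  coding-potential tools such as CPAT) and combined as
  $\sum_{i=1}^{8} p_i w_i$. The lookup tables and weights are embedded
  constants.
* *CTD (30)*: base composition (4), unordered adjacent hetero-pair
  transition frequencies AT, AC, AG, TG, TC, GC over the $L-1$ adjacent
  positions (6), and for each base the five positional quantiles of its
  occurrence list (20). The quantile convention is *floor-based*: with
  $c$ occurrences, slots are taken at occurrence indices
  $1, \max(1,\lfloor 0.25c \rfloor), \max(1,\lfloor 0.5c \rfloor),
  \max(1,\lfloor 0.75c \rfloor), c$ and divided by $L$. This convention
  reproduces the standard worked example of the descriptor exactly
  (every distribution slot of all four bases); note that published
  descriptions of the transition component are not always internally
  consistent — we count unordered adjacent pairs, which matches four of
  the six transition values usually quoted for that example, and we
  document rather than reconcile the other two.

**Amino-acid blocks.** Residues are ordered `ACDEFGHIKLMNPQRSTVWY`
throughout; `X` is tolerated (excluded from composition numerators,
zero contribution to correlation sums, still counted in lengths).

* *AAC (20)*: residue frequencies.
* *PAAC (23)* and *APAAC (26)*: Chou-style pseudo amino-acid
  composition. Sequence-order factors at lag $d$ are mean squared
  property differences (PAAC) or per-property mean products (APAAC,
  hydrophobicity and hydrophilicity separately) between residues $i$
  and $i+d$; composition entries are deflated by
  $1/(1 + w\sum\theta)$ and the order terms appended as
  $w\theta_d/(1 + w\sum\theta)$, $w = 0.05$. The property tables
  (Tanford hydrophobicity, Hopp–Woods hydrophilicity, side-chain mass)
  are embedded and standardized over the 20 residues. Because APAAC's
  correlation factors are products of centered properties they can be
  negative; this is the standard behaviour of the amphiphilic variant.
* *QSOrder (46)*: quasi-sequence-order with two residue distance
  matrices, $2 \times (20 + \lambda)$ values. The classical constants
  (Schneider–Wrede and Grantham matrices) are not bundled; instead two
  synthetic stand-in matrices are constructed from the embedded property
  tables (Euclidean distances over hydrophobicity/hydrophilicity and
  over side-chain mass/hydrophobicity, scaled to max 1, symmetric, zero
  diagonal). They play the same structural role; users with the
  classical matrices can pass them via the `matrices` argument.
* *k-mer (841)*: the exact 400 2-mer frequencies concatenated with
  4-mer frequencies folded into 441 buckets by a stable salted
  polynomial string hash. A 20-letter 4-mer space has $160{,}000$
  cells, so a fixed 841-wide layout is necessarily a folding; the
  hashing is deterministic and documented, and a `full` mode with exact
  sparse 4-mer counts exists for analyses that need it.

**Sequence-order lag.** The lag $\lambda$ is 3 everywhere by default:
the block widths above (23 = 20 + 3, 26 = 20 + 2·3, 46 = 2·(20 + 3))
force this value, and it keeps every encoder well defined for peptides
as short as 10 residues (a lag of 30, sometimes quoted as a generic
default for these descriptors, would be undefined there). It is
configurable.

## Embedding branch

The deep branch consumes one fixed-width vector per peptide. A real
protein language model (ESM-2-class, 1280-dim mean-pooled final layer)
can be supplied as a precomputed TSV (`embed_dataset(source = "file")`).
For fully offline, deterministic operation the package provides a
*stub* embedding: overlapping 3-mer tokens are hashed and projected,
jointly with their positions, through seed-derived sinusoidal random
features, summed and scaled to unit norm. The stub is
sequence-sensitive and permutation-sensitive and exercises every
downstream code path, but it encodes local composition only — results
obtained with it say nothing about what a trained language model would
add on real data.

## The three-model stack

* **GBDT branch**: depth-7 gradient-boosted trees (xgboost backend,
  histogram method, single thread, seeded) minimizing binary log-loss
  on $V_{1737}$; the branch output is the sigmoid of the additive tree
  score.
* **Self-attention branch**: the pooled embedding is one token. Q/K/V
  projections are applied and scores $QK^T/d_k$ pass through a softmax,
  which over a single key is identically 1 — so the attended value
  reduces to the V-projection and the query/key weights receive no
  gradient. This degenerate form is implemented exactly as such (the
  scaling constant $d_k$ defaults to the embedding width) and flagged
  here: with single-vector input, self-attention is a linear projection
  followed by the feed-forward head (one hidden ReLU layer, sigmoid
  output). Training is full-batch Adam, learning rate 0.001, 128
  epochs, binary cross-entropy, no early stopping, seeded
  initialization. A per-residue token mode would make the attention
  non-trivial but requires per-residue embeddings, which the pooled
  sources here do not provide; it is not implemented.
* **Meta-learner**: logistic regression on the 2-dimensional input
  $[ML_{out}, DL_{out}]$, $P = \sigma(W \cdot P_{MD} + B)$, decision
  threshold 0.5 with ties going to the negative class. Meta-features
  are collected *out-of-fold* with stratified 5-fold splitting —
  in-sample stacking would let the meta-learner read overfit branch
  outputs and inflate its weights — and the branches are then refit on
  the full training set.

All seeds derive from the single `seed` argument; with one BLAS/xgboost
thread the whole fit is reproducible bit-for-bit, and a saved bundle
(`save_sep_stack()`) reloads to identical predictions.

## Evaluation

`evaluate_predictions()` computes TP/TN/FP/FN at the threshold and
sensitivity, specificity, MCC, accuracy, precision and F1 from the
standard formulas, with the convention that any metric with a zero
denominator (including MCC) is reported as 0 — needed for degenerate
folds. AUC is the trapezoidal integral of the ROC over all distinct
score thresholds with tied scores grouped, which equals the pairwise
Mann–Whitney probability; the test suite checks both identities and
cross-checks against the pROC package.

## Synthetic benchmark

`simulate_sorf_data()` generates balanced labeled pairs: peptide
lengths uniform on 10–60 aa (small peptides just above the 10-residue
floor up to typical SEP sizes), every peptide M-initiated, nucleotides
the codon spelling plus a uniform stop codon, so each record is a
well-formed ORF whose frame-0 translation is its peptide. Class
separation of strength $\delta$ is injected at the distribution level —
positives draw residues $\propto \exp(\delta h/2)$ ($h$ = standardized
hydrophobicity) and synonymous codons with a G/C-third-position tilt
$\exp(\delta/2)$; negatives are uniform — rather than by planting
motifs, so that the hand-crafted encoders, the stub embedding and both
branches can all see the signal. $\delta = 0$ makes the classes
identically distributed (a true null); the default $\delta = 1$
produces a strong but imperfect signal (held-out ensemble AUC a little
above 0.9 at $n = 1000$), which we consider a realistic difficulty for
a desk-scale benchmark. The generator emulates class-conditional
compositional bias only; it does not reproduce the length, codon-usage
or homology structure of real lncRNA catalogues, so passing benchmarks
here demonstrates correctness and sensitivity of the pipeline, not
field performance.

Problem sizes used by the shipped checks (chosen to keep the full suite
desk-scale): dimensional and formula checks run on single sequences or
a few hundred random sequences; benchmark checks train on 1000 records
with 5-fold stacking (100 boosting rounds) and score 500 held-out
records; the separation-monotonicity sweep uses 3 seeds × 4 separation
levels with 3-fold stacking and 60 boosting rounds; the end-to-end
determinism check uses 80 records.

## Numerical and design notes

* Ties at $P = 0.5$ are classified negative (the decision rule is
  strictly "greater than").
* Scores clamp to $(10^{-9}, 1-10^{-9})$ before log-loss-style uses.
* The redundancy filter is a greedy longest-first single-linkage pass
  using gapless best-offset identity (matches / longer length). It is a
  deliberate lightweight stand-in for CD-HIT-style clustering — no
  external binaries — and is *not* equivalent to it; at desk scale it
  removes exact and near-duplicates deterministically.
* Unknown symbols: nucleotide input maps non-`ACGTN` to `N` and peptide
  input maps non-canonical residues to `X`, each with a warning
  (errors under `map_unknown = FALSE`).
* Peptides of exactly 10 residues are accepted (the length floor is
  ">= 10").
* The attention branch trained on stub embeddings typically performs
  near chance on the synthetic benchmark — the stub's sinusoidal hash
  features are a hard representation for a small MLP — and the
  meta-learner correspondingly down-weights it; this is the intended
  behaviour of the stack, which must not fall below its best branch by
  more than noise.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
train <- simulate_sorf_data(200, 200, seed = 1)
test  <- simulate_sorf_data(100, 100, seed = 2)
fit <- sep_stack(train, seed = 1)
fit
pred <- predict(fit, test)
evaluate_predictions(test$label, pred$P)
```

## Limitations

* No real protein-language-model inference is bundled; embeddings come
  from the stub or a user-supplied TSV.
* The 841-wide amino-acid k-mer block is a hash folding, not an exact
  4-mer count table (use `full` mode for exact counts).
* The QSOrder distance matrices are property-derived stand-ins, not
  the classical published constants.
* Benchmarks are synthetic; no claims are made about accuracy on real
  lncRNA/SEP catalogues, which additionally require redundancy control
  against homology (CD-HIT/BLAST-style) that the built-in filter only
  approximates.
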