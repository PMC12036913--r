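# sepstack

Stacked ensemble classification of sORF-encoded peptides (SEPs).

Long non-coding RNAs contain many short open reading frames (sORFs);
only some are translated into functional small peptides. `sepstack`
decides whether a paired sORF (nucleotide) / peptide (amino-acid)
record is a genuine coding pair. It is aimed at computational
biologists benchmarking coding-potential methods and at anyone who
needs a fully deterministic, offline-trainable sORF/SEP classifier.

## The model

Two views of each record feed a three-model stack:

1. **Fused descriptor vector** (1737 dims):
   `V = V_AAC ⊕ V_APAAC ⊕ V_PAAC ⊕ V_QSO ⊕ V_kmer_aa ⊕ V_CTD ⊕ V_Fickett ⊕ V_kmer_nt`
   — amino-acid composition (20), amphiphilic and plain pseudo
   amino-acid composition (26/23), quasi-sequence-order (46), amino-acid
   2-mer + hashed 4-mer frequencies (841), nucleotide CTD (30), Fickett
   TESTCODE score (1) and nucleotide 3/4-mer frequencies over `ACGTN`
   (750). A depth-7 gradient-boosted tree model (binary log-loss)
   produces `ML_Output = σ(Σ leaf scores)`.
2. **Peptide embedding** (1280 dims; deterministic stub, or a
   precomputed protein-language-model TSV). A single-token
   self-attention network trained with Adam (lr 0.001, 128 epochs,
   binary cross-entropy) produces `DL_Output`.

A logistic-regression meta-learner combines the two branch
probabilities, `P = σ(W·[ML_Output, DL_Output] + B)`, fitted on
stratified out-of-fold meta-features; a record is called a SEP when
`P > 0.5`. Performance is reported as SN, SP, MCC, ACC, PRE, F1 and
trapezoidal ROC AUC.

A synthetic paired-FASTA generator with a tunable class-separation
strength `delta` (compositional bias, no planted motifs) makes the
whole pipeline testable end to end without downloads.

## Worked example

```r
library(sepstack)
train <- simulate_sorf_data(200, 200, seed = 1)   # balanced, delta = 1
test  <- simulate_sorf_data(100, 100, seed = 2)
fit <- sep_stack(train, seed = 1)
fit
#> Stacked sORF/SEP ensemble
#>   records: 400   fused features: 1737   embeddings: stub (1280-dim)
#>   branches: depth-7 GBDT (150 rounds) + self-attention (128 epochs)
#>   meta-learner: logit(P) = -2.735 + 4.919 * ML + 0.645 * DL
pred <- predict(fit, test)
head(pred, 3)
#>           id ML_Output  DL_Output         P label_hat
#> 1 sorf_00001 0.9230623 0.87740956 0.9146097         1
#> 2 sorf_00002 0.9963539 0.02984752 0.8988966         1
#> 3 sorf_00003 0.9985021 0.65386340 0.9307426         1
evaluate_predictions(test$label, pred$P)
#> Binary classification report (threshold 0.5)
#>   counts: TP=86  TN=90  FP=10  FN=14
#>   SN=0.8600  SP=0.9000  MCC=0.7606  ACC=0.8800  PRE=0.8958  F1=0.8776  AUC=0.9396
```

`ML_Output`/`DL_Output` are the branch probabilities, `P` the stacked
probability and `label_hat` the 0.5-threshold call; at this training
size the ensemble separates the default synthetic benchmark with
held-out AUC ≈ 0.94 and MCC ≈ 0.76 (the descriptor branch carries most
of the signal; the stub-embedding branch contributes little, by
design).

## Command line

```sh
Rscript -e 'sepstack::sep_cli()' simulate --out-prefix bench --seed 1
Rscript -e 'sepstack::sep_cli()' train --nt bench_nt.fasta --aa bench_aa.fasta \
    --labels bench_labels.tsv --model-dir model --seed 1
Rscript -e 'sepstack::sep_cli()' predict --nt bench_nt.fasta --aa bench_aa.fasta \
    --model-dir model --out pred.tsv
Rscript -e 'sepstack::sep_cli()' evaluate --predictions pred.tsv \
    --labels bench_labels.tsv --out report.json
```

Subcommands: `simulate`, `encode`, `train`, `predict`, `evaluate`.
Every run writes a resolved-config JSON next to its outputs; seeds are
mandatory wherever randomness enters.

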