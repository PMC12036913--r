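Package: sepstack
Title: Stacked Ensemble Classification of sORF-Encoded Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether a short open reading frame (sORF) and the small
    peptide it encodes (SEP) form a genuine coding pair. Ten hand-crafted
    sequence encoders (nucleotide 3/4-mer, Fickett TESTCODE, CTD; amino-acid
    AAC, PAAC, APAAC, quasi-sequence-order and 2/4-mer) are fused into a
    1737-dimensional feature vector and combined with protein language model
    style embeddings inside a three-model stacked ensemble: gradient-boosted
    trees on the fused features, a self-attention network on the embeddings,
    and a logistic-regression meta-learner on the two branch probabilities.
    Includes paired FASTA input/output, a deterministic embedding stub, a
    synthetic paired sORF/SEP data generator with tunable class separation,
    a full binary-classification metric suite, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
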