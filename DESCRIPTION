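Package: lncentropy
Title: Coding-Potential Classification of Transcripts from Information-Entropy Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes long non-coding RNAs (lncRNAs) from protein-coding
    transcripts using a 35-dimensional feature vector built from topological
    entropy and generalized topological entropy of the nucleotide sequence
    (with a repetition-emphasizing modification), block Shannon entropies,
    gapped mutual information, Kullback-Leibler divergences, open reading
    frame statistics and sequence length, together with an 84-feature k-mer
    baseline. Includes FASTA preprocessing (length filtering, greedy
    redundancy removal, class balancing), cross-validated training and
    evaluation of support vector machine, random forest and gradient-boosted
    tree classifiers with grid search, ROC/PR analysis, feature-importance
    ranking, a two-class synthetic transcript generator, and a command-line
    interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
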