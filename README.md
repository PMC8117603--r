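# lncentropy

Sequence-only classification of transcripts into long non-coding RNAs
(lncRNAs) and protein-coding transcripts (PCTs), for people building or
evaluating coding-potential predictors. Each transcript is represented by a
compact 35-dimensional feature vector — sequence length, four open reading
frame (ORF) statistics, and a 30-value information-theory block — and
classified with an RBF-kernel SVM, a random forest, or gradient-boosted
trees under stratified 5-fold cross-validation with grid search. An
84-feature k-mer frequency baseline (4 mono- + 16 di- + 64 trinucleotide
frequencies) is included for comparison, along with FASTA preprocessing
(length filter, greedy redundancy removal, class balancing), a two-class
synthetic transcript generator, and a command-line interface.

## The features

The distinctive part of the representation is topological entropy and its
generalization, computed base-4 so values are comparable across features.
For a sequence ω and word length *n*,

    TE(ω, n) = log4(p_n) / n

where `p_n` counts the distinct *n*-words in the prefix window of length
`4^n + n − 1` (truncated at the sequence end). With `n_ω` the largest scale
satisfying `4^n + n − 1 ≤ |ω|`, the generalized form of order *k* averages
the per-length terms over the *k* largest supported word lengths:

    GTE(ω, k) = (1/k) · Σ_{i = n_ω−k+1..n_ω} log4(p_ω(i)) / i

Both come in a "modified" variant that discards words rarer than a frequency
threshold before counting, emphasizing repeated subwords. The full
35-vector is: length; first/longest ORF length and relative length; block
Shannon entropies (L = 1..4); TE (n = 3, 4, 5); GTE (k = 3, 4, 5); gapped
mutual information (g = 1..17); and Kullback–Leibler divergence of the
L-word distribution from its independence model (L = 1..3). Details,
conventions and edge cases are in the methods vignette
(`vignettes/lncentropy-methods.Rmd`).

## Worked example

```r
library(lncentropy)

spec <- synthetic_spec(n_per_class = 100, seed = 7)
ts <- generate_dataset(spec)
ts
#> transcript_set: 200 record(s)
#>   lengths: 201-2975 nt; labels: lncRNA=100 PCT=100 unlabeled=0
#>   provenance:
#>     generate_dataset: 200 -> 200

ft <- build_feature_table(ts, "integrated35")
fit <- lnc_train(ft, "gbt", seed = 7)
fit
#> lnc_model: gbt on integrated35 (200 transcripts, 5-fold CV, seed 7)
#>   pooled out-of-fold AUC 0.9891, AUPR 0.9888
#>   hyperparameters: max_depth=3, eta=0.05, nrounds=100

head(feature_importance(fit), 5)
#>           feature  importance
#> 1 orf_longest_rel 0.931528864
#> 2             SE2 0.031894155
#> 3             SE1 0.020977740
#> 4            GTE3 0.007849059
#> 5            MI15 0.001650041
```

The generator embeds an ORF covering 50–90% of each coding-like transcript
and draws noncoding-like transcripts from a background Markov chain, so the
pooled out-of-fold AUC of 0.989 says the classifier recovers that designed
signal from 200 transcripts, and the importance ranking confirms it leans on
the longest-ORF relative length with entropy features contributing the rest.
`plot(fit)` draws the pooled ROC and PR curves; `predict(fit, newdata)`
scores new feature tables.

Real FASTA flows through the same stages:

```r
ts  <- read_fasta("transcripts.fa", label_map = "labels.tsv")
ts  <- balance_downsample(dedup_redundant(filter_short(ts)), seed = 1)
ft  <- build_feature_table(ts, "integrated35")
fit <- lnc_train(ft, "svm_rbf", seed = 1)
```

or through the CLI (`inst/cli/lncentropy.R`) with subcommands `prep`,
`features`, `train-eval`, `synth` and `run-all`.

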