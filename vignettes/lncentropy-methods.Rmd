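---
title: "Classifying coding potential from information-entropy features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying coding potential from information-entropy features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncentropy)
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts longer than 200 nt that do not
encode protein. Separating them from protein-coding transcripts (PCTs) using
only the nucleotide sequence is a standard binary classification task in
transcript annotation. This package represents each transcript by a compact
35-dimensional feature vector built from information-theoretic sequence
complexity measures and open-reading-frame (ORF) statistics, and compares it
against an 84-dimensional k-mer frequency baseline using three classifier
families (RBF-kernel SVM, random forest, gradient-boosted trees) under
stratified five-fold cross-validation.

The intuition is that coding sequence is locally constrained — a long
stop-free reading frame, codon-position composition bias, repeated use of
preferred codons — and these constraints leave a measurable signature in
subword complexity that a much larger unstructured k-mer table captures only
implicitly.

## The feature model

All logarithms in the feature block are base 4, the natural base for a
four-letter alphabet, so every entropy-like quantity lives on a `[0, 1]`-ish
scale and the features are directly comparable.

**Topological entropy (TE).** For a sequence $\omega$ and word length $n$,

$$H_{top}(\omega, n) = \frac{\log_4 p_n}{n},$$

where $p_n$ is the number of *distinct* $n$-words among the overlapping
windows of the first $4^n + n - 1$ nucleotides of $\omega$. That window
length is the shortest prefix that could in principle contain all $4^n$
words, which makes the statistic length-normalized: 0 for a homopolymer, 1
when the prefix realizes every word (a de Bruijn sequence). The features use
$n = 3, 4, 5$.

**Generalized topological entropy (GTE).** Let $n_\omega$ be the largest $n$
with $4^n + n - 1 \le |\omega|$ (the word scale the sequence supports). For
order $k \le n_\omega$,

$$H^{(k)}(\omega) = \frac{1}{k} \sum_{i = n_\omega - k + 1}^{n_\omega}
\frac{\log_4 p_\omega(i)}{i},$$

with every $p_\omega(i)$ counted in the prefix window of length
$4^{n_\omega} + n_\omega - 1$. It averages the per-length complexity over the
$k$ largest supported word lengths; $k = 1$ reduces to TE at $n = n_\omega$.
The features use $k = 3, 4, 5$.

**Repetition modification.** Both TE and GTE are also computed in a
"modified" form (the default) that drops words whose occurrence count falls
below a frequency threshold before counting distinct words, emphasizing
repeated subwords. The threshold is configurable in two readings
(`threshold_mode`):

* `"literal"` (default): count $\ge 4^{n_\omega} / |\omega|$ for every term.
  Because $4^{n_\omega} \le |\omega|$ by the definition of $n_\omega$, this
  cutoff is below 1 and therefore never removes an observed word; it is kept
  as the default because it is the threshold's direct reading, and it makes
  the modified and unmodified values coincide.
* `"per_length"`: count $\ge 4^L / |\omega|$ with $L$ the word length of the
  term. For $L = 4, 5$ on transcripts shorter than $4^L$ this removes
  singleton words and genuinely emphasizes repetition.

After filtering, $p$ is floored at 1 so a fully filtered spectrum contributes
0 rather than $-\infty$, and the modified value can never exceed the
unmodified one (a property the test suite checks).

Two boundary choices are worth stating. At lengths where two scales satisfy
the two-sided window inequality (e.g. $|\omega| = 259$), the larger
$n_\omega$ is used — the most informative word length the sequence supports.
And when the sequence is shorter than the nominal window ($4^n + n - 1$
exceeds many real transcripts for $n = 5$), the window truncates at the
sequence end so that every feature remains defined for all transcripts that
pass the 200 nt filter; for long sequences the definition is unchanged. An
order $k > n_\omega$ is clamped to $n_\omega$ (flagged on the returned
value), which keeps the feature vector dense for transcripts shorter than
1028 nt.

**The remaining information-theory features.** Block Shannon entropies of the
overlapping $L$-word distribution for $L = 1..4$, normalized by $L$; gapped
mutual information between nucleotides $g$ apart for $g = 1..17$ (codon
structure shows up at $g$ multiples of 3); and Kullback–Leibler divergences
of the $L$-word distribution for $L = 1..3$ — against uniform for $L = 1$,
against the mononucleotide product (independence) model for $L = 2, 3$. The
block sizes 4 / 17 / 3 together with 3 TE + 3 GTE values give the 30-entry
information block.

**ORF and length features.** Sequence length, first-ORF length and relative
length, longest-ORF length (`ll`) and relative length (`lp`). ORFs are
detected on the forward strand in all three frames (transcripts are already
oriented), run from an ATG through the first in-frame stop, and the length
convention includes both the start and the stop codon — so a transcript that
is exactly one ORF has relative length 1. ORFs without a downstream in-frame
stop are not counted by default (`allow_open_ended` exposes the alternative).
"First" means leftmost start across frames; ties on length go to the smaller
start. The five values prepended to the 30-entry block give the integrated
35-dimensional vector.

**k-mer baseline.** 4 + 16 + 64 overlapping-window relative frequencies
(lexicographic within each k, no reverse-complement canonicalization since
transcripts are stranded). Windows containing `N` are skipped everywhere, in
features and baseline alike.

## Preprocessing

The preprocessing flow mirrors standard practice for building a training
corpus: drop sequences shorter than 200 nt (the lncRNA class definition
boundary — a 200 nt sequence is kept); remove redundancy; down-sample the
majority class to the minority size so the AUC is not inflated by class
imbalance.

Redundancy removal is a greedy longest-first clustering in the style of
cd-hit-est, but alignment-free: identity between two sequences is the
fraction of shared canonical 8-mers (a word and its reverse complement count
as one) relative to the distinct 8-mer set of the shorter sequence, and a
sequence joins an existing representative when that fraction reaches the
threshold (default 0.9, cd-hit-est's documented default). This measure is
deliberately cheap — redundancy reduction is preprocessing, not the
contribution — and errs toward keeping sequences: point-mutation divergence
destroys shared 8-mers quickly, so only near-duplicates and containments are
absorbed. An optional hook (`use_cdhit = TRUE`) shells out to an installed
`cd-hit-est` binary instead, when one is available.

## Classifier training and evaluation

Each classifier is evaluated by stratified five-fold cross-validation. Inside
every training fold, hyperparameters are selected by an inner five-fold grid
search scored by mean AUC: exhaustive over cost
$\{0.1, 1, 10, 100\}$ × kernel width $\{10^{-3}, 10^{-2}, 10^{-1}, 1\}$ for
the SVM (its only two tuned parameters), and staged coordinate-wise for the
tree models — trees, then depth, then minimum node size for the random
forest; depth, then learning rate, then rounds for boosting — because the
full product over tree parameters buys little at these grid sizes. Ties
prefer the earlier (simpler) grid value. The held-out folds' scores are
pooled into a single ROC and PR curve per algorithm; AUC is the trapezoidal
area (equal to the Mann–Whitney pair statistic, which the tests verify
exactly) and AUPR is the step-wise average precision. A final model is refit
on all rows with the modal fold-winning hyperparameters and carries the
gain-based feature importances for the tree models.

Features are z-scored inside each fold for the SVM only — RBF kernels are
scale-sensitive, trees are not — and SVM scores are a logistic link of the
decision values: a monotone transform, so ranking metrics are unaffected and
the procedure stays exactly reproducible (no internal calibration
resampling). Everything else that is stochastic (fold assignment, forest and
boosting seeds) derives from the single `seed` argument, and the tests check
that a fixed table and seed reproduce identical pooled scores.

## What the synthetic generator emulates

Real training corpora come from genome-annotation downloads that are too
large to bundle, so the package ships a generator whose two classes carry the
statistical structure the classifier actually exploits:

* **coding-like** (`PCT`): one embedded ATG→stop ORF whose target relative
  length is drawn from `[0.5, 0.9]` per transcript, interior codons drawn
  from the 61 sense codons with a codon-position composition bias (strength
  0.5 by default, mixing a uniform codon table with a position-specific
  nucleotide profile), placed at a random offset inside background sequence.
  The in-frame codon immediately upstream of the ORF is forced to a stop so
  the embedded ORF cannot silently grow by a chance upstream ATG — this keeps
  the designed ORF length the measured one.
* **noncoding-like** (`lncRNA`): a background Markov chain (order 1 by
  default, mildly AT-rich with CpG depletion, matching the gross composition
  of human transcripts) with no deliberate ORF; random ORFs of modest length
  still occur, as they do in real lncRNAs.

Lengths are log-uniform on `[200, 3000]` nt for both classes, so length alone
is uninformative by construction and the classes must be separated by
composition and ORF structure. Defaults are 500 transcripts per class and no
label noise; the `noise` parameter swaps an exact count of labels after
generation for robustness experiments. Generation is driven by R's
Mersenne-Twister with fixed `sample.kind`, so a seed pins the dataset across
platforms.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: real codon-usage tables and hexamer statistics, introns
and UTR structure, sequencing artifacts, transcript-biotype length
distributions, and homology between training and test sequences. The
synthetic benchmark demonstrates that the pipeline recovers a known signal
(AUC ≥ 0.95 for all three classifiers at the default conditions, with ORF
and length features at the top of the tree models' importance rankings); it
does not certify accuracy figures on any real annotation release.

## Numerical and design choices

* All entropies use base-4 logarithms; `0 · log 0 = 0` throughout.
* Degenerate inputs have defined values: a sequence with no valid window has
  block entropy 0, mutual information 0; distinct-word counts are floored at
  1 inside the entropy logs.
* The integrated feature block requires at least 18 nt (the largest MI gap
  plus one); the pipeline's 200 nt filter makes this moot in practice.
* Feature-table CSVs are written with full (17 significant digit) precision
  in binary mode, so rebuilding the same table yields a byte-identical file.
* The cross-validated ROC is pooled over out-of-fold scores (one curve per
  algorithm) rather than averaged per fold; pooling uses every transcript
  exactly once and matches how single published curves are usually drawn.
* Problem sizes used by the shipped checks: the entropy oracle suite runs
  200 random sequences of 200–1500 nt; the ORF oracle suite 500 sequences;
  the end-to-end benchmark the default 500 + 500 generator conditions.

## Known limitations

* The literal repetition threshold is vacuous (see above); the per-length
  mode is provided but is not the default, and no claim is made about which
  reading matches other implementations.
* The greedy deduplicator is not CD-HIT: it has no banded alignment, and its
  shared-8-mer identity is stricter than alignment identity for diverged
  pairs. Corpus sizes after deduplication are therefore not comparable with
  CD-HIT-derived counts.
* Only forward-strand ORFs with ATG starts are considered; no alternative
  start codons, no codon-usage or hexamer scores.
* The SVM reports ranking scores, not calibrated probabilities; AUC/AUPR are
  unaffected, but the scores should not be read as class probabilities.
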