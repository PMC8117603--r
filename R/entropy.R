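## Topological-entropy feature block.
##
## Core quantities, all in log base 4 so that every feature lives on the
## alphabet's natural scale:
##
##   TE_n(w)   = log4(p_n) / n,  p_n = number of distinct n-words observed in
##               the prefix window of length min(4^n + n - 1, |w|)
##   GTE_k(w)  = (1/k) * sum_{i = n_w-k+1}^{n_w} log4(p_i) / i, with p_i
##               counted in the prefix window of length min(4^{n_w}+n_w-1, |w|)
##
## where n_w is the largest n with 4^n + n - 1 <= |w|. The "modified" variants
## drop subwords whose occurrence count falls below a frequency threshold
## before counting distinct words, emphasizing repeated subwords.

log4 <- function(x) log(x) / log(4)

#' Supported subword-length scale of a sequence
#'
#' The largest word length `n` such that a prefix window of length
#' `4^n + n - 1` fits inside the sequence, i.e. the largest `n` with
#' `4^n + n - 1 <= seq_len`. At the boundary lengths where two values satisfy
#' the two-sided window condition, the larger (more informative) `n` is used.
#'
#' @param seq_len Sequence length in nt; must be at least 4.
#' @return Integer scale `n`.
#' @examples
#' n_omega(66)   # 3: 4^3 + 2 = 66
#' n_omega(200)  # 3
#' n_omega(259)  # 4: 4^4 + 3 = 259
#' @export
n_omega <- function(seq_len) {
  if (seq_len < 4L) stop("sequence length ", seq_len, " supports no word scale (need >= 4)")
  n <- 1L
  while (4^(n + 1L) + n <= seq_len) n <- n + 1L
  n
}

#' Configuration of the entropy feature block
#'
#' @param te_lengths Word lengths for the topological-entropy features
#'   (default `3:5`).
#' @param gte_orders Orders `k` for the generalized topological-entropy
#'   features (default `3:5`); an order exceeding the sequence's scale
#'   `n_omega` is clamped to it.
#' @param modified Apply the repetition-emphasizing frequency threshold
#'   (default `TRUE`).
#' @param threshold_mode `"literal"` uses the cutoff `4^n_omega / |seq|` for
#'   every term; `"per_length"` uses `4^L / |seq|` with `L` the word length of
#'   the term, which actually bites for long words on short transcripts.
#' @return An object of class `entropy_config`.
#' @export
entropy_config <- function(te_lengths = 3:5, gte_orders = 3:5,
                           modified = TRUE,
                           threshold_mode = c("literal", "per_length")) {
  threshold_mode <- match.arg(threshold_mode)
  te_lengths <- as.integer(te_lengths)
  gte_orders <- as.integer(gte_orders)
  if (!length(te_lengths) || any(te_lengths < 1L)) stop("invalid te_lengths")
  if (!length(gte_orders) || any(gte_orders < 1L)) stop("invalid gte_orders")
  structure(list(te_lengths = te_lengths, gte_orders = gte_orders,
                 modified = isTRUE(modified), threshold_mode = threshold_mode),
            class = "entropy_config")
}

#' Subword occurrence spectrum of a prefix window
#'
#' Counts every length-`L` word over overlapping positions of the first
#' `window_len` nt of the sequence (truncated at the sequence end); windows
#' containing `N` are skipped.
#'
#' @param seq Sequence string over `A,C,G,T,N`.
#' @param L Word length (`>= 1`, at most the sequence length).
#' @param window_len Prefix length to count in (default: whole sequence).
#' @return An object of class `subword_spectrum`: list with `word_length`,
#'   `window` (prefix length actually used) and `counts` (named integer
#'   vector of occurrence counts).
#' @examples
#' subword_spectrum("AAAA", 3)$counts       # AAA: 2
#' subword_spectrum("ACNGT", 2)$counts      # AC: 1, GT: 1
#' @export
subword_spectrum <- function(seq, L, window_len = nchar(seq)) {
  L <- as.integer(L)
  if (L < 1L) stop("'L' must be >= 1")
  if (L > nchar(seq)) stop("word length ", L, " exceeds sequence length ", nchar(seq))
  if (window_len < L) stop("'window_len' must be >= L")
  wl <- min(window_len, nchar(seq))
  w <- substring(seq, 1:(wl - L + 1L), L:wl)
  w <- w[!grepl("N", w, fixed = TRUE)]
  counts <- if (length(w)) {
    tab <- table(w)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  structure(list(word_length = L, window = wl, counts = counts),
            class = "subword_spectrum")
}

#' Distinct words at or above an occurrence threshold
#'
#' @param spec A [subword_spectrum()].
#' @param min_count Minimum occurrence count (default 0: plain distinct-word
#'   count, as any observed count is at least 1).
#' @return Integer number of distinct words with count `>= min_count`.
#' @export
distinct_count <- function(spec, min_count = 0) {
  stopifnot(inherits(spec, "subword_spectrum"), min_count >= 0)
  sum(spec$counts >= min_count)
}

## repetition-modification cutoff for a term of word length L
mod_threshold <- function(cfg, seq_len, L) {
  if (!cfg$modified) return(0)
  switch(cfg$threshold_mode,
         literal    = 4^n_omega(seq_len) / seq_len,
         per_length = 4^L / seq_len)
}

## distinct-word count for one term, thresholded and floored at 1 so a fully
## filtered spectrum contributes 0 rather than -Inf
term_p <- function(seq, L, window_len, thr) {
  p <- distinct_count(subword_spectrum(seq, L, window_len), thr)
  max(p, 1L)
}

#' Topological entropy of a sequence
#'
#' `log4(p)/n` where `p` is the number of distinct `n`-words in the prefix
#' window of length `min(4^n + n - 1, |seq|)`. With `cfg$modified`, words
#' rarer than the repetition threshold are discarded before counting (and
#' `p` is floored at 1). The value lies in `[0, 1]`: 0 for a homopolymer,
#' 1 when the window realizes all `4^n` words.
#'
#' @param seq Sequence string over `A,C,G,T,N` with `nchar(seq) >= n`.
#' @param n Word length.
#' @param cfg An [entropy_config()].
#' @return Entropy value in `[0, 1]`.
#' @examples
#' topological_entropy(strrep("A", 200), 3)                    # 0
#' cfg <- entropy_config(modified = FALSE)
#' topological_entropy(strrep("ACGT", 50), 3, cfg)             # 1/3
#' @export
topological_entropy <- function(seq, n, cfg = entropy_config()) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (n > nchar(seq)) stop("word length ", n, " exceeds sequence length ", nchar(seq))
  wl <- min(4^n + n - 1L, nchar(seq))
  thr <- mod_threshold(cfg, nchar(seq), n)
  log4(term_p(seq, n, wl, thr)) / n
}

#' Generalized topological entropy of a sequence
#'
#' The average of per-length topological-entropy terms over the `k` largest
#' supported word lengths: `(1/k) * sum_{i = n_w-k+1}^{n_w} log4(p_i)/i`,
#' each `p_i` counted in the prefix window of length
#' `min(4^{n_w} + n_w - 1, |seq|)` where `n_w = n_omega(nchar(seq))`. An
#' order `k > n_w` is clamped to `n_w` (reported via the `"clamped"`
#' attribute). With `k = 1` and `cfg$modified = FALSE` this reduces to
#' [topological_entropy()] at `n = n_w`.
#'
#' @param seq Sequence string over `A,C,G,T,N`, at least 4 nt.
#' @param k Order: number of word lengths averaged.
#' @param cfg An [entropy_config()].
#' @return Entropy value in `[0, 1]`, with attribute `clamped` (logical).
#' @examples
#' cfg <- entropy_config(modified = FALSE)
#' generalized_topological_entropy(substr(strrep("ACGT", 17), 1, 66), 3, cfg)  # 11/18
#' @export
generalized_topological_entropy <- function(seq, k, cfg = entropy_config()) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (nchar(seq) < 4L) stop("sequence too short for generalized topological entropy (need >= 4 nt)")
  nw <- n_omega(nchar(seq))
  clamped <- k > nw
  k <- min(k, nw)
  wl <- min(4^nw + nw - 1L, nchar(seq))
  terms <- vapply((nw - k + 1L):nw, function(i) {
    thr <- mod_threshold(cfg, nchar(seq), i)
    log4(term_p(seq, i, wl, thr)) / i
  }, numeric(1))
  structure(mean(terms), clamped = clamped)
}

#' Block Shannon entropy
#'
#' Shannon entropy (base-4 logarithm) of the overlapping `L`-word frequency
#' distribution over the whole sequence, normalized by `L` to `[0, 1]`.
#' Windows containing `N` are skipped; a sequence with no valid window has
#' entropy 0 by convention.
#'
#' @param seq Sequence string over `A,C,G,T,N` with `nchar(seq) >= L`.
#' @param L Word length.
#' @return Entropy value in `[0, 1]`.
#' @examples
#' shannon_block_entropy("ACGTACGTACGT", 1)  # 1
#' shannon_block_entropy("AACC", 1)          # 0.5
#' @export
shannon_block_entropy <- function(seq, L) {
  if (L > nchar(seq)) stop("word length ", L, " exceeds sequence length ", nchar(seq))
  counts <- subword_spectrum(seq, L)$counts
  if (!length(counts)) return(0)
  f <- counts / sum(counts)
  -sum(f * log4(f)) / L
}

#' Gapped mutual information between nucleotides
#'
#' Mutual information (log base 4, so at most 1) between the nucleotide at
#' position `i` and the one at position `i + g`, estimated from all valid
#' positions of the sequence; pairs involving `N` are skipped and the
#' marginals are computed from the same pair set.
#'
#' @param seq Sequence string over `A,C,G,T,N` with `nchar(seq) > g`.
#' @param g Gap in nt (`>= 1`).
#' @return Mutual information `>= 0`; 0 when fewer than one valid pair exists.
#' @examples
#' gapped_mutual_information(strrep("A", 50), 3)  # 0
#' @export
gapped_mutual_information <- function(seq, g) {
  g <- as.integer(g)
  if (g < 1L) stop("'g' must be >= 1")
  n <- nchar(seq)
  if (g >= n) stop("gap ", g, " leaves no pair in a sequence of length ", n)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  x <- chars[1:(n - g)]
  y <- chars[(1L + g):n]
  ok <- x != "N" & y != "N"
  if (!any(ok)) return(0)
  joint <- table(x[ok], y[ok])
  f <- joint / sum(joint)
  fx <- rowSums(f)
  fy <- colSums(f)
  ref <- outer(fx, fy)
  nz <- f > 0
  sum(f[nz] * log4(f[nz] / ref[nz]))
}

#' Kullback-Leibler divergence of the L-word distribution
#'
#' KL divergence (log base 4) from the observed overlapping `L`-word
#' distribution to a reference: for `L = 1` the uniform distribution (1/4
#' each); for `L >= 2` the product of the observed mononucleotide
#' frequencies (the independence model), so the value measures how far word
#' composition departs from what base composition alone predicts.
#'
#' @param seq Sequence string over `A,C,G,T,N` with `nchar(seq) >= L`.
#' @param L Word length.
#' @return Divergence `>= 0`; 0 when no valid window exists.
#' @examples
#' kl_divergence_block(strrep("A", 100), 1)  # 1
#' kl_divergence_block(strrep("A", 100), 2)  # 0
#' @export
kl_divergence_block <- function(seq, L) {
  L <- as.integer(L)
  if (L > nchar(seq)) stop("word length ", L, " exceeds sequence length ", nchar(seq))
  counts <- subword_spectrum(seq, L)$counts
  if (!length(counts)) return(0)
  f <- counts / sum(counts)
  ref <- if (L == 1L) {
    stats::setNames(rep(0.25, length(f)), names(f))
  } else {
    mono <- subword_spectrum(seq, 1L)$counts
    q <- mono / sum(mono)
    vapply(strsplit(names(f), "", fixed = TRUE),
           function(ch) prod(q[ch]), numeric(1))
  }
  sum(f * log4(f / ref))
}

#' The 30-value information-theory feature block
#'
#' Fixed order: block Shannon entropies `SE1..SE4`, topological entropies at
#' the configured word lengths (`TE3..TE5` by default), generalized
#' topological entropies at the configured orders (`GTE3..GTE5`), gapped
#' mutual information `MI1..MI17`, and Kullback-Leibler divergences
#' `KLD1..KLD3`.
#'
#' @param seq Sequence string over `A,C,G,T,N`; at least 18 nt (the largest
#'   mutual-information gap plus one), 200 nt or more in normal use.
#' @param cfg An [entropy_config()].
#' @return Named numeric vector of 30 finite values.
#' @export
entropy_feature_block <- function(seq, cfg = entropy_config()) {
  n <- nchar(seq)
  if (n < 18L) {
    stop("sequence of length ", n, " is below the 18 nt minimum: ",
         "MI features at gaps >= ", n, " and word-based features are undefined")
  }
  se <- vapply(1:4, function(L) shannon_block_entropy(seq, L), numeric(1))
  te <- vapply(cfg$te_lengths, function(nn) topological_entropy(seq, nn, cfg), numeric(1))
  gte <- vapply(cfg$gte_orders,
                function(k) as.numeric(generalized_topological_entropy(seq, k, cfg)),
                numeric(1))
  mi <- vapply(1:17, function(g) gapped_mutual_information(seq, g), numeric(1))
  kld <- vapply(1:3, function(L) kl_divergence_block(seq, L), numeric(1))
  stats::setNames(c(se, te, gte, mi, kld),
                  c(paste0("SE", 1:4),
                    paste0("TE", cfg$te_lengths),
                    paste0("GTE", cfg$gte_orders),
                    paste0("MI", 1:17),
                    paste0("KLD", 1:3)))
}
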