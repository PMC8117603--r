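#' Overlapping k-mer frequencies
#'
#' Relative frequencies of the observed k-mers over all overlapping windows
#' (step 1) of the sequence; windows containing `N` are skipped and the
#' frequencies sum to 1 over the observed words. No reverse-complement
#' canonicalization is applied: transcripts are stranded.
#'
#' @param seq Sequence string over `A,C,G,T,N` with `nchar(seq) >= k`.
#' @param k Word length.
#' @return Named numeric vector of frequencies over the observed words.
#' @examples
#' kmer_frequencies("ACGT", 2)  # AC, CG, GT each 1/3
#' @export
kmer_frequencies <- function(seq, k) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (k > nchar(seq)) stop("word length ", k, " exceeds sequence length ", nchar(seq))
  counts <- kmer_counts(seq, k)
  counts <- counts[counts > 0L]
  if (!sum(counts)) return(stats::setNames(numeric(0), character(0)))
  counts / sum(counts)
}

## counts over the full 4^k lexicographic alphabet; N-windows contribute to
## no word (Biostrings drops them)
kmer_counts <- function(seq, k) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
}

#' The 84-feature k-mer block
#'
#' The baseline representation the entropy feature set is compared against:
#' 4 mononucleotide, 16 dinucleotide and 64 trinucleotide relative
#' frequencies, lexicographically ordered within each k. Each k-block sums to
#' 1 when at least one valid window exists and is all zero otherwise.
#'
#' @param seq Sequence string over `A,C,G,T,N`, at least 3 nt.
#' @return Named numeric vector of exactly 84 entries.
#' @export
kmer_feature_block <- function(seq) {
  if (nchar(seq) < 3L) stop("sequence shorter than 3 nt has no trinucleotide window")
  blocks <- lapply(1:3, function(k) {
    counts <- kmer_counts(seq, k)
    tot <- sum(counts)
    if (tot > 0) counts / tot else counts * 0
  })
  unlist(blocks)
}
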