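#' Find open reading frames on the forward strand
#'
#' Scans the three forward reading frames for maximal ATG-to-stop ORFs. In
#' each frame, the ORF starts at the first ATG following the previous stop
#' codon (so two ORFs never share a stop) and runs through the first in-frame
#' stop codon (TAA/TAG/TGA), inclusive. Codons containing `N` never match a
#' start or a stop. ORFs without a downstream in-frame stop are dropped
#' unless `allow_open_ended = TRUE`, in which case they extend to the last
#' complete codon.
#'
#' @param seq Sequence string over `A,C,G,T,N`.
#' @param allow_open_ended Keep ATG runs that never hit a stop (default
#'   `FALSE`).
#' @return A data frame with one row per ORF, ordered by `start`: columns
#'   `start` (0-based offset of the A of ATG), `end` (0-based exclusive,
#'   one past the stop codon), `frame` (0/1/2) and `length_nt`.
#' @examples
#' find_orfs("ATGAAATAG")    # one ORF covering the whole string
#' find_orfs("CCATGTAACC")   # start 2, end 8
#' @export
find_orfs <- function(seq, allow_open_ended = FALSE) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, by = 3L, length.out = max(0L, (n - frame) %/% 3L))
    if (!length(starts)) next
    codons <- substring(seq, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    i <- 1L
    nc <- length(codons)
    while (i <= nc) {
      atg <- which(is_start[i:nc])
      if (!length(atg)) break
      a <- i + atg[1L] - 1L
      stp <- which(is_stop[a:nc])
      if (length(stp)) {
        s <- a + stp[1L] - 1L
        out[[length(out) + 1L]] <- data.frame(
          start = starts[a] - 1L, end = starts[s] + 2L,
          frame = frame, length_nt = starts[s] + 2L - (starts[a] - 1L))
        i <- s + 1L
      } else {
        if (allow_open_ended) {
          out[[length(out) + 1L]] <- data.frame(
            start = starts[a] - 1L, end = starts[nc] + 2L,
            frame = frame, length_nt = starts[nc] + 2L - (starts[a] - 1L))
        }
        break
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length_nt = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$frame), , drop = FALSE]
}

#' ORF and length feature block
#'
#' The five sequence-level features fed to the classifier alongside the
#' entropy block: sequence length; length of the first ORF (leftmost start
#' across frames, ties to the lower frame); its length relative to the
#' sequence; length of the longest ORF (`ll`; ties to the smaller start); and
#' its relative length (`lp`). ORF lengths count nucleotides from the A of
#' ATG through the last nt of the stop codon. All four ORF entries are 0 when
#' the sequence has no ORF.
#'
#' @param seq Non-empty sequence string over `A,C,G,T,N`.
#' @return Named numeric vector
#'   `c(length, orf_first_len, orf_first_rel, orf_longest_len, orf_longest_rel)`.
#' @examples
#' orf_feature_block("ATGAAATAG")   # 9, 9, 1, 9, 1
#' orf_feature_block("CCATGTAACC")  # 10, 6, 0.6, 6, 0.6
#' @export
orf_feature_block <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  orfs <- find_orfs(seq)
  if (nrow(orfs) == 0L) {
    v <- c(n, 0, 0, 0, 0)
  } else {
    first <- orfs[1L, ]                       # already ordered by start, frame
    longest <- orfs[order(-orfs$length_nt, orfs$start), ][1L, ]
    v <- c(n, first$length_nt, first$length_nt / n,
           longest$length_nt, longest$length_nt / n)
  }
  stats::setNames(v, c("length", "orf_first_len", "orf_first_rel",
                       "orf_longest_len", "orf_longest_rel"))
}

#' Write detected ORFs as a BED-like table
#'
#' @param seq Sequence string.
#' @param id Sequence identifier used in the first column.
#' @param path Output TSV path (0-based, half-open coordinates).
#' @return Invisibly, the ORF data frame.
#' @export
write_orf_bed <- function(seq, id, path) {
  orfs <- find_orfs(seq)
  bed <- data.frame(seqid = rep(id, nrow(orfs)), start = orfs$start,
                    end = orfs$end, frame = orfs$frame)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(orfs)
}
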