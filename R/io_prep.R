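#' Read transcripts from a FASTA file
#'
#' Reads DNA (or RNA) transcript FASTA and sanitizes every sequence:
#' uppercased, `U` mapped to `T`, any other non-`ACGT` character mapped to
#' `N`. Record order is preserved. Labels can be attached uniformly (one file
#' per class, the usual release layout) or per record via a two-column
#' id/label table.
#'
#' @param path Path to a FASTA file.
#' @param label Optional single class label (`"lncRNA"` or `"PCT"`) applied to
#'   every record in the file.
#' @param label_map Optional data frame (or path to a two-column TSV with
#'   header `id`, `label`) mapping record ids to labels; ids absent from the
#'   map stay unlabeled.
#' @return A [transcript_set()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgu", ">b", "NNNA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, label = NULL, label_map = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  labels <- rep(if (is.null(label)) NA_character_ else label, length(ids))
  if (!is.null(label_map)) {
    if (is.character(label_map) && length(label_map) == 1L) {
      label_map <- utils::read.delim(label_map, stringsAsFactors = FALSE,
                                     comment.char = "#")
    }
    if (!all(c("id", "label") %in% names(label_map))) {
      stop("label_map must have columns 'id' and 'label'")
    }
    m <- match(ids, label_map$id)
    labels[!is.na(m)] <- label_map$label[m[!is.na(m)]]
  }
  ts <- transcript_set(ids, as.character(recs), labels)
  add_provenance(ts, "read_fasta", nrow(ts), list(path = path))
}

#' Write transcripts to a FASTA file
#'
#' Sequences are wrapped at 60 columns. A read/write round trip reproduces
#' ids and sequences exactly.
#'
#' @param ts A [transcript_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ts, path) {
  stopifnot(inherits(ts, "transcript_set"))
  recs <- Biostrings::BStringSet(ts$seq)
  names(recs) <- ts$id
  Biostrings::writeXStringSet(recs, path, width = 60L)
  invisible(path)
}

#' Remove short transcripts
#'
#' Drops every sequence shorter than `min_len` nucleotides; a transcript of
#' exactly `min_len` nt is kept. The default of 200 nt is the conventional
#' lower bound of the lncRNA class definition.
#'
#' @param ts A [transcript_set()].
#' @param min_len Minimum retained length in nt (default 200).
#' @return The filtered `transcript_set`, provenance extended.
#' @examples
#' ts <- transcript_set(c("a", "b"), c(strrep("A", 199), strrep("A", 200)))
#' nrow(filter_short(ts))  # 1
#' @export
filter_short <- function(ts, min_len = 200L) {
  stopifnot(inherits(ts, "transcript_set"))
  if (min_len < 1L) stop("'min_len' must be >= 1")
  n0 <- nrow(ts)
  keep <- nchar(ts$seq) >= min_len
  out <- ts[keep, , drop = FALSE]
  class(out) <- class(ts)
  attr(out, "provenance") <- provenance(ts)
  add_provenance(out, "filter_short", n0, list(min_len = as.integer(min_len)))
}

#' Greedy redundancy removal
#'
#' Alignment-free stand-in for greedy sequence clustering as done by
#' redundancy-reduction tools: sequences are processed longest first (ties
#' broken by input order); each sequence is compared against the
#' already-retained representatives and absorbed when its identity to any of
#' them reaches `identity`, otherwise it becomes a new representative.
#' Identity between two sequences is the fraction of shared canonical 8-mers
#' (a word and its reverse complement count as one) relative to the distinct
#' 8-mer set of the shorter sequence. When a `cd-hit-est` executable is
#' available on the PATH and `use_cdhit = TRUE`, that program is used instead.
#'
#' @param ts A non-empty [transcript_set()].
#' @param identity Identity threshold in (0, 1]; default 0.9.
#' @param word_size k-mer length for the identity measure (default 8).
#' @param use_cdhit If `TRUE` and `cd-hit-est` is installed, shell out to it.
#' @return The deduplicated `transcript_set` (representatives in retained
#'   order), provenance extended.
#' @export
dedup_redundant <- function(ts, identity = 0.9, word_size = 8L,
                            use_cdhit = FALSE) {
  stopifnot(inherits(ts, "transcript_set"))
  if (nrow(ts) == 0L) stop("empty transcript_set")
  if (!is.numeric(identity) || identity <= 0 || identity > 1) {
    stop("'identity' must be in (0, 1]")
  }
  n0 <- nrow(ts)
  if (use_cdhit && nzchar(Sys.which("cd-hit-est"))) {
    keep_ids <- cdhit_est_ids(ts, identity)
    out <- ts[match(keep_ids, ts$id), , drop = FALSE]
  } else {
    ord <- order(-nchar(ts$seq))         # longest first, stable in ties
    ## inverted index code -> representative ids gives every candidate its
    ## exact intersection size with all retained representatives in one pass
    idx <- new.env(hash = TRUE, parent = emptyenv())
    seen <- new.env(hash = TRUE, parent = emptyenv())
    reps <- integer(0)
    sizes <- integer(0)
    for (i in ord) {
      if (!is.null(seen[[ts$seq[i]]])) next          # byte-identical duplicate
      codes <- canonical_kmer_set(ts$seq[i], k = word_size)
      absorbed <- FALSE
      if (length(codes)) {
        keys <- as.character(codes)
        hits <- unlist(mget(keys, envir = idx, ifnotfound = list(integer(0))),
                       use.names = FALSE)
        if (length(hits)) {
          shared <- tabulate(hits, nbins = length(reps))
          denom <- pmax(pmin(length(codes), sizes), 1L)
          absorbed <- any(shared / denom >= identity)
        }
      }
      if (!absorbed) {
        reps <- c(reps, i)
        sizes <- c(sizes, length(codes))
        seen[[ts$seq[i]]] <- TRUE
        r <- length(reps)
        for (k in as.character(codes)) idx[[k]] <- c(idx[[k]], r)
      }
    }
    out <- ts[reps, , drop = FALSE]
  }
  class(out) <- class(ts)
  attr(out, "provenance") <- provenance(ts)
  add_provenance(out, "dedup_redundant", n0, list(identity = identity))
}

## distinct canonical k-mers of one sequence as base-4 integer codes
## (k-mers containing N dropped); canonical = min(code, revcomp code)
canonical_kmer_set <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  v <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  nw <- n - k + 1L
  shifted <- vapply(0:(k - 1L), function(j) v[(1L + j):(nw + j)], numeric(nw))
  if (nw == 1L) shifted <- matrix(shifted, nrow = 1L)
  fwd <- drop(shifted %*% 4^((k - 1L):0))          # N (NA) propagates
  rc <- drop((3 - shifted) %*% 4^(0:(k - 1L)))
  codes <- pmin(fwd, rc)
  unique(codes[!is.na(codes)])
}

cdhit_est_ids <- function(ts, identity) {
  td <- tempfile("cdhit")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fin <- file.path(td, "in.fa"); fout <- file.path(td, "out.fa")
  write_fasta(ts, fin)
  status <- system2("cd-hit-est", c("-i", fin, "-o", fout, "-c", identity, "-d", "0"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("cd-hit-est failed with status ", status)
  read_fasta(fout)$id
}

#' Balance classes by down-sampling
#'
#' Randomly down-samples the majority class without replacement to the size of
#' the minority class. The minority class is untouched; the same seed always
#' yields the same record set, and the original record order is preserved.
#'
#' @param ts A fully labeled [transcript_set()] containing both classes.
#' @param seed Integer seed for the down-sampling draw.
#' @return A class-balanced `transcript_set`, provenance extended.
#' @export
balance_downsample <- function(ts, seed) {
  stopifnot(inherits(ts, "transcript_set"))
  if (anyNA(ts$label)) {
    stop("balance_downsample requires a label on every record; ",
         sum(is.na(ts$label)), " record(s) unlabeled")
  }
  cls <- unique(ts$label)
  if (length(cls) < 2L) stop("both classes must be present; found only: ", cls)
  n0 <- nrow(ts)
  counts <- table(ts$label)
  n_min <- min(counts)
  keep <- logical(nrow(ts))
  for (cl in names(counts)) {
    idx <- which(ts$label == cl)
    if (length(idx) > n_min) {
      idx <- with_seed(seed, sort(sample(idx, n_min)))
    }
    keep[idx] <- TRUE
  }
  out <- ts[keep, , drop = FALSE]
  class(out) <- class(ts)
  attr(out, "provenance") <- provenance(ts)
  add_provenance(out, "balance_downsample", n0, list(seed = as.integer(seed)))
}
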