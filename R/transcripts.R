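#' Transcript sets
#'
#' A `transcript_set` is the container every pipeline stage consumes and
#' produces: a set of transcript records (identifier, sanitized DNA sequence,
#' optional class label) together with a provenance log describing each
#' processing stage and the record counts before and after it.
#'
#' @param id Character vector of unique, non-empty record identifiers.
#' @param seq Character vector of sequences over `A,C,G,T,N` (sanitized with
#'   [sanitize_seq()] if not already).
#' @param label Optional character vector of class labels (`"lncRNA"` or
#'   `"PCT"`); `NA` where unknown.
#' @param provenance List of provenance entries (each a named list); normally
#'   left empty and grown by the pipeline stages.
#' @return An object of class `transcript_set`: a data frame with columns
#'   `id`, `seq`, `label` and a `provenance` attribute.
#' @examples
#' ts <- transcript_set(c("t1", "t2"), c("ACGTACGT", "AACCGGTT"))
#' nrow(ts)
#' @export
transcript_set <- function(id, seq, label = NULL, provenance = list()) {
  id <- as.character(id)
  seq <- sanitize_seq(as.character(seq))
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length")
  }
  if (any(!nzchar(id))) stop("empty transcript identifier")
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate transcript identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(label)) label <- rep(NA_character_, length(id))
  label <- as.character(label)
  if (length(label) != length(id)) stop("'label' length mismatch")
  bad <- !is.na(label) & !label %in% c("lncRNA", "PCT")
  if (any(bad)) {
    stop("labels must be 'lncRNA' or 'PCT'; got: ",
         paste(unique(label[bad]), collapse = ", "))
  }
  x <- data.frame(id = id, seq = seq, label = label, stringsAsFactors = FALSE)
  class(x) <- c("transcript_set", "data.frame")
  attr(x, "provenance") <- provenance
  x
}

#' Sanitize nucleotide sequences
#'
#' Uppercases, maps `U` to `T` (RNA input accepted) and collapses every other
#' character outside `A,C,G,T` (IUPAC ambiguity codes, gaps, whitespace
#' remnants) to `N`.
#'
#' @param seq Character vector of raw sequences.
#' @return Character vector over the alphabet `A,C,G,T,N`.
#' @examples
#' sanitize_seq("acgu")   # "ACGT"
#' sanitize_seq("AcRtN-") # "ACNTN" with the gap mapped to N
#' @export
sanitize_seq <- function(seq) {
  s <- toupper(seq)
  s <- chartr("U", "T", s)
  gsub("[^ACGT]", "N", s)
}

#' @export
print.transcript_set <- function(x, ...) {
  nl <- table(factor(x$label, levels = c("lncRNA", "PCT")), useNA = "ifany")
  cat(sprintf("transcript_set: %d record(s)\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  lengths: %d-%d nt; labels: lncRNA=%d PCT=%d unlabeled=%d\n",
                min(nchar(x$seq)), max(nchar(x$seq)),
                nl[["lncRNA"]], nl[["PCT"]], sum(is.na(x$label))))
  }
  pv <- provenance(x)
  if (length(pv)) {
    cat("  provenance:\n")
    for (e in pv) {
      cat(sprintf("    %s: %d -> %d\n", e$stage, e$n_before, e$n_after))
    }
  }
  invisible(x)
}

#' Provenance log of a transcript set
#'
#' @param x A `transcript_set`.
#' @return The list of provenance entries recorded so far; each entry has at
#'   least `stage`, `n_before` and `n_after`.
#' @export
provenance <- function(x) {
  stopifnot(inherits(x, "transcript_set"))
  attr(x, "provenance") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## append one stage entry, keeping counts consistent with the record table
add_provenance <- function(x, stage, n_before, extra = list()) {
  pv <- provenance(x)
  pv[[length(pv) + 1L]] <- c(list(stage = stage, n_before = n_before,
                                  n_after = nrow(x)), extra)
  attr(x, "provenance") <- pv
  x
}

## run code with a private, restorable RNG state so library calls never
## perturb the caller's stream; Mersenne-Twister + Rejection sampling pinned
## for cross-platform reproducibility
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  code
}
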