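#' Assemble a per-transcript feature table
#'
#' Computes one feature vector per transcript and stacks them into a labeled
#' table. The `"integrated35"` set is the 35-dimensional representation:
#' sequence length and four ORF features ([orf_feature_block()]) followed by
#' the 30-value information-theory block ([entropy_feature_block()]). The
#' `"kmer84"` set is the 84-feature k-mer baseline ([kmer_feature_block()]).
#'
#' @param ts A [transcript_set()]; sequences must satisfy the per-feature
#'   minimum lengths (guaranteed after [filter_short()] at 200 nt).
#' @param feature_set `"integrated35"` or `"kmer84"`.
#' @param cfg An [entropy_config()] (integrated set only).
#' @return A `feature_table`: data frame with columns `id`, `label`, then the
#'   feature columns in fixed order; attributes `feature_set` and `schema`.
#' @export
build_feature_table <- function(ts, feature_set = c("integrated35", "kmer84"),
                                cfg = entropy_config()) {
  stopifnot(inherits(ts, "transcript_set"))
  feature_set <- match.arg(feature_set)
  rows <- lapply(seq_len(nrow(ts)), function(i) {
    tryCatch({
      if (feature_set == "integrated35") {
        c(orf_feature_block(ts$seq[i]), entropy_feature_block(ts$seq[i], cfg))
      } else {
        kmer_feature_block(ts$seq[i])
      }
    }, error = function(e) {
      stop("feature extraction failed for transcript '", ts$id[i], "': ",
           conditionMessage(e), call. = FALSE)
    })
  })
  mat <- do.call(rbind, rows)
  if (any(!is.finite(mat))) {
    bad <- which(rowSums(!is.finite(mat)) > 0)[1]
    stop("non-finite feature value for transcript '", ts$id[bad], "'")
  }
  out <- data.frame(id = ts$id, label = ts$label, mat,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  structure(out, class = c("feature_table", "data.frame"),
            feature_set = feature_set, schema = colnames(mat))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d transcripts x %d features\n",
              attr(x, "feature_set"), nrow(x), length(feature_schema(x))))
  NextMethod()
}

#' Feature column names of a feature table
#'
#' @param x A `feature_table`.
#' @return Character vector of feature column names, in table order.
#' @export
feature_schema <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  attr(x, "schema")
}

## numeric feature matrix + 0/1 response (lncRNA is the positive class)
feature_matrix <- function(x) {
  m <- as.matrix(x[, feature_schema(x), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$id
  m
}

#' Write / read a feature table as CSV
#'
#' The CSV starts with an optional `#` header comment, then a header row
#' `id,label,<features...>`. Rebuilding the same table from the same inputs
#' and configuration yields a byte-identical file.
#'
#' @param x A `feature_table`.
#' @param path CSV path.
#' @param comment Optional single header-comment line (written prefixed with
#'   `"# "`).
#' @return `write_feature_table`: invisibly, `path`. `read_feature_table`:
#'   the `feature_table`.
#' @export
write_feature_table <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "feature_table"))
  con <- file(path, open = "wb")                 # "wb": byte-stable newlines
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(paste(c("id", "label", feature_schema(x)), collapse = ","), con)
  vals <- apply(feature_matrix(x), 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  writeLines(paste(x$id, ifelse(is.na(x$label), "", x$label), vals, sep = ","), con)
  invisible(path)
}

#' @rdname write_feature_table
#' @param feature_set Declared feature set of the file being read.
#' @export
read_feature_table <- function(path, feature_set = c("integrated35", "kmer84")) {
  feature_set <- match.arg(feature_set)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    stop("feature CSV must contain 'id' and 'label' columns: ", path)
  }
  schema <- setdiff(names(df), c("id", "label"))
  expected <- if (feature_set == "integrated35") 35L else 84L
  if (length(schema) != expected) {
    stop("expected ", expected, " feature columns for ", feature_set,
         ", found ", length(schema))
  }
  df$label <- as.character(df$label)
  df$label[is.na(df$label) | !nzchar(df$label)] <- NA_character_
  structure(df, class = c("feature_table", "data.frame"),
            feature_set = feature_set, schema = schema)
}
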