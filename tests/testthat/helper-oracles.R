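# Independent reference implementations used to validate the package's
# entropy, ORF and ranking computations. Deliberately naive: plain loops and
# direct definitions, sharing no code path with the package internals.

BASES4 <- c("A", "C", "G", "T")

random_seq <- function(len, probs = rep(0.25, 4), n_rate = 0) {
  alph <- BASES4
  p <- probs
  if (n_rate > 0) {
    alph <- c(alph, "N")
    p <- c(probs * (1 - n_rate), n_rate)
  }
  paste(sample(alph, len, replace = TRUE, prob = p), collapse = "")
}

## enumerate all length-L substrings of the first window_len characters,
## count, skip N-windows
oracle_word_counts <- function(seq, L, window_len = nchar(seq)) {
  wl <- min(window_len, nchar(seq))
  counts <- list()
  if (wl < L) return(numeric(0))
  for (i in 1:(wl - L + 1)) {
    w <- substr(seq, i, i + L - 1)
    if (grepl("N", w, fixed = TRUE)) next
    counts[[w]] <- (if (is.null(counts[[w]])) 0 else counts[[w]]) + 1
  }
  unlist(counts)
}

oracle_n_omega <- function(len) {
  best <- NA_integer_
  for (n in 1:12) if (4^n + n - 1 <= len) best <- n
  best
}

oracle_threshold <- function(len, L, modified, mode) {
  if (!modified) return(0)
  if (mode == "literal") 4^oracle_n_omega(len) / len else 4^L / len
}

oracle_te <- function(seq, n, modified = TRUE, mode = "literal") {
  wl <- min(4^n + n - 1, nchar(seq))
  cnt <- oracle_word_counts(seq, n, wl)
  thr <- oracle_threshold(nchar(seq), n, modified, mode)
  p <- max(sum(cnt >= thr), 1)
  log(p, base = 4) / n
}

oracle_gte <- function(seq, k, modified = TRUE, mode = "literal") {
  nw <- oracle_n_omega(nchar(seq))
  k <- min(k, nw)
  wl <- min(4^nw + nw - 1, nchar(seq))
  terms <- numeric(0)
  for (i in (nw - k + 1):nw) {
    cnt <- oracle_word_counts(seq, i, wl)
    thr <- oracle_threshold(nchar(seq), i, modified, mode)
    p <- max(sum(cnt >= thr), 1)
    terms <- c(terms, log(p, base = 4) / i)
  }
  mean(terms)
}

oracle_mi <- function(seq, g) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  joint <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
  for (i in 1:(n - g)) {
    x <- ch[i]; y <- ch[i + g]
    if (x == "N" || y == "N") next
    joint[x, y] <- joint[x, y] + 1
  }
  if (sum(joint) == 0) return(0)
  f <- joint / sum(joint)
  mi <- 0
  for (x in BASES4) for (y in BASES4) {
    if (f[x, y] > 0) {
      mi <- mi + f[x, y] * log(f[x, y] / (sum(f[x, ]) * sum(f[, y])), base = 4)
    }
  }
  mi
}

## all maximal ATG->stop ORFs, built from stop-delimited segments per frame
oracle_orfs <- function(seq) {
  n <- nchar(seq)
  res <- NULL
  for (f in 0:2) {
    if (n - f < 3) next
    starts <- seq(f + 1, n - 2, by = 3)
    codons <- substring(seq, starts, starts + 2)
    stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
    seg_start <- 1
    for (s in stop_idx) {
      if (seg_start <= s - 1) {
        seg <- seg_start:(s - 1)
        atg <- seg[codons[seg] == "ATG"]
        if (length(atg)) {
          a <- atg[1]
          res <- rbind(res, data.frame(start = starts[a] - 1, end = starts[s] + 2,
                                       frame = f,
                                       length_nt = starts[s] + 2 - starts[a] + 1))
        }
      }
      seg_start <- s + 1
    }
  }
  if (is.null(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length_nt = integer(0)))
  }
  res <- res[order(res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## pair-counting AUC: P(score+ > score-) + 0.5 P(score+ = score-)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## direct precision/recall at every distinct threshold, step-wise area
oracle_aupr <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_r <- 0
  area <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    prec <- tp / sum(called)
    rec <- tp / P
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

## de Bruijn cycle over ACGT by the standard FKM (Lyndon word) construction,
## linearized with an (n-1)-character wrap
de_bruijn_seq <- function(n) {
  k <- 4
  a <- integer(k * n + 1)
  out <- integer(0)
  gen <- function(t, p) {
    if (t > n) {
      if (n %% p == 0) out <<- c(out, a[2:(p + 1)])
    } else {
      a[t + 1] <<- a[t - p + 1]
      gen(t + 1, p)
      j <- a[t - p + 1] + 1
      while (j <= k - 1) {
        a[t + 1] <<- j
        gen(t + 1, t)
        j <- j + 1
      }
    }
  }
  gen(1, 1)
  cyc <- BASES4[out + 1]
  paste(c(cyc, cyc[seq_len(n - 1)]), collapse = "")
}

## construct a feature_table directly from a matrix (for classifier tests
## that need full control over the signal)
make_feature_table <- function(X, labels, feature_set = "integrated35") {
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  df <- data.frame(id = sprintf("r%04d", seq_len(nrow(X))),
                   label = labels, X, stringsAsFactors = FALSE,
                   check.names = FALSE)
  structure(df, class = c("feature_table", "data.frame"),
            feature_set = feature_set, schema = colnames(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
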