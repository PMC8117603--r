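#' Specification of the two-class synthetic transcript generator
#'
#' Defines the generative conditions for a labeled benchmark set with two
#' separable classes: "coding-like" transcripts (class `PCT`) carrying one
#' embedded ATG-to-stop ORF with codon-position composition bias, and
#' "noncoding-like" transcripts (class `lncRNA`) drawn from a low-order
#' Markov background. Lengths are log-uniform on `[min_len, max_len]`, so
#' the generated sets always pass the 200 nt pipeline filter.
#'
#' @param n_per_class Transcripts per class (default 500).
#' @param min_len,max_len Length bounds in nt (defaults 200 and 3000;
#'   `min_len` must be at least 200).
#' @param coding_orf_rel Target relative length of the embedded ORF: a range
#'   to draw from per transcript (default `c(0.5, 0.9)`) or a single value.
#' @param coding_codon_bias Strength of the codon-position composition bias
#'   inside the ORF, in `[0, 1]` (default 0.5; 0 = uniform codon usage).
#' @param noncoding_markov_order Background model order, 0, 1 or 2
#'   (default 1).
#' @param background_freq Stationary base composition of the background,
#'   named `A,C,G,T` (default mildly AT-rich, as for human transcripts).
#' @param noise Fraction of labels swapped after generation (default 0).
#' @param seed Integer seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 500L, min_len = 200L, max_len = 3000L,
                           coding_orf_rel = c(0.5, 0.9),
                           coding_codon_bias = 0.5,
                           noncoding_markov_order = 1L,
                           background_freq = c(A = 0.28, C = 0.22, G = 0.22, T = 0.28),
                           noise = 0, seed = 1L) {
  if (n_per_class < 1L) stop("'n_per_class' must be >= 1")
  if (min_len < 200L) stop("'min_len' must be >= 200 (the pipeline length filter)")
  if (max_len < min_len) stop("'max_len' must be >= 'min_len'")
  rng <- range(coding_orf_rel)
  if (rng[1] <= 0 || rng[2] > 0.95) {
    stop("'coding_orf_rel' must lie in (0, 0.95]: the ORF must fit inside the transcript")
  }
  if (min_len * rng[1] < 9) stop("'coding_orf_rel' too small for 'min_len': ORF below 3 codons")
  if (coding_codon_bias < 0 || coding_codon_bias > 1) stop("'coding_codon_bias' must be in [0, 1]")
  if (!noncoding_markov_order %in% 0:2) stop("'noncoding_markov_order' must be 0, 1 or 2")
  if (noise < 0 || noise > 1) stop("'noise' must be in [0, 1]")
  stopifnot(identical(names(background_freq), c("A", "C", "G", "T")),
            all(background_freq > 0))
  structure(list(n_per_class = as.integer(n_per_class),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 coding_orf_rel = rng, coding_codon_bias = coding_codon_bias,
                 noncoding_markov_order = as.integer(noncoding_markov_order),
                 background_freq = background_freq / sum(background_freq),
                 noise = noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

BASES <- c("A", "C", "G", "T")

## CpG-depleted transition matrix built around the stationary composition;
## order 2 adds a mild homopolymer tendency on top
transition_matrix <- function(freq, order) {
  tm <- matrix(rep(freq, each = 4), 4, 4, dimnames = list(BASES, BASES))
  tm["C", "G"] <- tm["C", "G"] * 0.25
  if (order >= 2L) diag(tm) <- diag(tm) * 1.3
  tm / rowSums(tm)
}

## one background fragment, consuming the caller's RNG stream
bg_fragment <- function(n, spec) {
  if (n <= 0L) return("")
  freq <- spec$background_freq
  if (spec$noncoding_markov_order == 0L) {
    return(paste(sample(BASES, n, replace = TRUE, prob = freq), collapse = ""))
  }
  tm <- transition_matrix(freq, spec$noncoding_markov_order)
  cum <- t(apply(tm, 1L, cumsum))
  out <- character(n)
  out[1L] <- sample(BASES, 1L, prob = freq)
  if (n > 1L) {
    u <- stats::runif(n - 1L)
    for (i in 2:n) {
      out[i] <- BASES[findInterval(u[i - 1L], cum[out[i - 1L], ]) + 1L]
    }
  }
  paste(out, collapse = "")
}

## 61 sense codons with position-specific composition bias mixed in
codon_weights <- function(bias) {
  p1 <- c(A = 0.30, C = 0.20, G = 0.33, T = 0.17)
  p2 <- c(A = 0.31, C = 0.23, G = 0.19, T = 0.27)
  p3 <- c(A = 0.16, C = 0.30, G = 0.30, T = 0.24)
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  codons <- sort(codons)
  keep <- !codons %in% c("TAA", "TAG", "TGA")
  codons <- codons[keep]
  prof <- vapply(strsplit(codons, ""), function(ch) p1[ch[1]] * p2[ch[2]] * p3[ch[3]],
                 numeric(1))
  w <- (1 - bias) / length(codons) + bias * prof / sum(prof)
  stats::setNames(w / sum(w), codons)
}

gen_lengths <- function(spec, count) {
  round(exp(stats::runif(count, log(spec$min_len), log(spec$max_len))))
}

gen_coding_impl <- function(spec, count, offset = 0L) {
  if (count == 0L) return(transcript_set(character(0), character(0)))
  w <- codon_weights(spec$coding_codon_bias)
  lens <- gen_lengths(spec, count)
  seqs <- character(count)
  for (i in seq_len(count)) {
    len <- lens[i]
    rel <- stats::runif(1, spec$coding_orf_rel[1], spec$coding_orf_rel[2])
    n_codon <- max(3L, round(rel * len / 3))
    n_codon <- min(n_codon, len %/% 3L)
    orf <- paste0("ATG",
                  paste(sample(names(w), n_codon - 2L, replace = TRUE, prob = w),
                        collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    flank <- len - 3L * n_codon
    up <- sample.int(flank + 1L, 1L) - 1L
    upseq <- bg_fragment(up, spec)
    if (up >= 3L) {
      # close the reading frame upstream so the embedded ORF cannot be
      # extended by a chance in-frame ATG in the flank
      substr(upseq, up - 2L, up) <- sample(c("TAA", "TAG", "TGA"), 1L)
    }
    seqs[i] <- paste0(upseq, orf, bg_fragment(flank - up, spec))
  }
  transcript_set(sprintf("pct_%05d", offset + seq_len(count)), seqs,
                 rep("PCT", count))
}

gen_noncoding_impl <- function(spec, count, offset = 0L) {
  if (count == 0L) return(transcript_set(character(0), character(0)))
  lens <- gen_lengths(spec, count)
  seqs <- vapply(lens, bg_fragment, character(1), spec = spec)
  transcript_set(sprintf("lnc_%05d", offset + seq_len(count)), seqs,
                 rep("lncRNA", count))
}

#' Generate coding-like transcripts
#'
#' Each transcript embeds one ATG-to-stop ORF of approximately
#' `coding_orf_rel` times the transcript length (interior stop-free by
#' construction, codon-position bias applied) at a random position, flanked
#' by background sequence. Labeled `PCT`.
#'
#' @param spec A [synthetic_spec()].
#' @param count Number of transcripts (default `spec$n_per_class`).
#' @return A [transcript_set()]; identical for identical spec seeds.
#' @export
generate_coding_like <- function(spec, count = spec$n_per_class) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ts <- with_seed(spec$seed, gen_coding_impl(spec, count))
  add_provenance(ts, "generate_coding_like", nrow(ts), list(seed = spec$seed))
}

#' Generate noncoding-like transcripts
#'
#' Background Markov chain of the configured order with no deliberately
#' embedded ORF. Labeled `lncRNA`.
#'
#' @inheritParams generate_coding_like
#' @return A [transcript_set()]; identical for identical spec seeds.
#' @export
generate_noncoding_like <- function(spec, count = spec$n_per_class) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ts <- with_seed(spec$seed, gen_noncoding_impl(spec, count))
  add_provenance(ts, "generate_noncoding_like", nrow(ts), list(seed = spec$seed))
}

#' Generate the full labeled two-class dataset
#'
#' `n_per_class` transcripts of each class, shuffled, with label noise (an
#' exact count of `round(noise * 2 * n_per_class)` swapped labels) applied
#' last. Fully determined by `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [transcript_set()] of `2 * n_per_class` records whose provenance
#'   records the generator parameters.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ts <- with_seed(spec$seed, {
    coding <- gen_coding_impl(spec, spec$n_per_class)
    noncoding <- gen_noncoding_impl(spec, spec$n_per_class)
    all_id <- c(coding$id, noncoding$id)
    all_seq <- c(coding$seq, noncoding$seq)
    all_lab <- c(coding$label, noncoding$label)
    ord <- sample(length(all_id))
    lab <- all_lab[ord]
    n_flip <- round(spec$noise * length(lab))
    if (n_flip > 0L) {
      flip <- sample(length(lab), n_flip)
      lab[flip] <- ifelse(lab[flip] == "PCT", "lncRNA", "PCT")
    }
    transcript_set(all_id[ord], all_seq[ord], lab)
  })
  add_provenance(ts, "generate_dataset", nrow(ts), list(spec = unclass(spec)))
}
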