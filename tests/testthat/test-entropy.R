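unmod <- entropy_config(modified = FALSE)

test_that("supported word scale follows the window inequality", {
  # independently enumerate the largest n with 4^n + n - 1 <= len
  for (len in c(4, 20, 66, 67, 200, 258, 259, 1027, 1028, 3000)) {
    expect_equal(n_omega(len), oracle_n_omega(len), info = paste("len", len))
  }
  expect_equal(n_omega(66), 3)
  expect_equal(n_omega(200), 3)
  expect_equal(n_omega(259), 4)   # boundary: largest admissible n wins
  expect_error(n_omega(3), "no word scale")
})

test_that("subword spectra count overlapping words and skip N windows", {
  sp <- subword_spectrum("AAAA", 3)
  expect_equal(sp$counts, c(AAA = 2L))
  sp2 <- subword_spectrum(strrep("ACGT", 50), 3, window_len = 66)
  expect_setequal(names(sp2$counts), c("ACG", "CGT", "GTA", "TAC"))
  expect_equal(sum(sp2$counts), 64)
  sp3 <- subword_spectrum("ACNGT", 2)
  expect_equal(sp3$counts[order(names(sp3$counts))], c(AC = 1L, GT = 1L))
  expect_error(subword_spectrum("ACG", 4), "exceeds")
})

test_that("distinct-word counting honors the occurrence threshold", {
  sp <- subword_spectrum("AAAA", 3)
  expect_equal(distinct_count(sp, 0), 1)
  sp2 <- subword_spectrum(paste0(strrep("AC", 3), strrep("GT", 5)), 2)
  expect_equal(distinct_count(sp2, 3), 3)      # AC(3), GT(5), TG(4) pass; CA(2), CG(1) fail
  expect_equal(distinct_count(sp2, 100), 0)
})

test_that("topological entropy closed forms hold", {
  expect_equal(topological_entropy(strrep("A", 200), 3), 0)
  db <- de_bruijn_seq(3)                      # 66 nt, all 64 trinucleotides
  expect_equal(nchar(db), 66)
  expect_equal(length(oracle_word_counts(db, 3, 66)), 64)
  expect_equal(topological_entropy(db, 3, unmod), 1)
  expect_equal(topological_entropy(strrep("ACGT", 50), 3, unmod), 1 / 3)
  expect_error(topological_entropy("ACG", 4), "exceeds")
})

test_that("generalized topological entropy closed forms and clamping hold", {
  expect_equal(as.numeric(generalized_topological_entropy(strrep("A", 300), 3)), 0)
  s66 <- substr(strrep("ACGT", 17), 1, 66)
  expect_equal(as.numeric(generalized_topological_entropy(s66, 3, unmod)), 11 / 18)
  set.seed(42)
  for (len in c(200, 500, 1100)) {
    s <- random_seq(len)
    gte1 <- generalized_topological_entropy(s, 1, unmod)
    expect_equal(as.numeric(gte1),
                 topological_entropy(s, n_omega(len), unmod),
                 tolerance = 1e-14)
  }
  # k above the supported scale (n_omega = 3 at 200 nt) is clamped and flagged
  s200 <- random_seq(200)
  g5 <- generalized_topological_entropy(s200, 5, unmod)
  expect_true(attr(g5, "clamped"))
  expect_equal(as.numeric(g5),
               as.numeric(generalized_topological_entropy(s200, 3, unmod)))
  expect_error(generalized_topological_entropy("ACG", 2), "too short")
})

test_that("entropies match the naive enumeration oracle on random sequences", {
  set.seed(101)
  for (rep in 1:40) {
    len <- sample(200:1500, 1)
    s <- random_seq(len, n_rate = if (rep %% 5 == 0) 0.02 else 0)
    for (modified in c(TRUE, FALSE)) {
      for (mode in c("literal", "per_length")) {
        cfg <- entropy_config(modified = modified, threshold_mode = mode)
        n <- sample(3:5, 1)
        k <- sample(3:5, 1)
        expect_equal(topological_entropy(s, n, cfg),
                     oracle_te(s, n, modified, mode), tolerance = 1e-12)
        expect_equal(as.numeric(generalized_topological_entropy(s, k, cfg)),
                     oracle_gte(s, k, modified, mode), tolerance = 1e-12)
      }
    }
  }
})

test_that("the repetition modification can only lower the entropy", {
  set.seed(55)
  for (rep in 1:25) {
    s <- random_seq(sample(200:800, 1))
    for (mode in c("literal", "per_length")) {
      cfg <- entropy_config(modified = TRUE, threshold_mode = mode)
      for (n in 3:5) {
        expect_lte(topological_entropy(s, n, cfg),
                   topological_entropy(s, n, unmod) + 1e-14)
      }
      for (k in 3:5) {
        expect_lte(as.numeric(generalized_topological_entropy(s, k, cfg)),
                   as.numeric(generalized_topological_entropy(s, k, unmod)) + 1e-14)
      }
    }
  }
})

test_that("block Shannon entropy matches hand-computed values", {
  expect_equal(shannon_block_entropy("ACGTACGTACGT", 1), 1)
  expect_equal(shannon_block_entropy("AAAA", 2), 0)
  expect_equal(shannon_block_entropy("AACC", 1), 0.5)
  expect_equal(shannon_block_entropy("NNNN", 2), 0)   # no valid window
  expect_error(shannon_block_entropy("AC", 3), "exceeds")
})

test_that("gapped mutual information matches the direct estimator", {
  expect_equal(gapped_mutual_information(strrep("A", 100), 5), 0)
  s <- strrep("AC", 100)
  expect_equal(gapped_mutual_information(s, 1), oracle_mi(s, 1), tolerance = 1e-14)
  expect_equal(gapped_mutual_information(s, 1), 0.5, tolerance = 1e-3)
  set.seed(9)
  for (rep in 1:10) {
    s <- random_seq(sample(50:300, 1), n_rate = 0.05)
    g <- sample(1:17, 1)
    expect_equal(gapped_mutual_information(s, g), oracle_mi(s, g), tolerance = 1e-13)
  }
  expect_error(gapped_mutual_information("ACGT", 4), "no pair")
})

test_that("mutual information is invariant under sequence reversal", {
  set.seed(13)
  for (rep in 1:10) {
    s <- random_seq(300)
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    for (g in c(1, 5, 17)) {
      expect_equal(gapped_mutual_information(s, g),
                   gapped_mutual_information(r, g), tolerance = 1e-13)
    }
  }
})

test_that("iid uniform sequences carry vanishing mutual information", {
  set.seed(77)
  s <- random_seq(1e5)
  expect_lt(gapped_mutual_information(s, 7), 0.02)
})

test_that("KL divergence block behaves at its reference distributions", {
  expect_equal(kl_divergence_block(strrep("A", 100), 1), 1)
  expect_equal(kl_divergence_block(strrep("A", 100), 2), 0)
  expect_equal(kl_divergence_block(strrep("ACGT", 50), 1), 0)
  set.seed(21)
  expect_gte(kl_divergence_block(random_seq(500, c(.4, .1, .1, .4)), 3), 0)
})

test_that("the 30-entry feature block has fixed order, range and determinism", {
  set.seed(31)
  s <- random_seq(700)
  v <- entropy_feature_block(s)
  expect_length(v, 30)
  expect_equal(names(v)[1:4], paste0("SE", 1:4))
  expect_equal(names(v)[5:10], c("TE3", "TE4", "TE5", "GTE3", "GTE4", "GTE5"))
  expect_equal(names(v)[11:27], paste0("MI", 1:17))
  expect_equal(names(v)[28:30], paste0("KLD", 1:3))
  expect_true(all(is.finite(v)))
  expect_true(all(v[1:10] >= 0 & v[1:10] <= 1))   # SE/TE/GTE in [0,1]
  expect_true(all(v[11:30] >= -1e-14))            # MI/KLD nonnegative
  expect_identical(v, entropy_feature_block(s))

  h <- entropy_feature_block(strrep("A", 1100))
  expect_equal(unname(h[["KLD1"]]), 1)
  expect_equal(unname(h[setdiff(names(h), "KLD1")]),
               rep(0, 29), tolerance = 1e-14)

  expect_error(entropy_feature_block(strrep("A", 17)), "18 nt")
})
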