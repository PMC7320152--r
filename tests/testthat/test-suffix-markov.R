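test_that("suffix counts match hand enumeration", {
  # [S, D, M] at depth 2: one window, N((S,D)) = 1 with M following
  co <- corpus_from_label_sequences(list(c("S", "D", "M")),
                                    alphabet = c("S", "D", "M"))
  tr <- build_suffix_tree(co, 2)
  expect_equal(tr$total_tuples, 1L)
  expect_equal(unname(tr$counts["S:D", "M"]), 1L)
  expect_equal(sum(tr$counts), 1L)
  expect_equal(format_suffix("S:D"), "DS")  # printed newest-first

  # [A,B,A,B,A] at depth 1: 4 windows, N((A))=2 all to B, N((B))=2 all to A
  co2 <- corpus_from_label_sequences(list(c("A", "B", "A", "B", "A")))
  tr2 <- build_suffix_tree(co2, 1)
  expect_equal(unname(tr2$counts["A", "B"]), 2L)
  expect_equal(unname(tr2$counts["B", "A"]), 2L)
  expect_equal(tr2$total_tuples, 4L)

  # depth 0: single empty suffix, conditional counts = label frequencies
  tr0 <- build_suffix_tree(co2, 0)
  expect_equal(nrow(tr0$counts), 1L)
  expect_equal(unname(tr0$counts[1, ]), c(3L, 2L))
})

test_that("windows never span sequence boundaries and short sequences drop out", {
  co <- corpus_from_label_sequences(list(c("A", "B"), c("B", "A", "A"), "A"))
  tr <- build_suffix_tree(co, 2)
  # only the length-3 sequence contributes a single (D+1)-window
  expect_equal(tr$total_tuples, 1L)
  expect_equal(unname(tr$counts["B:A", "A"]), 1L)
  # but all syllables count toward the corpus-wide label frequencies
  expect_equal(sum(tr$zero_counts), 6L)
})

test_that("tree construction rejects bad input and oversized tables", {
  df <- grid_syllables(3)
  df$label <- c("A", NA, "B")
  co <- segment_into_sequences(df, alphabet = c("A", "B"))
  expect_error(build_suffix_tree(co, 1), "labeled")
  co2 <- corpus_from_label_sequences(list(letters[1:10]))
  expect_error(build_suffix_tree(co2, 2, max_cells = 100), "cap")
})

test_that("entropy rate matches the printed worked examples", {
  # two-label 0th-order with pmf (0.43, 0.57): H = 0.9858, printed as 0.98
  m0 <- markov_model(matrix(c(0.43, 0.57), 1), alphabet = c("J", "N"),
                     depth = 0)
  expect_equal(analytic_entropy_rate(m0),
               -(0.43 * log2(0.43) + 0.57 * log2(0.57)))
  expect_lt(abs(analytic_entropy_rate(m0) - 0.98), 0.01)

  # 1st-order chain p(J|J)=0.64, p(N|N)=0.67 -> 0.93 bits/symbol at 2 dp
  m1 <- markov_model(rbind(c(0.64, 0.36), c(0.33, 0.67)),
                     alphabet = c("J", "N"))
  expect_equal(round(analytic_entropy_rate(m1), 2), 0.93)
  # same value through the plug-in estimator on the exact-count tree
  expect_equal(entropy_rate(as_suffix_tree(m1)), analytic_entropy_rate(m1),
               tolerance = 1e-12)

  # uniform iid over 4 labels is exactly 2 bits at any depth
  co <- corpus_from_label_sequences(
    list(rep(c("a", "b", "c", "d"), times = 8)))
  for (d in 0:2) {
    tr <- build_suffix_tree(co, d)
    expect_lte(entropy_rate(tr), 2 + 1e-12)
  }
  m4 <- markov_model(matrix(0.25, 1, 4), alphabet = letters[1:4], depth = 0)
  expect_equal(analytic_entropy_rate(m4), 2)
})

test_that("plug-in entropy rate and SIS equal brute-force enumeration", {
  set.seed(17)
  for (rep in 1:5) {
    nc <- sample(2:4, 1)
    alpha <- LETTERS[seq_len(nc)]
    seqs <- replicate(40, sample(alpha, sample(3:10, 1), replace = TRUE),
                      simplify = FALSE)
    co <- corpus_from_label_sequences(seqs, alphabet = alpha)
    for (d in 1:2) {
      tr <- build_suffix_tree(co, d)
      expect_equal(entropy_rate(tr), naive_entropy_rate(seqs, d),
                   tolerance = 1e-12)
      expect_equal(sis(tr), naive_mi(seqs, d), tolerance = 1e-12)
      # identity: SIS = H(p_x) - H(X|Y) on the same tuple ensemble
      p_x <- colSums(tr$counts) / tr$total_tuples
      expect_equal(sis(tr),
                   -sum(p_x[p_x > 0] * log2(p_x[p_x > 0])) - entropy_rate(tr),
                   tolerance = 1e-12)
      expect_gte(sis(tr), 0)
      expect_lte(entropy_rate(tr), log2(nc) + 1e-12)
    }
  }
})

test_that("conditional entropy is non-increasing in suffix depth", {
  set.seed(23)
  seqs <- replicate(60, sample(c("A", "B", "C"), sample(4:12, 1),
                               replace = TRUE), simplify = FALSE)
  co <- corpus_from_label_sequences(seqs)
  h <- vapply(0:3, function(d) entropy_rate(build_suffix_tree(co, d)),
              numeric(1))
  expect_true(all(diff(h) <= 1e-12))
})

test_that("SIS is exactly zero on a factorized ensemble and 1 on repetition", {
  # all 4 pairs over a 2-label alphabet equally frequent -> independence
  co <- corpus_from_label_sequences(
    list(c("A", "A"), c("A", "B"), c("B", "A"), c("B", "B")))
  tr <- build_suffix_tree(co, 1)
  expect_identical(sis(tr), 0)
  expect_true(all(sis_contributions(tr) == 0))

  # deterministic repetition with equal tuple mass: SIS = 1 bit
  co2 <- corpus_from_label_sequences(list(rep("A", 5), rep("B", 5)))
  tr2 <- build_suffix_tree(co2, 1)
  expect_equal(sis(tr2), 1.0)
  expect_equal(normalized_sis(tr2), 1.0)
})

test_that("worked pair pmf gives the known contribution values", {
  # pair pmf {AA: 0.4, AB: 0.1, BA: 0.1, BB: 0.4}
  seqs <- c(replicate(4, c("A", "A"), simplify = FALSE),
            list(c("A", "B"), c("B", "A")),
            replicate(4, c("B", "B"), simplify = FALSE))
  co <- corpus_from_label_sequences(seqs)
  tr <- build_suffix_tree(co, 1)
  contrib <- sis_contributions(tr)
  expect_equal(unname(contrib["A", "A"]), 0.4 * log2(0.4 / 0.25))
  expect_equal(round(unname(contrib["A", "A"]), 3), 0.271)
  expect_equal(round(sis(tr), 3), 0.278)
  expect_equal(sum(contrib), sis(tr), tolerance = 1e-9)
  # off-diagonal motifs are under-represented: negative contributions
  expect_lt(contrib["A", "B"], 0)
})

test_that("contributions sum to the SIS at depth 2 as well", {
  set.seed(29)
  seqs <- replicate(50, sample(c("x", "y"), sample(4:9, 1), replace = TRUE),
                    simplify = FALSE)
  co <- corpus_from_label_sequences(seqs)
  tr <- build_suffix_tree(co, 2)
  expect_equal(sum(sis_contributions(tr)), sis(tr), tolerance = 1e-9)
})

test_that("SIS requires a suffix", {
  co <- corpus_from_label_sequences(list(c("A", "B", "A")))
  expect_error(sis(build_suffix_tree(co, 0)), "depth")
})

test_that("validity criterion counts zero cells among all potential tuples", {
  co <- corpus_from_label_sequences(
    list(c("A", "A"), c("A", "B"), c("B", "A"), c("B", "B")))
  expect_true(validity_check(build_suffix_tree(co, 1)))
  # 1 of 4 pairs unobserved: 25% >= 10% -> invalid
  co2 <- corpus_from_label_sequences(
    list(c("A", "A"), c("A", "B"), c("B", "A")))
  expect_false(validity_check(build_suffix_tree(co2, 1)))
  # 52 of 512 triplets unobserved (10.16%) -> invalid; 51 (9.96%) -> valid
  tr <- build_suffix_tree(co, 1)  # template for structure
  mock <- tr
  mock$depth <- 2
  mock$alphabet <- LETTERS[1:8]
  counts <- matrix(1L, 64, 8)
  counts[seq_len(52)] <- 0L
  mock$counts <- counts
  expect_false(validity_check(mock))
  counts[seq_len(52)] <- 1L; counts[seq_len(51)] <- 0L
  mock$counts <- counts
  expect_true(validity_check(mock))
})

test_that("resampled scores are deterministic and degenerate at reps = 1", {
  model <- persistent_markov_model(3, 0.5)
  co <- generate_sequences(model, 200, seed = 7)
  r1 <- resampled_scores(co, 1, reps = 1, seed = 5)
  expect_equal(r1$sd2_entropy, 0)
  expect_equal(r1$sd2_sis, 0)
  a <- resampled_scores(co, 1, reps = 10, seed = 5)
  b <- resampled_scores(co, 1, reps = 10, seed = 5)
  expect_identical(a, b)
  expect_error(resampled_scores(co, 1, frac = 1.2), "frac")
})

test_that("resampling uncertainty shrinks with corpus size", {
  model <- persistent_markov_model(2, 0.6)
  small <- generate_sequences(model, 150, seed = 13)
  big <- generate_sequences(model, 600, seed = 13)
  rs <- resampled_scores(small, 1, reps = 15, seed = 1)
  rb <- resampled_scores(big, 1, reps = 15, seed = 1)
  expect_lt(rb$sd2_entropy, rs$sd2_entropy)
})

test_that("normalized SIS divides by log2(N_c) and rejects tiny alphabets", {
  set.seed(41)
  seqs <- replicate(80, sample(LETTERS[1:8], sample(3:8, 1), replace = TRUE),
                    simplify = FALSE)
  co <- corpus_from_label_sequences(seqs, alphabet = LETTERS[1:8])
  tr <- build_suffix_tree(co, 1)
  expect_equal(normalized_sis(tr), sis(tr) / 3)
  one <- build_suffix_tree(corpus_from_label_sequences(list(rep("A", 4))), 1)
  expect_error(normalized_sis(one), "2 labels")
})

test_that("suffix trees serialize to JSON and back", {
  co <- corpus_from_label_sequences(list(c("A", "B", "A", "A", "B")))
  tr <- build_suffix_tree(co, 1)
  path <- tempfile(fileext = ".json")
  write_suffix_tree(tr, path)
  back <- read_suffix_tree(path)
  expect_equal(back$counts, tr$counts)
  expect_equal(back$zero_counts, tr$zero_counts)
  expect_equal(entropy_rate(back), entropy_rate(tr))
  expect_equal(sis(back), sis(tr))
})
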