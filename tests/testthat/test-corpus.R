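test_that("segmentation breaks exactly at ISIs above the threshold", {
  # ISIs 0.05, 0.2, 0.03 over 4 syllables -> sequences of sizes 2 and 2
  df <- data.frame(start_s = c(0.00, 0.08, 0.31, 0.37),
                   end_s   = c(0.03, 0.11, 0.34, 0.40))
  co <- segment_into_sequences(df)
  expect_equal(unname(table(co$syllables$seq_id)), c(2L, 2L),
               ignore_attr = TRUE)

  # a single syllable is one sequence of one
  co1 <- segment_into_sequences(df[1, ])
  expect_equal(n_sequences(co1), 1L)
  expect_equal(n_syllables(co1), 1L)

  # all ISIs at or below the threshold keep one sequence; equality keeps it
  # (gap of exactly the threshold, using binary-exact times)
  df2 <- data.frame(start_s = c(0, 1, 2), end_s = c(0.5, 1.5, 2.5))
  co2 <- segment_into_sequences(df2, isi_threshold = 0.5)
  expect_equal(n_sequences(co2), 1L)

  # strictly greater breaks
  co3 <- segment_into_sequences(df2, isi_threshold = 0.4999)
  expect_equal(n_sequences(co3), 3L)
})

test_that("segmentation rejects unsorted or overlapping input naming the pair", {
  df <- data.frame(start_s = c(0.1, 0.0), end_s = c(0.13, 0.03))
  expect_error(segment_into_sequences(df), "rows 1 and 2")
  df2 <- data.frame(start_s = c(0.0, 0.02), end_s = c(0.03, 0.05))
  expect_error(segment_into_sequences(df2), "overlap")
})

test_that("segment/flatten round-trips the syllable list", {
  set.seed(11)
  start <- cumsum(runif(200, 0.01, 0.4))
  df <- data.frame(start_s = start, end_s = start + 0.005)
  co <- segment_into_sequences(df)
  out <- flatten_corpus(co)
  expect_equal(out$start_s, df$start_s)
  expect_equal(out$end_s, df$end_s)
  # boundary exists exactly where ISI > threshold
  isi <- df$start_s[-1] - df$end_s[-nrow(df)]
  expect_equal(diff(out$seq_id) == 1L, isi > 0.160)
})

test_that("relabel merges alphabets and composes functorially", {
  labs <- c("Simple-short", "Simple-long", "Up-short", "Up-long",
            "Down-short", "Down-long", "Multiple-short", "Multiple-long")
  set.seed(3)
  seqs <- replicate(30, sample(labs, sample(2:8, 1), replace = TRUE),
                    simplify = FALSE)
  co <- corpus_from_label_sequences(seqs, alphabet = labs)

  to_jn <- setNames(ifelse(grepl("^Simple", labs), "N", "J"), labs)
  co_jn <- relabel(co, to_jn)
  expect_setequal(co_jn$alphabet, c("J", "N"))
  expect_equal(co_jn$syllables$seq_id, co$syllables$seq_id)

  to5 <- setNames(sub("^(Up|Down|Multiple)-(short|long)$", "\\1-merged", labs),
                  labs)
  expect_length(relabel(co, to5)$alphabet, 5L)

  # identity mapping leaves the corpus unchanged
  ident <- setNames(labs, labs)
  expect_equal(relabel(co, ident)$syllables$label, co$syllables$label)

  # functoriality: relabel(relabel(c, f), g) == relabel(c, g o f)
  f <- to5
  g <- setNames(ifelse(grepl("^Simple", unique(unname(to5))), "N", "J"),
                unique(unname(to5)))
  lhs <- relabel(relabel(co, f), g)
  rhs <- relabel(co, setNames(unname(g[unname(f)]), names(f)))
  expect_equal(lhs$syllables$label, rhs$syllables$label)
  expect_equal(lhs$alphabet, rhs$alphabet)

  expect_error(relabel(co, to_jn[-1]), "Simple-short")
})

test_that("adjacent-pair correlation behaves at the known poles", {
  set.seed(5)
  # independent durations on a wide grid: |r| < 3/sqrt(n)
  df <- grid_syllables(3000, gap = 1)
  df$end_s <- df$start_s + pmin(rexp(3000, 50), 0.9)
  co <- segment_into_sequences(df, isi_threshold = 2)
  r <- adjacent_pair_correlation(co, "duration")
  expect_lt(abs(r$r), 3 / sqrt(r$n_pairs))
  expect_equal(r$n_pairs, n_syllables(co) - n_sequences(co))

  # each syllable copies its predecessor's duration: r is exactly 1
  d <- rep(rexp(50, 30), each = 3)   # constant within each 3-syllable run
  start <- cumsum(c(0.1, head(d, -1) + rep(c(0.01, 0.01, 0.5), 50)[-150]))
  co2 <- segment_into_sequences(data.frame(start_s = start, end_s = start + d),
                                isi_threshold = 0.3)
  expect_equal(n_sequences(co2), 50L)
  expect_equal(adjacent_pair_correlation(co2, "duration")$r, 1)

  # fewer than 3 pairs is an error
  co3 <- segment_into_sequences(grid_syllables(3), isi_threshold = 1)
  expect_error(adjacent_pair_correlation(co3, "duration"), "pairs")
})

test_that("isi pairs are counted within sequences only", {
  # two sequences of 4 and 3 syllables: (4-1)+(3-1) ISIs, (4-2)+(3-2) pairs
  df <- rbind(grid_syllables(4), within(grid_syllables(3), {
    start_s <- start_s + 4; end_s <- end_s + 4
  })[, c("start_s", "end_s")])
  co <- segment_into_sequences(df)
  expect_equal(n_sequences(co), 2L)
  r <- adjacent_pair_correlation(co, "isi")
  expect_equal(r$n_pairs, 3L)
})

test_that("corpus serialization round-trips through CSV + JSON", {
  set.seed(9)
  model <- persistent_markov_model(3, 0.6, alphabet = c("S", "D", "M"))
  co <- make_label_corpus(model, 40, seed = 21)
  co$features <- matrix(runif(n_syllables(co) * 4), ncol = 4)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_corpus(co, csv, js)
  back <- read_corpus(csv, js)
  expect_equal(back$syllables$start_s, co$syllables$start_s)
  expect_equal(back$syllables$label, co$syllables$label)
  expect_equal(back$syllables$seq_id, co$syllables$seq_id)
  expect_equal(unname(back$features), unname(co$features))
  expect_equal(back$alphabet, co$alphabet)
})
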