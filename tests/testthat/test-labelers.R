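test_that("jump_label partitions by jump count and direction", {
  expect_equal(jump_label(0), "Simple")
  expect_equal(jump_label(1, "down"), "Down")
  expect_equal(jump_label(1, "up"), "Up")
  expect_equal(jump_label(3, "up,down,up"), "Multiple")
  expect_equal(jump_label(c(0, 1, 1, 2, 5), c("", "up", "down", "up,up", "")),
               c("Simple", "Up", "Down", "Multiple", "Multiple"))
  expect_error(jump_label(1), "jump_dirs")
  expect_error(jump_label(NA), "missing")
})

test_that("duration split fits per-class medians and splits at them", {
  df <- grid_syllables(8)
  df$end_s <- df$start_s + c(0.010, 0.020, 0.030, 0.040,   # Simple
                             0.050, 0.060, 0.070, 0.080)   # Multiple
  df$label <- rep(c("Simple", "Multiple"), each = 4)
  co <- segment_into_sequences(df, isi_threshold = 1,
                               alphabet = c("Simple", "Multiple"))
  expect_error(fit_duration_split(co), "Up")
  sch <- fit_duration_split(co, base_labels = c("Simple", "Multiple"))
  expect_equal(unname(sch$split_medians["Simple"]), 0.025)
  split <- apply_jump_scheme(co, sch)
  expect_equal(split$syllables$label[1:4],
               c("Simple-short", "Simple-short", "Simple-long", "Simple-long"))
  expect_length(split$alphabet, 4L)

  # duration exactly at the median goes to -short
  df2 <- df[1:4, ]; df2$label <- "Simple"
  co2 <- segment_into_sequences(df2, isi_threshold = 1)
  sch2 <- jump_scheme(c(Simple = 0.030), global_median = 0.0353)
  out <- apply_jump_scheme(co2, sch2)
  expect_equal(out$syllables$label[3], "Simple-short")

  # split halves each class within one syllable
  set.seed(8)
  dur <- pmin(rexp(201, 30) + 0.002, 0.9)
  df3 <- grid_syllables(201, gap = 1); df3$end_s <- df3$start_s + dur
  df3$label <- "Simple"
  co3 <- segment_into_sequences(df3, isi_threshold = 2)
  sch3 <- fit_duration_split(co3, base_labels = "Simple")
  out3 <- apply_jump_scheme(co3, sch3)
  tab <- table(out3$syllables$label)
  expect_lte(abs(tab[["Simple-short"]] - tab[["Simple-long"]]), 1)
})

test_that("unclassified fallback uses the global median with strict 'shorter'", {
  sch <- jump_scheme(c(Simple = 0.0276), global_median = 0.0353)
  expect_equal(assign_unclassified(0.020, sch), "Simple")
  expect_equal(assign_unclassified(0.090, sch), "Multiple")
  expect_equal(assign_unclassified(0.0353, sch), "Multiple")
})

test_that("spectral preprocessing yields normalized fixed-length features", {
  set.seed(12)
  freqs <- seq(0, 125000, length.out = 128)
  cfg <- filterbank_config()
  spec <- matrix(runif(128 * 40), nrow = 128)
  v <- preprocess_spectral(spec, freqs, cfg)
  expect_length(v, 2016L)
  expect_equal(sum(v), 1)
  # scaling input power leaves the feature unchanged
  expect_equal(preprocess_spectral(spec * 10, freqs, cfg), v)
  # flat spectrum excites all channels equally (unit-area filters)
  flat <- matrix(1, nrow = 128, ncol = 10)
  vf <- preprocess_spectral(flat, freqs, cfg)
  ch <- rowSums(matrix(vf, nrow = cfg$n_filters, byrow = TRUE))
  expect_lt(diff(range(ch)), 1e-9)
  expect_error(preprocess_spectral(spec[, 1, drop = FALSE], freqs, cfg),
               "2 frames")
})

test_that("cosine k-means recovers exact and well-separated clusters", {
  set.seed(14)
  # k distinct points are their own centroids (up to permutation)
  pts <- diag(4) + 0.01
  cents <- train_centroids(pts, k = 4, seed = 1, nstart = 5)
  sim <- unname(assign_by_centroid(pts, cents))
  expect_length(unique(sim), 4L)

  # well-separated blobs: purity > 0.95 against generator ground truth
  fx <- make_feature_corpus(persistent_markov_model(6, 0.4), 300,
                            dim = 24, separation = 1, corruption = 0,
                            seed = 15)
  cents2 <- train_centroids(fx$corpus$features, k = 6, seed = 2)
  assigned <- assign_by_centroid(fx$corpus$features, cents2)
  purity <- mean(vapply(split(fx$corpus$syllables$label, assigned),
                        function(l) max(table(l)) / length(l), numeric(1)))
  expect_gt(purity, 0.95)

  # seeded determinism
  c_a <- train_centroids(fx$corpus$features, k = 6, seed = 3)
  c_b <- train_centroids(fx$corpus$features, k = 6, seed = 3)
  expect_identical(c_a, c_b)

  expect_error(train_centroids(pts[c(1, 1, 1, 1), ], k = 4, seed = 1),
               "distinct")
})

test_that("stats::kmeans on unit vectors agrees on well-separated blobs", {
  # independent cross-check of the clustering result, not the implementation
  fx <- make_feature_corpus(persistent_markov_model(4, 0.4), 200,
                            dim = 16, separation = 1, corruption = 0,
                            seed = 16)
  X <- fx$corpus$features / sqrt(rowSums(fx$corpus$features^2))
  km <- kmeans(X, centers = 4, nstart = 10)
  ours <- assign_by_centroid(fx$corpus$features,
                             train_centroids(fx$corpus$features, 4, seed = 4))
  # same partition up to label names
  expect_equal(length(unique(paste(km$cluster, ours))), 4L)
})

test_that("centroid assignment is scale-invariant with deterministic ties", {
  cents <- usv_centroids(rbind(c(1, 0), c(0, 1)), labels = c("x", "y"))
  expect_equal(assign_by_centroid(c(2, 0), cents), "x")
  expect_equal(assign_by_centroid(c(0, 0.5), cents), "y")
  # equidistant feature goes to the lowest centroid index
  expect_equal(assign_by_centroid(c(1, 1), cents), "x")
  # feature equal to 2x a centroid maps to it
  expect_equal(assign_by_centroid(rbind(2 * c(0, 1)), cents), "y")
  expect_error(assign_by_centroid(c(0, 0), cents), "zero-norm")
  expect_error(assign_by_centroid(c(1, 0, 0), cents), "dimension")
})

test_that("centroid sets serialize to JSON and back", {
  cents <- usv_centroids(matrix(runif(12), 3), labels = c("a", "b", "c"))
  path <- tempfile(fileext = ".json")
  write_centroids(cents, path)
  back <- read_centroids(path)
  expect_equal(back$centroids, cents$centroids, ignore_attr = TRUE)
  expect_equal(back$labels, cents$labels)
})
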