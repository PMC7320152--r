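# Synthetic fixture generators with known ground truth. The defaults encode
# the statistics reported for large mouse-USV databases: syllable durations
# following a shifted exponential whose binned density is a*exp(b*x) with
# (a, b) = (0.51, -0.41) in 4-ms bin units, sequence lengths following a
# truncated power law a*x^b with (a, b) = (0.6, -1.88), a bimodal ISI
# distribution with modes near 20 ms and 70 ms, and a lag-1 correlation of
# 0.44 between adjacent syllable durations.

#' Truncated discrete power-law sampler
#'
#' Draws integers from `{xmin, ..., xmax}` with probability proportional to
#' `x^b`.
#'
#' @param n number of draws.
#' @param b exponent (default -1.88).
#' @param xmin,xmax support bounds.
#' @return integer vector.
#' @export
rtrunc_power <- function(n, b = -1.88, xmin = 1, xmax = 50) {
  stopifnot(xmax >= xmin, xmin >= 1)
  support <- xmin:xmax
  sample(support, n, replace = TRUE, prob = support^b)
}

# Correlation transfer of the Gaussian copula with exponential marginals:
# for Z bivariate normal with correlation phi, the Pearson correlation of
# qexp(pnorm(Z)) is sum_n c_n^2 phi^n / n! / Var, with c_n the Hermite
# coefficients of qexp(pnorm(.)). Scale and shift of the marginal do not
# affect it, so the map is computed once and cached.
copula_env <- new.env(parent = emptyenv())

exp_copula_coefs <- function(nmax = 16) {
  if (!is.null(copula_env$cn)) return(copula_env$cn)
  hermite <- function(z, n) {
    h0 <- rep(1, length(z)); h1 <- z
    if (n == 0) return(h0)
    if (n == 1) return(h1)
    for (k in 2:n) { h2 <- z * h1 - (k - 1) * h0; h0 <- h1; h1 <- h2 }
    h1
  }
  g <- function(z) stats::qexp(stats::pnorm(z))
  cn <- vapply(seq_len(nmax), function(n) {
    stats::integrate(function(z) g(z) * hermite(z, n) * stats::dnorm(z),
                     -8, 8, subdivisions = 400)$value
  }, numeric(1))
  copula_env$cn <- cn
  cn
}

# latent AR(1) coefficient phi achieving a target lag-1 Pearson correlation
# for exponential marginals
exp_copula_phi <- function(rho) {
  cn <- exp_copula_coefs()
  v <- sum(cn^2 / factorial(seq_along(cn)))
  rho_of <- function(phi) {
    sum(cn^2 * phi^seq_along(cn) / factorial(seq_along(cn))) / v
  }
  rho_max <- rho_of(0.999)
  if (rho < 0 || rho > rho_max) {
    stop(sprintf(
      "target lag-1 correlation %.3f unattainable for exponential marginals via a Gaussian copula (attainable range [0, %.3f])",
      rho, rho_max))
  }
  if (rho == 0) return(0)
  stats::uniroot(function(p) rho_of(p) - rho, c(0, 0.999), tol = 1e-6)$root
}

# exponential durations (seconds) whose binned density reproduces
# a*exp(b*x) in bin units, with within-sequence lag-1 correlation rho via a
# latent AR(1) Gaussian copula
sample_durations <- function(lens, a = 0.51, b = -0.41, binwidth_ms = 4,
                             rho = 0.44) {
  rate <- -b
  x0 <- log(a / rate) / rate            # support shift in bin units
  phi <- exp_copula_phi(rho)
  sd_innov <- sqrt(1 - phi^2)
  lapply(lens, function(L) {
    innov <- c(stats::rnorm(1), stats::rnorm(L - 1, sd = sd_innov))
    z <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    (x0 + stats::qexp(stats::pnorm(z), rate = rate)) * binwidth_ms / 1000
  })
}

# bimodal ISI sampler: two-Gaussian mixture truncated to (isi_min, isi_max]
sample_isis <- function(n, modes = c(0.020, 0.070), sds = c(0.005, 0.015),
                        weights = c(0.5, 0.5), isi_min = 0.001,
                        isi_max = 0.160) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    comp <- sample(seq_along(modes), length(todo), replace = TRUE,
                   prob = weights)
    v <- stats::rnorm(length(todo), modes[comp], sds[comp])
    ok <- v > isi_min & v <= isi_max
    out[todo[ok]] <- v[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a fully timed, labeled synthetic corpus
#'
#' Labels follow the given Markov ground-truth model; sequence lengths a
#' truncated power law; syllable durations a shifted exponential with a
#' target lag-1 correlation between adjacent durations (induced by a latent
#' AR(1) Gaussian copula, which preserves the exponential marginal exactly);
#' within-sequence ISIs a bimodal mixture bounded by the 160 ms segmentation
#' threshold; between-sequence gaps always exceed it.
#'
#' @param model a `markov_model` providing the label syntax.
#' @param n_sequences number of sequences.
#' @param length_params `c(a, b)` of the length power law (a is implied by
#'   normalization; b is the exponent).
#' @param length_range integer support of sequence lengths.
#' @param duration_params `c(a, b)` of the duration exponential in
#'   `duration_binwidth_ms` units.
#' @param duration_binwidth_ms bin unit of the duration parameters (ms).
#' @param duration_lag1_corr target correlation of adjacent durations.
#' @param isi_modes,isi_sds,isi_weights ISI mixture parameters (seconds).
#' @param isi_min shortest ISI emitted (seconds); two emissions closer than
#'   about a millisecond are physically one syllable.
#' @param seed optional integer seed.
#' @return a labeled `usv_corpus`.
#' @export
make_label_corpus <- function(model, n_sequences,
                              length_params = c(0.6, -1.88),
                              length_range = c(1, 50),
                              duration_params = c(0.51, -0.41),
                              duration_binwidth_ms = 4,
                              duration_lag1_corr = 0.44,
                              isi_modes = c(0.020, 0.070),
                              isi_sds = c(0.005, 0.015),
                              isi_weights = c(0.5, 0.5),
                              isi_min = 0.001,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- rtrunc_power(n_sequences, b = length_params[2],
                       xmin = length_range[1], xmax = length_range[2])
  seqs <- generate_label_seqs(model, lens)
  durs <- sample_durations(lens, a = duration_params[1], b = duration_params[2],
                           binwidth_ms = duration_binwidth_ms,
                           rho = duration_lag1_corr)
  n_isi <- sum(pmax(lens - 1, 0))
  isis <- sample_isis(n_isi, modes = isi_modes, sds = isi_sds,
                      weights = isi_weights, isi_min = isi_min)
  # assemble times: sequences separated by gaps safely above the threshold
  seq_gaps <- 0.2 + stats::rexp(n_sequences, rate = 1 / 0.3)
  start <- numeric(sum(lens)); end <- numeric(sum(lens))
  t_cursor <- 0.1
  row <- 1L; isi_i <- 1L
  for (s in seq_along(lens)) {
    t_cursor <- t_cursor + seq_gaps[s]
    for (j in seq_len(lens[s])) {
      if (j > 1) {
        t_cursor <- t_cursor + isis[isi_i]
        isi_i <- isi_i + 1L
      }
      start[row] <- t_cursor
      end[row] <- t_cursor + durs[[s]][j]
      t_cursor <- end[row]
      row <- row + 1L
    }
  }
  df <- data.frame(
    start_s = start, end_s = end,
    label = unlist(seqs, use.names = FALSE),
    seq_id = rep(seq_along(lens), lens),
    stringsAsFactors = FALSE
  )
  usv_corpus(df, alphabet = model$alphabet,
             provenance = "synthetic labeled corpus")
}

#' Generate a cluster-structured feature corpus with hidden Markov labels
#'
#' Each syllable's hidden label follows the ground-truth Markov model; its
#' feature vector is the label's ground-truth centroid multiplied elementwise
#' by iid uniform noise in `noise_range`. When `corruption > 0` a corrupted
#' copy of the centroids (each multiplied elementwise by iid uniform noise in
#' `1 +/- corruption`) is returned as the starting point for optimization
#' experiments.
#'
#' @param model a `markov_model`; its alphabet names the clusters.
#' @param n_sequences number of sequences.
#' @param dim feature dimensionality (default 2016, 16 channels x 126
#'   frames; smaller values give statistically equivalent fixtures cheaper).
#' @param centroids optional k x dim matrix of ground-truth centroids;
#'   defaults to `0.5 + separation * (uniform(0,1) - 0.5)` entries: clusters
#'   scattered around a shared base vector, with `separation` controlling
#'   their angular spread (1 = iid uniform(0, 1) entries, well separated).
#' @param separation spread of the default centroids around the base vector;
#'   ignored when `centroids` is supplied. Because multiplicative noise in
#'   high dimension projects only weakly onto any one between-cluster
#'   direction, small values are needed to emulate the heavily overlapping
#'   clusters of real syllable feature spaces.
#' @param noise_range multiplicative feature noise bounds (default
#'   `[0.9, 1.1]`).
#' @param corruption relative amplitude of the centroid corruption
#'   (default 0.2 for `1 +/- 20%`; 0 disables).
#' @param length_sampler optional sequence-length sampler.
#' @param seed optional integer seed.
#' @return list with `corpus` (features + hidden true labels), `centroids`
#'   (ground truth, `usv_centroids`) and `corrupted_centroids` (or `NULL`).
#' @export
make_feature_corpus <- function(model, n_sequences, dim = 2016,
                                centroids = NULL, separation = 1,
                                noise_range = c(0.9, 1.1),
                                corruption = 0.2, length_sampler = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(model$alphabet)
  if (is.null(centroids)) {
    centroids <- matrix(0.5 + separation * (stats::runif(k * dim) - 0.5),
                        nrow = k)
  }
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == k)
  dim <- ncol(centroids)
  corpus <- generate_sequences(model, n_sequences,
                               length_sampler = length_sampler)
  lab_idx <- match(corpus$syllables$label, model$alphabet)
  n <- length(lab_idx)
  noise <- matrix(stats::runif(n * dim, noise_range[1], noise_range[2]),
                  nrow = n)
  corpus$features <- centroids[lab_idx, , drop = FALSE] * noise
  truth <- usv_centroids(centroids, labels = model$alphabet)
  corrupted <- NULL
  if (corruption > 0) {
    cmat <- centroids * matrix(stats::runif(k * dim, 1 - corruption,
                                            1 + corruption), nrow = k)
    corrupted <- usv_centroids(cmat, labels = model$alphabet)
  }
  list(corpus = corpus, centroids = truth, corrupted_centroids = corrupted)
}

#' Synthesize chirp audio for a timed corpus
#'
#' Places one frequency-modulated tone per syllable at the corpus timings
#' over white Gaussian background noise. Pitch jumps (from the `jump_count`
#' and `jump_dirs` columns, when present) are realized as instantaneous
#' carrier steps of `jump_size` Hz, large enough for unambiguous detection.
#' The waveform ends at the last syllable's end time.
#'
#' @param corpus a timed `usv_corpus` (non-overlapping syllables).
#' @param fs sampling rate (default 250 kHz).
#' @param freq_range carrier start-frequency range (Hz).
#' @param sweep_range linear FM slope range (Hz/s; sign drawn at random).
#' @param jump_size carrier step per pitch jump (Hz, default 30 kHz).
#' @param snr_db tone power over noise power, dB.
#' @param seed optional integer seed.
#' @return list with `wave` (numeric vector, unit noise SD), `fs`, and
#'   `truth` (the syllable table with exact boundaries).
#' @export
make_audio_fixture <- function(corpus, fs = 250000,
                               freq_range = c(40e3, 70e3),
                               sweep_range = c(5e4, 2e5),
                               jump_size = 30e3, snr_db = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- corpus$syllables
  check_time_order(df)
  n_samp <- ceiling(max(df$end_s) * fs)
  wave <- stats::rnorm(n_samp)
  amp <- sqrt(2 * 10^(snr_db / 10))     # tone amplitude for unit noise SD
  for (i in seq_len(nrow(df))) {
    i0 <- floor(df$start_s[i] * fs) + 1
    i1 <- min(ceiling(df$end_s[i] * fs), n_samp)
    t <- (seq(i0, i1) - i0) / fs
    f0 <- stats::runif(1, freq_range[1], freq_range[2])
    slope <- sample(c(-1, 1), 1) * stats::runif(1, sweep_range[1], sweep_range[2])
    f_inst <- f0 + slope * t
    jc <- if (!is.null(df$jump_count)) df$jump_count[i] else 0
    if (!is.na(jc) && jc > 0) {
      dirs <- strsplit(as.character(df$jump_dirs[i]), ",")[[1]]
      dirs <- trimws(dirs)
      cuts <- floor(seq_along(t) / length(t) * (jc + 1))
      for (j in seq_len(jc)) {
        step <- if (dirs[j] == "up") jump_size else -jump_size
        f_inst[cuts >= j] <- f_inst[cuts >= j] + step
      }
    }
    f_inst <- pmin(pmax(f_inst, 26e3), 115e3)
    phase <- 2 * pi * cumsum(f_inst) / fs
    wave[i0:i1] <- wave[i0:i1] + amp * sin(phase)
  }
  list(wave = wave, fs = fs, truth = df)
}

#' Standard SIM recovery fixture
#'
#' The canonical synthetic test bed for centroid-refinement experiments:
#' 8 clusters whose centroids are scattered tightly around a shared base
#' vector (separation 0.16 in 16 dimensions), so that under +/-10%
#' multiplicative feature noise the ground-truth centroids classify almost
#' perfectly while +/-20% centroid corruption causes substantial
#' misassignment -- the overlap regime of real syllable feature spaces.
#' Labels carry 1st-order Markov syntax (self-transition probability 0.5).
#'
#' @param seed integer seed.
#' @param n_sequences number of sequences (default 500).
#' @param k clusters (default 8).
#' @param dim feature dimension (default 16).
#' @param separation centroid spread (default 0.16).
#' @param stay_prob self-transition probability of the label chain.
#' @return as [make_feature_corpus()], plus `model` (the label chain).
#' @export
sim_recovery_fixture <- function(seed, n_sequences = 500, k = 8, dim = 16,
                                 separation = 0.16, stay_prob = 0.5) {
  model <- persistent_markov_model(k, stay_prob)
  fx <- make_feature_corpus(model, n_sequences, dim = dim,
                            separation = separation, corruption = 0.2,
                            seed = seed)
  fx$model <- model
  fx
}

#' Corpus tailored for parser boundary-accuracy fixtures
#'
#' Same construction as [make_label_corpus()], but with every placed
#' syllable resolvable at the default [parser_config()]: the duration
#' exponential is shifted so its floor (~10 ms) clears the parser's 5 ms
#' minimum duration, and ISIs are floored above the 10 ms merge gap. Audio
#' rendered from this corpus therefore certifies boundary accuracy rather
#' than the detectability of ultra-short syllables.
#'
#' @param seed integer seed.
#' @param n_sequences number of sequences.
#' @return a labeled `usv_corpus`.
#' @export
parser_fixture_corpus <- function(seed, n_sequences = 40) {
  model <- persistent_markov_model(2, 0.5)
  make_label_corpus(model, n_sequences,
                    duration_params = c(1.2, -0.41),  # floor ~10.5 ms
                    isi_modes = c(0.030, 0.070),
                    isi_sds = c(0.005, 0.015),
                    isi_min = 0.014,
                    seed = seed)
}
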