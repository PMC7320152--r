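# Two reference labeling families:
#   * a pitch-jump/duration labeler: Simple / Up / Down / Multiple from the
#     jump features, each split at its median duration into -short / -long
#     for 8 labels, with a duration fallback for unclassified syllables;
#   * a centroid labeler: filterbank spectral features clustered by
#     k-means under cosine distance, syllables assigned to the nearest
#     centroid.

#' Base pitch-jump label of a syllable
#'
#' 0 jumps -> `Simple`; exactly 1 jump -> `Up` or `Down` by its direction;
#' 2 or more jumps -> `Multiple`.
#'
#' @param jump_count non-negative integer vector.
#' @param jump_dirs character vector of comma-separated directions
#'   (`"up"`/`"down"`), required where `jump_count == 1`.
#' @return character vector of base labels.
#' @export
jump_label <- function(jump_count, jump_dirs = NULL) {
  if (anyNA(jump_count)) stop("jump_count missing for some syllables")
  if (any(jump_count < 0 | jump_count != round(jump_count))) {
    stop("jump_count must be non-negative integers")
  }
  out <- character(length(jump_count))
  out[jump_count == 0] <- "Simple"
  out[jump_count >= 2] <- "Multiple"
  one <- which(jump_count == 1)
  if (length(one) > 0) {
    if (is.null(jump_dirs)) stop("jump_dirs required when jump_count == 1")
    d1 <- vapply(strsplit(as.character(jump_dirs[one]), ","),
                 function(p) trimws(p[1]), character(1))
    if (anyNA(d1) || !all(d1 %in% c("up", "down"))) {
      stop("jump direction must be 'up' or 'down'")
    }
    out[one] <- ifelse(d1 == "up", "Up", "Down")
  }
  out
}

#' Fit the duration-split scheme from base-labeled data
#'
#' Stores the median duration of each base class and the global median
#' duration; [apply_jump_scheme()] splits each base class at its median into
#' `-short` (duration <= median) and `-long`.
#'
#' @param corpus a `usv_corpus` whose `label` column holds base labels.
#' @param base_labels the base classes expected to be present.
#' @return object of class `jump_scheme`: list with `split_medians` (named,
#'   seconds) and `global_median` (seconds).
#' @export
fit_duration_split <- function(corpus,
                               base_labels = c("Simple", "Up", "Down", "Multiple")) {
  df <- corpus$syllables
  if (is.null(df$label)) stop("corpus has no base labels")
  empty <- base_labels[!base_labels %in% df$label]
  if (length(empty) > 0) {
    stop("no syllables with base label: ", paste(empty, collapse = ", "))
  }
  med <- vapply(base_labels, function(b) {
    stats::median(df$duration_s[df$label == b])
  }, numeric(1))
  jump_scheme(med, stats::median(df$duration_s))
}

#' Construct a duration-split scheme from known medians
#'
#' Allows running with externally supplied split points (e.g. medians fitted
#' on another database) instead of refitting.
#'
#' @param split_medians named numeric vector of per-base-label median
#'   durations (seconds).
#' @param global_median median duration over all syllables (seconds), the
#'   fallback split for unclassified syllables.
#' @return object of class `jump_scheme`.
#' @export
jump_scheme <- function(split_medians, global_median) {
  if (any(split_medians <= 0) || global_median <= 0) {
    stop("medians must be positive")
  }
  structure(list(split_medians = split_medians,
                 global_median = global_median),
            class = "jump_scheme")
}

#' Split base labels into -short / -long by the scheme's medians
#'
#' A duration exactly equal to the class median goes to `-short`.
#'
#' @param corpus base-labeled `usv_corpus`.
#' @param scheme a `jump_scheme`.
#' @return corpus relabeled with the 8 split labels.
#' @export
apply_jump_scheme <- function(corpus, scheme) {
  df <- corpus$syllables
  med <- scheme$split_medians[as.character(df$label)]
  if (anyNA(med)) {
    stop("scheme has no median for label: ",
         df$label[which(is.na(med))[1]])
  }
  df$label <- paste0(df$label,
                     ifelse(df$duration_s <= med, "-short", "-long"))
  corpus$syllables <- df
  corpus$alphabet <- as.vector(outer(names(scheme$split_medians),
                                     c("-short", "-long"), paste0))
  corpus
}

#' Fallback base label for unclassified syllables
#'
#' Syllables shorter than the global median duration are taken as `Simple`,
#' the rest as `Multiple` (short unclassified syllables are overwhelmingly
#' simple sweeps; long ones tend to contain multiple components).
#'
#' @param duration_s numeric vector of durations (seconds).
#' @param scheme a `jump_scheme` with `global_median` set.
#' @return character vector of `"Simple"` / `"Multiple"`.
#' @export
assign_unclassified <- function(duration_s, scheme) {
  ifelse(duration_s < scheme$global_median, "Simple", "Multiple")
}

## ---- spectral features -----------------------------------------------------

#' Filterbank configuration for spectral syllable features
#'
#' @param n_filters number of filterbank channels (default 16).
#' @param n_frames number of time-normalized frames (default 126, so the
#'   flattened feature length is 16 x 126 = 2016).
#' @param band frequency range (Hz) spanned by the bank.
#' @return object of class `filterbank_config` with derived `out_dim`.
#' @export
filterbank_config <- function(n_filters = 16, n_frames = 126,
                              band = c(25e3, 125e3)) {
  stopifnot(n_filters >= 1, n_frames >= 2, band[2] > band[1], band[1] >= 0)
  structure(list(n_filters = n_filters, n_frames = n_frames, band = band,
                 out_dim = n_filters * n_frames),
            class = "filterbank_config")
}

# Triangular filters with log-spaced center frequencies over the band, each
# normalized to unit area so a flat spectrum excites all channels equally.
# A smooth log-spaced bank of this kind stands in for a gammatone bank.
filterbank_matrix <- function(freqs, config) {
  nf <- config$n_filters
  lo <- max(config$band[1], min(freqs[freqs > 0]))
  hi <- min(config$band[2], max(freqs))
  edges <- exp(seq(log(lo), log(hi), length.out = nf + 2))
  H <- matrix(0, nrow = nf, ncol = length(freqs))
  for (i in seq_len(nf)) {
    l <- edges[i]; c <- edges[i + 1]; r <- edges[i + 2]
    up <- freqs >= l & freqs <= c
    dn <- freqs > c & freqs <= r
    H[i, up] <- (freqs[up] - l) / (c - l)
    H[i, dn] <- (r - freqs[dn]) / (r - c)
    s <- sum(H[i, ])
    if (s > 0) H[i, ] <- H[i, ] / s
  }
  H
}

#' Filterbank feature vector of one syllable spectrogram
#'
#' Passes the power spectrogram through a log-spaced triangular filterbank,
#' linearly resamples each channel's energy track to a fixed number of
#' frames, flattens channel-by-channel, and normalizes the total energy to
#' 1 (so the representation is invariant to recording level).
#'
#' @param power numeric matrix, frequencies x time frames (power spectrum).
#' @param freqs frequency axis (Hz), one per row of `power`.
#' @param config a [filterbank_config()].
#' @return numeric vector of length `config$out_dim`.
#' @export
preprocess_spectral <- function(power, freqs, config = filterbank_config()) {
  power <- as.matrix(power)
  if (nrow(power) != length(freqs)) stop("freqs must match rows of power")
  if (ncol(power) < 2) stop("syllable spectrogram has fewer than 2 frames")
  if (max(freqs) < config$band[2] * 0.5) {
    stop("frequency axis does not cover the filterbank band")
  }
  H <- filterbank_matrix(freqs, config)
  E <- H %*% power                      # n_filters x n_frames_in
  tin <- seq(0, 1, length.out = ncol(E))
  tout <- seq(0, 1, length.out = config$n_frames)
  En <- t(apply(E, 1, function(e) stats::approx(tin, e, tout)$y))
  v <- as.numeric(t(En))                # channel-major blocks of n_frames
  s <- sum(v)
  if (s <= 0) stop("spectrogram has no energy in the filterbank band")
  v / s
}

## ---- centroid labeler ------------------------------------------------------

#' Construct a centroid set
#'
#' @param centroids numeric matrix, one centroid per row.
#' @param labels one label per centroid (default `"C1"..."Ck"`).
#' @param metric only `"cosine"` is supported.
#' @return object of class `usv_centroids`.
#' @export
usv_centroids <- function(centroids, labels = NULL, metric = "cosine") {
  centroids <- as.matrix(centroids)
  if (is.null(labels)) labels <- paste0("C", seq_len(nrow(centroids)))
  if (length(labels) != nrow(centroids)) stop("one label per centroid")
  if (any(!is.finite(centroids))) stop("centroids must be finite")
  if (any(sqrt(rowSums(centroids^2)) == 0)) stop("zero-norm centroid")
  metric <- match.arg(metric, "cosine")
  structure(list(centroids = centroids, labels = as.character(labels),
                 metric = metric),
            class = "usv_centroids")
}

#' @export
print.usv_centroids <- function(x, ...) {
  cat("usv_centroids:", nrow(x$centroids), "centroids of dimension",
      ncol(x$centroids), "(", x$metric, "distance )\n")
  invisible(x)
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero-norm feature vector")
  m / nrm
}

#' Train centroids by k-means under cosine distance
#'
#' Lloyd iterations on unit-normalized feature vectors with cosine
#' assignment (spherical k-means): centroids are cluster means; a cluster
#' that empties is reseeded from the point farthest from its centroid. The
#' best of `nstart` random initializations (by total cosine distance to the
#' assigned centroid) is returned. At most `n_train` vectors (sampled without
#' replacement) are used for training.
#'
#' @param features numeric matrix, one syllable per row.
#' @param k number of clusters (default 8).
#' @param n_train training subsample size (default 5000).
#' @param seed optional integer seed.
#' @param nstart random restarts (default 10).
#' @param iter_max Lloyd iterations per start (default 50).
#' @param labels optional centroid labels.
#' @return a [usv_centroids()] object.
#' @export
train_centroids <- function(features, k = 8, n_train = 5000, seed = NULL,
                            nstart = 10, iter_max = 50, labels = NULL) {
  features <- as.matrix(features)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(features)
  if (n > n_train) {
    features <- features[sample(n, n_train), , drop = FALSE]
    n <- n_train
  }
  X <- unit_rows(features)
  if (nrow(unique(X)) < k) stop("fewer than k distinct feature directions")
  best <- NULL; best_obj <- Inf
  for (s in seq_len(nstart)) {
    C <- X[sample(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (it in seq_len(iter_max)) {
      sim <- X %*% t(unit_rows(C))
      a <- max.col(sim, ties.method = "first")
      for (j in seq_len(k)) {
        if (!any(a == j)) {
          # reseed empty cluster from the overall worst-fit point
          far <- which.min(sim[cbind(seq_len(n), a)])
          C[j, ] <- X[far, ]
          a[far] <- j
        } else {
          C[j, ] <- colMeans(X[a == j, , drop = FALSE])
        }
      }
      if (identical(a, assign_old)) break
      assign_old <- a
    }
    obj <- sum(1 - (X %*% t(unit_rows(C)))[cbind(seq_len(n), a)])
    if (obj < best_obj) { best_obj <- obj; best <- C }
  }
  usv_centroids(best, labels = labels)
}

#' Assign features to the nearest centroid by cosine distance
#'
#' Ties go to the lowest centroid index. Assignment is invariant to the
#' scale of both the feature and the centroid.
#'
#' @param features numeric matrix (or single vector) of features.
#' @param centroids a `usv_centroids` object.
#' @return character vector of centroid labels.
#' @export
assign_by_centroid <- function(features, centroids) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != ncol(centroids$centroids)) {
    stop("feature dimension ", ncol(features), " does not match centroids (",
         ncol(centroids$centroids), ")")
  }
  sim <- unit_rows(as.matrix(features)) %*% t(unit_rows(centroids$centroids))
  centroids$labels[max.col(round(sim, 12), ties.method = "first")]
}
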