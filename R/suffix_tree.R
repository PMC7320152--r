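# Depth-D suffix-tree Markov models of labeled syllable sequences, and the
# information-theoretic scores computed from them: entropy rate, the Syntax
# Information Score (SIS = mutual information between a label and its
# suffix), per-motif SIS contributions, the zero-cell validity criterion,
# and resampled uncertainty.
#
# Conventions used throughout:
#   * suffixes are stored oldest -> newest and joined with ":"; display
#     reverses them (newest first) to match how they are conventionally read;
#   * all logs are base 2; 0 * log(0) is taken as 0;
#   * (D+1)-tuple windows never span a sequence boundary;
#   * probabilities are plug-in (maximum likelihood) count ratios, with no
#     smoothing or bias correction.

SUFFIX_SEP <- ":"

# All N_c^depth suffix keys in canonical index order: the suffix
# (a_1 .. a_D), oldest first, has index 1 + sum_j (a_j - 1) * N_c^(D - j),
# i.e. the oldest position is the most significant digit.
suffix_keys <- function(alphabet, depth) {
  if (depth == 0) return("")
  nc <- length(alphabet)
  g <- do.call(expand.grid,
               c(rep(list(seq_len(nc)), depth),
                 list(KEEP.OUT.ATTRS = FALSE)))
  # expand.grid varies the first column fastest; column j has digit weight
  # nc^(j-1), so columns depth..1 read oldest -> newest.
  mat <- as.matrix(g)[, depth:1, drop = FALSE]
  apply(mat, 1, function(r) paste(alphabet[r], collapse = SUFFIX_SEP))
}

# Shared counting core: label sequences -> suffix_tree. `zero_counts` keeps
# the plain label frequencies over all syllables (the corpus-wide 0th-order
# pmf), used by the optional x_marginal = "corpus" mode of sis().
tree_from_label_seqs <- function(label_seqs, alphabet, depth,
                                 max_cells = 2^20) {
  nc <- length(alphabet)
  if (nc < 1) stop("empty alphabet")
  if (depth < 0) stop("depth must be >= 0")
  if (nc^(depth + 1) > max_cells) {
    stop("N_c^(depth+1) = ", nc^(depth + 1), " exceeds the cap of ", max_cells,
         "; reduce the depth or merge labels (or raise max_cells)")
  }
  n_suffix <- as.integer(nc^depth)
  lin_parts <- vector("list", length(label_seqs))
  zero <- integer(nc)
  for (si in seq_along(label_seqs)) {
    s <- label_seqs[[si]]
    m <- match(s, alphabet)
    if (anyNA(m)) {
      stop("label not in alphabet: ", s[which(is.na(m))[1]])
    }
    zero <- zero + tabulate(m, nc)
    L <- length(s)
    if (L < depth + 1) next
    n_win <- L - depth
    if (depth == 0) {
      k <- rep(1L, n_win)
    } else {
      k <- rep(1, n_win)
      for (j in seq_len(depth)) {
        k <- k + (m[j:(j + n_win - 1)] - 1) * nc^(depth - j)
      }
    }
    x <- m[(depth + 1):L]
    lin_parts[[si]] <- (x - 1) * n_suffix + k
  }
  lin <- unlist(lin_parts, use.names = FALSE)
  counts <- matrix(tabulate(lin, n_suffix * nc), nrow = n_suffix, ncol = nc,
                   dimnames = list(suffix_keys(alphabet, depth), alphabet))
  structure(
    list(depth = depth, alphabet = alphabet, counts = counts,
         zero_counts = stats::setNames(zero, alphabet),
         total_tuples = length(lin), n_syllables = sum(zero)),
    class = "suffix_tree"
  )
}

#' Build a depth-D suffix-tree Markov model from a labeled corpus
#'
#' Scans every sequence and accumulates, for each of the `N_c^D` possible
#' suffixes (the D labels preceding a syllable, stored oldest first), the
#' number of times the suffix occurred and the number of times each label
#' followed it. Windows are taken only inside sequences; a sequence shorter
#' than `depth + 1` contributes nothing. Counts are raw; probabilities are
#' derived on demand as plug-in ratios.
#'
#' @param corpus a fully labeled `usv_corpus`.
#' @param depth suffix length D (>= 0; depth 0 is the label-frequency model).
#' @param max_cells guard on the table size `N_c^(D+1)`.
#' @return object of class `suffix_tree` with elements `depth`, `alphabet`,
#'   `counts` (suffix x label matrix), `zero_counts` (label frequencies over
#'   all syllables), `total_tuples`, `n_syllables`.
#' @export
build_suffix_tree <- function(corpus, depth, max_cells = 2^20) {
  if (is.null(corpus$syllables$label) || anyNA(corpus$syllables$label)) {
    stop("all syllables must be labeled to build a suffix tree")
  }
  alphabet <- if (!is.null(corpus$alphabet)) corpus$alphabet else
    sort(unique(as.character(corpus$syllables$label)))
  if (any(grepl(SUFFIX_SEP, alphabet, fixed = TRUE))) {
    stop("labels must not contain the suffix separator '", SUFFIX_SEP, "'")
  }
  tree_from_label_seqs(label_sequences(corpus), alphabet, depth, max_cells)
}

#' @export
print.suffix_tree <- function(x, ...) {
  cat("suffix_tree: depth", x$depth, "over", length(x$alphabet), "labels;",
      x$total_tuples, "tuples from", x$n_syllables, "syllables\n")
  zeros <- mean(x$counts == 0)
  cat(sprintf("  zero cells: %.1f%% of %d potential (D+1)-tuples (%s)\n",
              100 * zeros, length(x$counts),
              if (validity_check(x)) "valid" else "invalid"))
  invisible(x)
}

#' Suffix occupancy counts and conditional probabilities
#'
#' @param tree a `suffix_tree`.
#' @return `suffix_counts()`: named vector N(suffix); `cond_probs()`: matrix
#'   of plug-in conditional probabilities P(label | suffix), rows with an
#'   unobserved suffix set to 0.
#' @export
suffix_counts <- function(tree) rowSums(tree$counts)

#' @rdname suffix_counts
#' @export
cond_probs <- function(tree) {
  ns <- rowSums(tree$counts)
  p <- tree$counts / ifelse(ns > 0, ns, 1)
  p[ns == 0, ] <- 0
  p
}

# -sum p log2 p along rows, 0 log 0 := 0
neg_plogp_rows <- function(p) {
  t <- p * log2(p)
  t[p == 0] <- 0
  -rowSums(t)
}

#' Entropy rate of a suffix-tree model
#'
#' Plug-in estimate of `H = -sum_ij mu_i P_ij log2 P_ij` (bits/symbol) where
#' `mu_i = N(suffix_i)/total` and `P_ij = N(label_j | suffix_i)/N(suffix_i)`.
#' At depth 0 this is the entropy of the label distribution.
#'
#' @param tree a `suffix_tree` with at least one observed tuple.
#' @return entropy rate in bits/symbol.
#' @export
entropy_rate <- function(tree) {
  stopifnot(inherits(tree, "suffix_tree"))
  if (tree$total_tuples == 0) stop("empty suffix tree: no (D+1)-tuples observed")
  mu <- rowSums(tree$counts) / tree$total_tuples
  sum(mu * neg_plogp_rows(cond_probs(tree)))
}

# Shared pmf set for the mutual-information computations. p_xy is the
# empirical distribution over (D+1)-tuples; by default p_x and p_y are its
# marginals (one ensemble, guaranteeing MI >= 0). x_marginal = "corpus"
# instead uses the label frequencies over all syllables, which can differ at
# sequence boundaries.
tuple_distributions <- function(tree, x_marginal = c("tuple", "corpus")) {
  x_marginal <- match.arg(x_marginal)
  p_xy <- tree$counts / tree$total_tuples
  p_y <- rowSums(p_xy)
  p_x <- if (x_marginal == "tuple") colSums(p_xy) else
    tree$zero_counts / sum(tree$zero_counts)
  list(p_xy = p_xy, p_y = p_y, p_x = p_x)
}

#' Syntax Information Score (SIS) of a suffix-tree model
#'
#' The SIS is the mutual information (bits/symbol) between a syllable label X
#' and its length-D suffix Y: `I(X;Y) = sum p(x,y) log2[p(x,y)/(p(x)p(y))]`,
#' with all three pmfs taken from the same empirical (D+1)-tuple ensemble
#' (`p(x)` and `p(y)` as marginals of `p(x,y)`), which guarantees
#' `SIS >= 0` and the identity `SIS = H(p_x) - H(X|Y)`. Setting
#' `x_marginal = "corpus"` uses the 0th-order label pmf over all syllables
#' instead; the two differ only through sequence-boundary effects.
#'
#' @param tree a `suffix_tree` of depth >= 1.
#' @param x_marginal `"tuple"` (default) or `"corpus"`.
#' @return SIS in bits/symbol.
#' @export
sis <- function(tree, x_marginal = c("tuple", "corpus")) {
  sum(sis_contributions(tree, x_marginal))
}

#' Per-motif contributions to the SIS
#'
#' Decomposes the SIS into the contribution of every (D+1)-tuple:
#' `p(x,y) * log2[p(x,y)/(p(x)p(y))]`, the pointwise KL term. Contributions
#' sum exactly to the SIS; individual motifs may contribute negatively
#' (observed less often than independence predicts); unobserved tuples
#' contribute 0.
#'
#' @inheritParams sis
#' @return matrix (suffix x label) of contributions in bits.
#' @export
sis_contributions <- function(tree, x_marginal = c("tuple", "corpus")) {
  stopifnot(inherits(tree, "suffix_tree"))
  if (tree$depth < 1) stop("SIS requires depth >= 1 (no suffix at depth 0)")
  if (tree$total_tuples == 0) stop("empty suffix tree: no (D+1)-tuples observed")
  d <- tuple_distributions(tree, x_marginal)
  q <- outer(d$p_y, d$p_x)
  contrib <- d$p_xy * log2(d$p_xy / q)
  contrib[d$p_xy == 0] <- 0
  contrib
}

#' Zero-cell validity criterion for a suffix-tree estimate
#'
#' A plug-in estimate is accepted only if the fraction of unobserved
#' (D+1)-tuples among all `N_c^(D+1)` potential ones is below
#' `max_zero_fraction` (default 10%); too many unobserved cells indicate that
#' the data cannot support the model order.
#'
#' @param tree a `suffix_tree`.
#' @param max_zero_fraction rejection threshold (default 0.10).
#' @return logical.
#' @export
validity_check <- function(tree, max_zero_fraction = 0.10) {
  mean(tree$counts == 0) < max_zero_fraction
}

#' Normalized SIS
#'
#' SIS divided by `log2(N_c)`, the number of bits needed to encode one label,
#' making scores comparable across alphabet sizes. Lies in `[0, 1]`.
#'
#' @inheritParams sis
#' @return dimensionless score.
#' @export
normalized_sis <- function(tree, x_marginal = c("tuple", "corpus")) {
  nc <- length(tree$alphabet)
  if (nc < 2) stop("normalized SIS requires at least 2 labels")
  sis(tree, x_marginal) / log2(nc)
}

#' Resampled entropy rate and SIS with uncertainty
#'
#' Repeats the model fit `reps` times, each time on a random subset of
#' `ceil(frac * n_sequences)` sequences drawn without replacement, and
#' reports the mean and twice the standard deviation of the entropy rate and
#' SIS (the conventional 25 repetitions on 60% of the sequences by default).
#'
#' @param corpus a labeled `usv_corpus` with at least 2 sequences.
#' @param depth suffix depth.
#' @param reps repetitions (default 25).
#' @param frac fraction of sequences per repetition, in (0, 1].
#' @param seed optional integer seed.
#' @return list with `mean_entropy`, `sd2_entropy`, `mean_sis`, `sd2_sis`
#'   (SIS entries are `NA` at depth 0), `reps`, `depth`.
#' @export
resampled_scores <- function(corpus, depth, reps = 25, frac = 0.6,
                             seed = NULL) {
  if (!(frac > 0 && frac <= 1)) stop("frac must be in (0, 1]")
  ids <- unique(corpus$syllables$seq_id)
  if (length(ids) < 2) stop("need at least 2 sequences to resample")
  if (!is.null(seed)) set.seed(seed)
  seqs <- label_sequences(corpus)
  alphabet <- if (!is.null(corpus$alphabet)) corpus$alphabet else
    sort(unique(unlist(seqs)))
  n_take <- ceiling(frac * length(seqs))
  H <- numeric(reps); S <- numeric(reps)
  for (i in seq_len(reps)) {
    take <- sample(length(seqs), n_take)
    tr <- tree_from_label_seqs(seqs[take], alphabet, depth)
    H[i] <- entropy_rate(tr)
    S[i] <- if (depth >= 1) sis(tr) else NA_real_
  }
  sd2 <- function(x) if (length(x) < 2) 0 else 2 * stats::sd(x)
  list(mean_entropy = mean(H), sd2_entropy = sd2(H),
       mean_sis = mean(S),
       sd2_sis = if (depth >= 1) sd2(S) else NA_real_,
       reps = reps, depth = depth)
}

#' Entropy-rate curve over model depths
#'
#' @param corpus labeled `usv_corpus`.
#' @param max_depth deepest model to fit.
#' @return data.frame with columns `depth`, `entropy_rate`, `sis`
#'   (`NA` at depth 0), `valid`.
#' @export
entropy_rate_curve <- function(corpus, max_depth) {
  rows <- lapply(0:max_depth, function(d) {
    tr <- build_suffix_tree(corpus, d)
    data.frame(depth = d, entropy_rate = entropy_rate(tr),
               sis = if (d >= 1) sis(tr) else NA_real_,
               valid = validity_check(tr))
  })
  do.call(rbind, rows)
}

#' Syntax score summary for a labeled corpus
#'
#' Convenience wrapper: fits the depth-D suffix tree and returns its entropy
#' rate, SIS, normalized SIS and validity in one object.
#'
#' @inheritParams build_suffix_tree
#' @return object of class `syntax_score`.
#' @export
syntax_score <- function(corpus, depth) {
  tr <- build_suffix_tree(corpus, depth)
  structure(
    list(entropy_rate = entropy_rate(tr),
         sis = if (depth >= 1) sis(tr) else NA_real_,
         normalized_sis = if (depth >= 1 && length(tr$alphabet) >= 2)
           normalized_sis(tr) else NA_real_,
         depth = depth, n_tuples = tr$total_tuples,
         valid = validity_check(tr)),
    class = "syntax_score"
  )
}

#' @export
print.syntax_score <- function(x, ...) {
  cat(sprintf("syntax_score (depth %d, %d tuples%s):\n", x$depth, x$n_tuples,
              if (x$valid) "" else ", INVALID estimate"))
  cat(sprintf("  entropy rate   %.4f bits/symbol\n", x$entropy_rate))
  if (!is.na(x$sis)) {
    cat(sprintf("  SIS            %.4f bits/symbol\n", x$sis))
    cat(sprintf("  normalized SIS %.4f\n", x$normalized_sis))
  }
  invisible(x)
}

#' Display a stored suffix in reading order
#'
#' Suffixes are stored oldest label first; the conventional display reads
#' them newest first ("read from right to left").
#'
#' @param key suffix key string (labels joined by `:`).
#' @return character; the reversed suffix.
#' @export
format_suffix <- function(key) {
  vapply(strsplit(key, SUFFIX_SEP, fixed = TRUE), function(p) {
    paste(rev(p), collapse = "")
  }, character(1))
}
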