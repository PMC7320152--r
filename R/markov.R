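# Synthetic Markov ground-truth models: a depth-D chain specified by its
# conditional probabilities p(x | suffix), with analytic stationary
# distribution (the eigenvalue-1 eigenvector of the suffix-state transition
# matrix), entropy rate and SIS. Used to validate the plug-in suffix-tree
# estimators on generated realizations.

#' Define a synthetic Markov ground-truth model
#'
#' The model is a D-order Markov chain over a label alphabet, given as a
#' `N_c^D x N_c` matrix of conditional probabilities `p(label | suffix)`.
#' Rows follow the canonical suffix order of [build_suffix_tree()] (oldest
#' label most significant). Any D-order chain is equivalently a 1st-order
#' chain over suffix states, which is how the stationary distribution is
#' obtained.
#'
#' @param cond_probs numeric matrix, `N_c^depth` rows summing to 1, one
#'   column per label.
#' @param alphabet character vector of labels (defaults to column names).
#' @param depth model order D (inferred from the row count when `NULL`).
#' @return object of class `markov_model`.
#' @export
markov_model <- function(cond_probs, alphabet = colnames(cond_probs),
                         depth = NULL) {
  cond_probs <- as.matrix(cond_probs)
  if (is.null(alphabet)) {
    alphabet <- paste0("L", seq_len(ncol(cond_probs)))
  }
  nc <- length(alphabet)
  if (ncol(cond_probs) != nc) stop("one column per label required")
  if (is.null(depth)) {
    depth <- round(log(nrow(cond_probs)) / log(nc))
  }
  if (nrow(cond_probs) != nc^depth) {
    stop("expected ", nc^depth, " rows (N_c^depth), got ", nrow(cond_probs))
  }
  if (any(cond_probs < 0)) stop("negative conditional probability")
  if (any(abs(rowSums(cond_probs) - 1) > 1e-12)) {
    stop("each conditional distribution must sum to 1 (tolerance 1e-12)")
  }
  dimnames(cond_probs) <- list(suffix_keys(alphabet, depth), alphabet)
  structure(list(depth = depth, alphabet = alphabet, cond_probs = cond_probs),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("markov_model: order", x$depth, "over", length(x$alphabet), "labels (",
      paste(x$alphabet, collapse = " "), ")\n")
  invisible(x)
}

#' Convenience constructor: a chain with a tunable self-transition bias
#'
#' Each label follows itself (the newest label of the suffix) with
#' probability `stay_prob` and any other label uniformly otherwise. A handy
#' source of chains with known, dialable syntax strength.
#'
#' @param n_labels alphabet size.
#' @param stay_prob probability of repeating the previous label.
#' @param depth model order (the bias always acts on the newest suffix label).
#' @param alphabet optional label names.
#' @return a `markov_model`.
#' @export
persistent_markov_model <- function(n_labels, stay_prob, depth = 1,
                                    alphabet = NULL) {
  stopifnot(n_labels >= 2, stay_prob >= 0, stay_prob <= 1, depth >= 1)
  if (is.null(alphabet)) alphabet <- paste0("C", seq_len(n_labels))
  ns <- n_labels^depth
  cond <- matrix((1 - stay_prob) / (n_labels - 1), nrow = ns, ncol = n_labels)
  # newest suffix label = least significant digit of the row index
  newest <- ((seq_len(ns) - 1) %% n_labels) + 1
  cond[cbind(seq_len(ns), newest)] <- stay_prob
  markov_model(cond, alphabet, depth)
}

# 1st-order transition matrix over the N_c^D suffix states: from suffix
# (a_1..a_D), emitting label x moves to (a_2..a_D, x).
state_transition_matrix <- function(model) {
  nc <- length(model$alphabet)
  d <- model$depth
  ns <- nc^d
  P <- matrix(0, ns, ns,
              dimnames = list(rownames(model$cond_probs),
                              rownames(model$cond_probs)))
  if (d == 0) return(matrix(1, 1, 1, dimnames = list("", "")))
  from <- seq_len(ns)
  base <- ((from - 1) %% nc^(d - 1)) * nc
  for (x in seq_len(nc)) {
    to <- base + x
    P[cbind(from, to)] <- P[cbind(from, to)] + model$cond_probs[, x]
  }
  P
}

# Strong connectivity of the positive-transition graph via boolean
# transitive closure (matrix squaring).
is_irreducible <- function(P) {
  A <- (P > 0) | diag(nrow(P)) > 0
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  all(A)
}

#' Analytic stationary distribution over suffix states
#'
#' Computes `mu = e / sum(e)` where `e` is the eigenvector of the suffix-state
#' transition matrix with eigenvalue 1, after verifying irreducibility.
#'
#' @param model a `markov_model`.
#' @return named numeric vector `mu` with `mu >= 0`, `sum(mu) == 1` and
#'   `mu %*% P == mu` to 1e-9.
#' @export
analytic_stationary <- function(model) {
  P <- state_transition_matrix(model)
  if (nrow(P) == 1) return(stats::setNames(1, rownames(P)))
  if (!is_irreducible(P)) {
    stop("chain is reducible: no unique stationary distribution")
  }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-8) {
    stop("no eigenvalue-1 eigenvector found")
  }
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  v[v < 0 & v > -1e-12] <- 0
  v <- v / sum(v)
  if (max(abs(drop(v %*% P) - v)) > 1e-9) {
    stop("stationary distribution failed the mu %*% P == mu check")
  }
  stats::setNames(v, rownames(P))
}

#' Analytic entropy rate of a Markov ground-truth model
#'
#' Closed-form `H = -sum_ij mu_i P_ij log2 P_ij` with `mu` the analytic
#' stationary distribution over suffixes and `P_ij` the model's conditional
#' probabilities.
#'
#' @param model a `markov_model`.
#' @return bits/symbol.
#' @export
analytic_entropy_rate <- function(model) {
  mu <- analytic_stationary(model)
  sum(mu * neg_plogp_rows(model$cond_probs))
}

#' Analytic SIS of a Markov ground-truth model
#'
#' Mutual information between the next label and the suffix under the
#' stationary law: `p(y) = mu`, `p(x,y) = mu_y * p(x|y)`, and `p(x)` the
#' label marginal of `p(x,y)` (which equals the stationary 0th-order label
#' distribution). Equals `H(p_x) - analytic_entropy_rate(model)`.
#'
#' @param model a `markov_model` of order >= 1.
#' @return bits/symbol, always >= 0.
#' @export
analytic_sis <- function(model) {
  if (model$depth < 1) stop("SIS requires a model of order >= 1")
  mu <- analytic_stationary(model)
  p_xy <- model$cond_probs * mu
  p_x <- colSums(p_xy)
  q <- outer(mu, p_x)
  contrib <- p_xy * log2(p_xy / q)
  contrib[p_xy == 0] <- 0
  sum(contrib)
}

#' Exact-count suffix tree of a ground-truth model
#'
#' Loads the model's stationary tuple probabilities into a `suffix_tree` as
#' (fractional) counts, so the plug-in [entropy_rate()] and [sis()] evaluate
#' the analytic quantities exactly — the zero-sample limit of estimation.
#'
#' @param model a `markov_model`.
#' @return a `suffix_tree` with probability-mass "counts".
#' @export
as_suffix_tree <- function(model) {
  mu <- analytic_stationary(model)
  counts <- model$cond_probs * mu
  structure(
    list(depth = model$depth, alphabet = model$alphabet, counts = counts,
         zero_counts = colSums(counts), total_tuples = sum(counts),
         n_syllables = NA_integer_),
    class = "suffix_tree"
  )
}

#' Generate labeled sequences from a ground-truth model
#'
#' Realizations are generated syllable-by-syllable: the initial D labels of
#' each sequence are drawn from the stationary suffix distribution (so the
#' generated ensemble is itself stationary), and every further label from the
#' conditional distribution of the current suffix.
#'
#' @param model a `markov_model`.
#' @param n_sequences number of sequences.
#' @param length_sampler function(n) returning n sequence lengths (>= 1);
#'   default: truncated power law with exponent -1.88 on
#'   `{depth+1, ..., 100}`.
#' @param seed optional integer seed.
#' @return a labeled `usv_corpus` (times on a nominal grid; see
#'   [corpus_from_label_sequences()]).
#' @export
generate_sequences <- function(model, n_sequences, length_sampler = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(length_sampler)) {
    lo <- max(2, model$depth + 1)
    length_sampler <- function(n) rtrunc_power(n, b = -1.88, xmin = lo, xmax = 100)
  }
  lens <- length_sampler(n_sequences)
  if (length(lens) != n_sequences || any(lens < 1) || any(lens != round(lens))) {
    stop("length_sampler must return ", n_sequences, " integer lengths >= 1")
  }
  seqs <- generate_label_seqs(model, lens)
  corpus_from_label_sequences(seqs, alphabet = model$alphabet,
                              provenance = "synthetic Markov realization")
}

# core sampler (uses the current RNG stream)
generate_label_seqs <- function(model, lens) {
  nc <- length(model$alphabet)
  d <- model$depth
  mu <- analytic_stationary(model)
  cum <- t(apply(model$cond_probs, 1, cumsum))
  ns <- nrow(cum)
  shift <- if (d >= 1) nc^(d - 1) else 1
  lapply(lens, function(L) {
    out <- integer(L)
    if (d == 0) {
      out <- pmin(findInterval(stats::runif(L), cum[1, ]) + 1L, nc)
      return(model$alphabet[out])
    }
    state <- sample.int(ns, 1, prob = mu)
    # unpack initial suffix digits, oldest first
    k <- state - 1L
    init <- integer(d)
    for (j in seq_len(d)) {
      w <- nc^(d - j)
      init[j] <- (k %/% w) + 1L
      k <- k %% w
    }
    n_init <- min(d, L)
    out[seq_len(n_init)] <- init[seq_len(n_init)]
    if (L > d) {
      u <- stats::runif(L - d)
      for (t in (d + 1):L) {
        x <- findInterval(u[t - d], cum[state, ]) + 1L
        if (x > nc) x <- nc
        out[t] <- x
        state <- ((state - 1L) %% shift) * nc + x
      }
    }
    model$alphabet[out]
  })
}

#' Estimation error of the plug-in scores on generated data
#'
#' Generates about `n_syllables` syllables from the model (sequence lengths
#' from the default sampler), fits a suffix tree of the model's own depth,
#' and returns the absolute differences between the plug-in and analytic
#' entropy rate and SIS.
#'
#' @param model a `markov_model`.
#' @param n_syllables target number of generated syllables.
#' @param seed optional integer seed.
#' @param length_sampler optional function(n) of sequence lengths.
#' @return list with `delta_entropy`, `delta_sis` (`NA` for order-0 models),
#'   `valid` (the zero-cell criterion of the estimated tree),
#'   `n_syllables` actually generated.
#' @export
estimation_error <- function(model, n_syllables, seed = NULL,
                             length_sampler = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(length_sampler)) {
    lo <- max(2, model$depth + 1)
    length_sampler <- function(n) rtrunc_power(n, b = -1.88, xmin = lo, xmax = 100)
  }
  lens <- integer(0)
  while (sum(lens) < n_syllables) {
    need <- n_syllables - sum(lens)
    lens <- c(lens, length_sampler(max(16, ceiling(need / 6))))
  }
  lens <- lens[cumsum(lens) - lens < n_syllables]
  seqs <- generate_label_seqs(model, lens)
  tree <- tree_from_label_seqs(seqs, model$alphabet, model$depth)
  dh <- abs(entropy_rate(tree) - analytic_entropy_rate(model))
  ds <- if (model$depth >= 1) abs(sis(tree) - analytic_sis(model)) else NA_real_
  list(delta_entropy = dh, delta_sis = ds,
       valid = validity_check(tree), n_syllables = sum(lens))
}
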