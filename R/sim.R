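# Syntax Information Maximization (SIM): greedy refinement of a centroid set
# by multiplicative random perturbation. Each iteration draws one random
# vector V (entries uniform in [0.9, 1.1]), perturbs each centroid in turn
# with the same V (elementwise product), re-assigns every training syllable
# and evaluates the SIS of the resulting labeling; the best candidate is
# applied if it beats the current SIS, otherwise a failure counter grows and
# at 5 consecutive failures the best candidate is force-applied. After
# convergence on the training set, the recorded perturbation chain is
# replayed on the held-out test set.

#' Split a corpus into SIM training and test halves
#'
#' Sequences are shuffled and split 50/50 (an odd count gives the training
#' half the extra sequence), keeping whole sequences together.
#'
#' @param corpus a `usv_corpus` with features.
#' @param seed optional integer seed for the shuffle.
#' @return list with `train` and `test` corpora.
#' @export
sim_split <- function(corpus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(corpus$syllables$seq_id)
  if (length(ids) < 2) stop("need at least 2 sequences to split")
  ids <- sample(ids)
  n_train <- ceiling(length(ids) / 2)
  list(train = subset_sequences(corpus, ids[seq_len(n_train)]),
       test = subset_sequences(corpus, ids[-seq_len(n_train)]))
}

#' Multiplicative perturbation vector
#'
#' @param dim vector length.
#' @param seed optional integer seed.
#' @param range perturbation bounds (default `[0.9, 1.1]`).
#' @return numeric vector of iid uniform entries in `range`.
#' @export
perturbation_vector <- function(dim, seed = NULL, range = c(0.9, 1.1)) {
  stopifnot(dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(dim, range[1], range[2])
}

# SIS of the labeling induced by assigning `features` to `centroids`,
# with sequence structure given by seq_id.
assignment_sis <- function(features, seq_id, centroids, depth) {
  labels <- assign_by_centroid(features, centroids)
  seqs <- unname(split(labels, seq_id))
  tree <- tree_from_label_seqs(seqs, centroids$labels, depth)
  if (tree$total_tuples == 0) {
    stop("no (D+1)-tuples in the assignment; sequences too short for depth ",
         depth)
  }
  sis(tree)
}

#' Initialize a SIM optimizer state
#'
#' @param train,test `usv_corpus` objects carrying feature matrices (see
#'   [sim_split()]).
#' @param centroids initial `usv_centroids`.
#' @param depth suffix depth at which the SIS is optimized (default 1).
#' @param seed integer seed governing every random draw of the run.
#' @return object of class `sim_state`.
#' @export
sim_state <- function(train, test, centroids, depth = 1, seed = 1) {
  stopifnot(inherits(centroids, "usv_centroids"))
  if (is.null(train$features) || is.null(test$features)) {
    stop("train and test corpora must carry feature matrices")
  }
  st <- structure(
    list(centroids = centroids,
         init_centroids = centroids,
         train_features = train$features,
         train_seq = train$syllables$seq_id,
         test_features = test$features,
         test_seq = test$syllables$seq_id,
         depth = depth,
         seed = seed,
         failure_counter = 0L,
         applied = list(),
         sis_train = NA_real_,
         sis_train_history = numeric(0),
         sis_test_history = numeric(0),
         converged = FALSE,
         iterations = 0L),
    class = "sim_state")
  st$sis_train <- assignment_sis(st$train_features, st$train_seq,
                                 centroids, depth)
  st$sis_train_history <- st$sis_train
  st
}

#' Evaluate one centroid perturbation without changing the state
#'
#' Forms the candidate centroid as the elementwise product of centroid
#' `index` with `V`, re-assigns all training syllables against the candidate
#' set, and reports the SIS change.
#'
#' @param state a `sim_state`.
#' @param index centroid row to perturb.
#' @param V multiplicative perturbation vector (length = feature dimension).
#' @return list with `delta` (candidate SIS minus current training SIS),
#'   `sis` (candidate SIS) and `centroids` (the candidate set).
#' @export
evaluate_perturbation <- function(state, index, V) {
  cents <- state$centroids
  if (length(V) != ncol(cents$centroids)) {
    stop("perturbation length ", length(V), " does not match centroid dimension ",
         ncol(cents$centroids))
  }
  cents$centroids[index, ] <- cents$centroids[index, ] * V
  s <- assignment_sis(state$train_features, state$train_seq, cents, state$depth)
  list(delta = s - state$sis_train, sis = s, centroids = cents)
}

#' One SIM iteration
#'
#' Draws a fresh perturbation vector from the state's RNG stream, tries it on
#' every centroid, and applies the acceptance rule: the best candidate SIS is
#' applied if it exceeds the current training SIS (failure counter resets to
#' 0); otherwise the failure counter increments, and on reaching 5 the best
#' candidate is applied regardless and the counter resets.
#'
#' @param state a `sim_state`.
#' @param failure_limit forced-apply threshold (default 5).
#' @return the updated `sim_state`.
#' @export
sim_step <- function(state, failure_limit = 5) {
  k <- nrow(state$centroids$centroids)
  V <- perturbation_vector(ncol(state$centroids$centroids))
  cand_sis <- numeric(k)
  cands <- vector("list", k)
  for (i in seq_len(k)) {
    ev <- evaluate_perturbation(state, i, V)
    cand_sis[i] <- ev$sis
    cands[[i]] <- ev$centroids
  }
  best <- which.max(cand_sis)
  state$iterations <- state$iterations + 1L
  if (cand_sis[best] > state$sis_train) {
    state <- apply_perturbation(state, best, V, cands[[best]],
                                cand_sis[best], forced = FALSE)
  } else {
    state$failure_counter <- state$failure_counter + 1L
    if (state$failure_counter >= failure_limit) {
      state <- apply_perturbation(state, best, V, cands[[best]],
                                  cand_sis[best], forced = TRUE)
    }
  }
  state
}

apply_perturbation <- function(state, index, V, centroids, new_sis, forced) {
  state$centroids <- centroids
  state$sis_train <- new_sis
  state$failure_counter <- 0L
  state$applied <- c(state$applied,
                     list(list(index = index, V = V, forced = forced,
                               sis_after = new_sis)))
  state$sis_train_history <- c(state$sis_train_history, new_sis)
  state
}

#' Run SIM to convergence and replay the chain on the test set
#'
#' Iterates [sim_step()] until the training SIS converges (the best-so-far
#' training SIS has improved by at most `tol` over the last `window` applied
#' perturbations) or `max_iters` iterations have been spent. The recorded
#' perturbation chain is then replayed from the initial centroids on the test
#' corpus, logging the test SIS after every applied perturbation; index 1 of
#' both histories is the SIS of the initial labeling.
#'
#' The whole run, replay included, is reproducible from `state$seed`.
#'
#' @param state a `sim_state`.
#' @param max_iters iteration budget (default 500).
#' @param tol convergence tolerance in bits (default 1e-4).
#' @param window applied-perturbation window for the convergence test
#'   (default 20).
#' @param failure_limit forced-apply threshold (default 5).
#' @return the final `sim_state`, with `sis_train_history`,
#'   `sis_test_history`, `applied`, `converged` and `iterations` filled in.
#' @export
run_sim <- function(state, max_iters = 500, tol = 1e-4, window = 20,
                    failure_limit = 5) {
  set.seed(state$seed)
  for (it in seq_len(max_iters)) {
    state <- sim_step(state, failure_limit = failure_limit)
    n_app <- length(state$applied)
    if (n_app > window) {
      b <- cummax(state$sis_train_history)
      if (b[n_app + 1] - b[n_app + 1 - window] <= tol) {
        state$converged <- TRUE
        break
      }
    }
  }
  state$sis_test_history <- replay_sim(state)
  state
}

#' Replay a recorded perturbation chain on the test corpus
#'
#' Deterministic: starts from the initial centroids and applies the stored
#' perturbations in order, evaluating the test-set SIS after each.
#'
#' @param state a `sim_state` after (or during) a run.
#' @return numeric vector of test SIS values, one per history entry
#'   (index 1 = initial labeling).
#' @export
replay_sim <- function(state) {
  cents <- state$init_centroids
  out <- numeric(length(state$applied) + 1)
  out[1] <- assignment_sis(state$test_features, state$test_seq,
                           cents, state$depth)
  for (i in seq_along(state$applied)) {
    ap <- state$applied[[i]]
    cents$centroids[ap$index, ] <- cents$centroids[ap$index, ] * ap$V
    out[i + 1] <- assignment_sis(state$test_features, state$test_seq,
                                 cents, state$depth)
  }
  out
}

#' @export
print.sim_state <- function(x, ...) {
  cat("sim_state: depth", x$depth, "|", nrow(x$centroids$centroids),
      "centroids x", ncol(x$centroids$centroids), "dims\n")
  cat(sprintf("  %d iterations, %d applied perturbations (%d forced)%s\n",
              x$iterations, length(x$applied),
              sum(vapply(x$applied, function(a) a$forced, logical(1))),
              if (x$converged) ", converged" else ""))
  cat(sprintf("  train SIS %.4f -> %.4f bits/symbol\n",
              x$sis_train_history[1], x$sis_train))
  if (length(x$sis_test_history) > 0) {
    cat(sprintf("  test SIS  %.4f -> %.4f bits/symbol\n",
                x$sis_test_history[1],
                x$sis_test_history[length(x$sis_test_history)]))
  }
  invisible(x)
}
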