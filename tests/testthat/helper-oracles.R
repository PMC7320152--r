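# Independent brute-force oracles: recompute entropy rate and mutual
# information directly from enumerated (D+1)-tuples with plain loops,
# sharing no code with the package internals.

naive_tuples <- function(label_seqs, depth) {
  out <- list()
  for (s in label_seqs) {
    L <- length(s)
    if (L < depth + 1) next
    for (i in seq_len(L - depth)) {
      out[[length(out) + 1]] <- s[i:(i + depth)]
    }
  }
  out
}

naive_entropy_rate <- function(label_seqs, depth) {
  tups <- naive_tuples(label_seqs, depth)
  suf <- vapply(tups, function(t) paste(t[seq_len(depth)], collapse = "\r"),
                character(1))
  nxt <- vapply(tups, function(t) t[depth + 1], character(1))
  total <- length(tups)
  H <- 0
  for (s in unique(suf)) {
    in_s <- suf == s
    mu <- sum(in_s) / total
    p <- table(nxt[in_s]) / sum(in_s)
    H <- H - mu * sum(p * log2(p))
  }
  unname(H)
}

naive_mi <- function(label_seqs, depth) {
  tups <- naive_tuples(label_seqs, depth)
  suf <- vapply(tups, function(t) paste(t[seq_len(depth)], collapse = "\r"),
                character(1))
  nxt <- vapply(tups, function(t) t[depth + 1], character(1))
  total <- length(tups)
  joint <- table(suf, nxt) / total
  py <- rowSums(joint); px <- colSums(joint)
  mi <- 0
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log2(joint[i, j] / (py[i] * px[j]))
      }
    }
  }
  unname(mi)
}

# stationary distribution by power iteration (independent of eigen())
power_iter_stationary <- function(P, iters = 10000, tol = 1e-13) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) {
    v2 <- drop(v %*% P)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# quick timed syllable table on a single sequence-friendly grid
grid_syllables <- function(n, duration = 0.03, gap = 0.05) {
  start <- (0:(n - 1)) * (duration + gap)
  data.frame(start_s = start, end_s = start + duration)
}
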