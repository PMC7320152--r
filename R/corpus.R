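# Corpus containers: syllable tables, ISI-based sequence segmentation, label
# remapping. A corpus is the unit every downstream model (suffix trees, SIM)
# consumes.

#' Construct a USV corpus
#'
#' A corpus bundles a syllable table (one row per syllable, time-ordered),
#' an optional label alphabet, and an optional feature matrix whose rows are
#' aligned with the syllable rows. Sequence membership is carried in the
#' `seq_id` column; use [segment_into_sequences()] to derive it from
#' inter-syllable intervals.
#'
#' @param syllables data.frame with at least `start_s`, `end_s` and `seq_id`
#'   columns (times in seconds). Optional columns: `mean_freq_hz`,
#'   `jump_count`, `jump_dirs` (comma-separated `"up"`/`"down"`), `label`.
#'   A `duration_s` column is (re)derived as `end_s - start_s`.
#' @param alphabet character vector of distinct label symbols, or `NULL` to
#'   infer from the `label` column when present.
#' @param features numeric matrix with one row per syllable, or `NULL`.
#' @param provenance free-text origin note.
#' @return An object of class `usv_corpus`.
#' @export
usv_corpus <- function(syllables, alphabet = NULL, features = NULL,
                       provenance = "") {
  stopifnot(is.data.frame(syllables))
  req <- c("start_s", "end_s", "seq_id")
  miss <- setdiff(req, names(syllables))
  if (length(miss) > 0) {
    stop("syllable table is missing column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(syllables)
  if (n > 0) {
    if (any(syllables$end_s <= syllables$start_s)) {
      bad <- which(syllables$end_s <= syllables$start_s)[1]
      stop("syllable ", bad, " has end_s <= start_s")
    }
    check_time_order(syllables)
    syllables$duration_s <- syllables$end_s - syllables$start_s
    if (is.unsorted(syllables$seq_id)) {
      stop("seq_id must be non-decreasing")
    }
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != n) {
      stop("feature matrix has ", nrow(features), " rows for ", n, " syllables")
    }
  }
  if (!is.null(alphabet)) {
    alphabet <- as.character(alphabet)
    if (anyDuplicated(alphabet)) stop("alphabet symbols must be distinct")
    if (!is.null(syllables$label)) {
      lab <- syllables$label[!is.na(syllables$label)]
      unknown <- setdiff(unique(lab), alphabet)
      if (length(unknown) > 0) {
        stop("label(s) not in alphabet: ", paste(unknown, collapse = ", "))
      }
    }
  } else if (!is.null(syllables$label) && !anyNA(syllables$label)) {
    alphabet <- sort(unique(as.character(syllables$label)))
  }
  structure(
    list(syllables = syllables, alphabet = alphabet, features = features,
         provenance = provenance),
    class = "usv_corpus"
  )
}

check_time_order <- function(df) {
  n <- nrow(df)
  if (n < 2) return(invisible(TRUE))
  if (is.unsorted(df$start_s)) {
    i <- which(diff(df$start_s) < 0)[1]
    stop("syllables are not sorted by start time: rows ", i, " and ", i + 1,
         " (start ", df$start_s[i], " > ", df$start_s[i + 1], ")")
  }
  ov <- which(df$start_s[-1] < df$end_s[-n])
  if (length(ov) > 0) {
    i <- ov[1]
    stop("syllables overlap: row ", i, " ends at ", df$end_s[i],
         " after row ", i + 1, " starts at ", df$start_s[i + 1])
  }
  invisible(TRUE)
}

#' @export
print.usv_corpus <- function(x, ...) {
  cat("usv_corpus:", nrow(x$syllables), "syllables in",
      n_sequences(x), "sequences\n")
  if (!is.null(x$alphabet)) {
    cat("  alphabet (", length(x$alphabet), "): ",
        paste(x$alphabet, collapse = " "), "\n", sep = "")
  }
  if (!is.null(x$features)) {
    cat("  features:", ncol(x$features), "dimensions\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of syllables / sequences in a corpus
#' @param corpus a `usv_corpus`.
#' @return integer count.
#' @export
n_syllables <- function(corpus) nrow(corpus$syllables)

#' @rdname n_syllables
#' @export
n_sequences <- function(corpus) length(unique(corpus$syllables$seq_id))

#' Per-sequence label vectors
#'
#' @param corpus a labeled `usv_corpus`.
#' @return list of character vectors, one per sequence, in corpus order.
#' @export
label_sequences <- function(corpus) {
  lab <- corpus$syllables$label
  if (is.null(lab)) stop("corpus has no labels")
  unname(split(as.character(lab), corpus$syllables$seq_id))
}

#' Inter-syllable intervals within each sequence
#'
#' The ISI between consecutive syllables is `next start_s - previous end_s`.
#'
#' @param corpus a `usv_corpus`.
#' @return list of numeric vectors (seconds), one per sequence; a sequence of
#'   one syllable yields a zero-length vector.
#' @export
corpus_isis <- function(corpus) {
  df <- corpus$syllables
  lapply(unname(split(seq_len(nrow(df)), df$seq_id)), function(i) {
    if (length(i) < 2) return(numeric(0))
    df$start_s[i[-1]] - df$end_s[i[-length(i)]]
  })
}

#' Segment a syllable table into sequences by inter-syllable interval
#'
#' An ISI strictly greater than `isi_threshold` ends the current sequence and
#' starts a new one (an ISI exactly equal to the threshold keeps the sequence
#' going). The default threshold of 160 ms is the convention used for mouse
#' USV recordings.
#'
#' @param syllables data.frame with `start_s` and `end_s` columns, sorted by
#'   start time and non-overlapping.
#' @param isi_threshold seconds; default 0.160.
#' @inheritParams usv_corpus
#' @return a `usv_corpus` whose `seq_id` column encodes the segmentation.
#' @export
segment_into_sequences <- function(syllables, isi_threshold = 0.160,
                                   alphabet = NULL, features = NULL,
                                   provenance = "") {
  stopifnot(is.data.frame(syllables), isi_threshold > 0)
  n <- nrow(syllables)
  if (n == 0) stop("no syllables to segment")
  check_time_order(syllables)
  if (n == 1) {
    syllables$seq_id <- 1L
  } else {
    isi <- syllables$start_s[-1] - syllables$end_s[-n]
    syllables$seq_id <- cumsum(c(1L, as.integer(isi > isi_threshold)))
  }
  usv_corpus(syllables, alphabet = alphabet, features = features,
             provenance = provenance)
}

#' Flatten a corpus back to its syllable table
#'
#' Inverse of [segment_into_sequences()] up to the added `seq_id` and
#' `duration_s` columns.
#'
#' @param corpus a `usv_corpus`.
#' @return the syllable data.frame.
#' @export
flatten_corpus <- function(corpus) corpus$syllables

#' Remap corpus labels
#'
#' Applies a label-to-label surjection, e.g. merging an 8-label scheme down to
#' the jump / no-jump dichotomy. Sequence structure is untouched; the output
#' alphabet is the image of the mapping over the input alphabet.
#'
#' @param corpus a labeled `usv_corpus`.
#' @param mapping named character vector, `names(mapping)` = old labels,
#'   values = new labels. Must cover every label in the corpus.
#' @return a relabeled `usv_corpus`.
#' @export
relabel <- function(corpus, mapping) {
  lab <- corpus$syllables$label
  if (is.null(lab)) stop("corpus has no labels")
  unmapped <- setdiff(unique(as.character(lab)), names(mapping))
  if (length(unmapped) > 0) {
    stop("mapping does not cover label(s): ", paste(unmapped, collapse = ", "))
  }
  old_alpha <- if (!is.null(corpus$alphabet)) corpus$alphabet else
    sort(unique(as.character(lab)))
  if (length(setdiff(old_alpha, names(mapping))) > 0) {
    stop("mapping does not cover the corpus alphabet")
  }
  corpus$syllables$label <- unname(mapping[as.character(lab)])
  corpus$alphabet <- unique(unname(mapping[old_alpha]))
  corpus
}

#' Extract a sub-corpus holding the given sequences
#'
#' @param corpus a `usv_corpus`.
#' @param seq_ids sequence identifiers to keep.
#' @return a `usv_corpus`; syllable times are preserved as-is.
#' @export
subset_sequences <- function(corpus, seq_ids) {
  keep <- corpus$syllables$seq_id %in% seq_ids
  if (!any(keep)) stop("no matching sequences")
  feat <- if (is.null(corpus$features)) NULL else
    corpus$features[keep, , drop = FALSE]
  df <- corpus$syllables[keep, , drop = FALSE]
  # re-sort sequences chronologically so time-order invariants hold
  ord <- order(df$start_s)
  df <- df[ord, , drop = FALSE]
  if (!is.null(feat)) feat <- feat[ord, , drop = FALSE]
  rownames(df) <- NULL
  usv_corpus(df, alphabet = corpus$alphabet, features = feat,
             provenance = corpus$provenance)
}

#' Build a corpus from bare label sequences
#'
#' Convenience for simulation output where only the label structure matters:
#' syllables are laid out on a regular time grid with within-sequence gaps
#' well under the 160 ms segmentation threshold and between-sequence gaps
#' well over it, so segmentation invariants hold.
#'
#' @param label_seqs list of character vectors.
#' @param alphabet label alphabet; inferred when `NULL`.
#' @param duration_s,gap_s,seq_gap_s layout constants (seconds).
#' @param provenance free-text origin note.
#' @return a labeled `usv_corpus`.
#' @export
corpus_from_label_sequences <- function(label_seqs, alphabet = NULL,
                                        duration_s = 0.03, gap_s = 0.05,
                                        seq_gap_s = 0.3, provenance = "") {
  stopifnot(length(label_seqs) > 0, gap_s <= 0.160, seq_gap_s > 0.160)
  lens <- lengths(label_seqs)
  if (any(lens == 0)) stop("empty label sequence")
  n <- sum(lens)
  seq_id <- rep(seq_along(label_seqs), lens)
  gaps <- ifelse(diff(seq_id) == 0, gap_s, seq_gap_s)
  start <- cumsum(c(0.1, duration_s + gaps))
  df <- data.frame(
    start_s = start,
    end_s = start + duration_s,
    label = unlist(label_seqs, use.names = FALSE),
    seq_id = seq_id,
    stringsAsFactors = FALSE
  )
  usv_corpus(df, alphabet = alphabet, provenance = provenance)
}
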