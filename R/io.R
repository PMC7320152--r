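# Plain-text serialization: syllable tables as CSV (feature columns
# feature_0..feature_{d-1}), corpora / models / trees / centroids as JSON
# with an embedded schema version. Counts are written as exact integers.

SCHEMA_VERSION <- "1"

#' Read / write syllable tables
#'
#' CSV with header columns `start_s`, `end_s` and optionally `mean_freq_hz`,
#' `jump_count`, `jump_dirs`, `label`, `seq_id` and feature columns
#' `feature_0 ... feature_{d-1}`. Times are seconds.
#'
#' @param path CSV file path.
#' @return `read_syllables()`: list with `syllables` (data.frame) and
#'   `features` (matrix or `NULL`).
#' @export
read_syllables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s") %in% names(df))) {
    stop("syllable CSV must have start_s and end_s columns")
  }
  fcols <- grep("^feature_[0-9]+$", names(df), value = TRUE)
  features <- NULL
  if (length(fcols) > 0) {
    fcols <- fcols[order(as.integer(sub("^feature_", "", fcols)))]
    features <- as.matrix(df[, fcols, drop = FALSE])
    df <- df[, setdiff(names(df), fcols), drop = FALSE]
  }
  list(syllables = df, features = features)
}

#' @rdname read_syllables
#' @param syllables data.frame of syllables.
#' @param features optional numeric feature matrix (one row per syllable).
#' @export
write_syllables <- function(syllables, path, features = NULL) {
  df <- syllables
  if (!is.null(features)) {
    features <- as.matrix(features)
    colnames(features) <- paste0("feature_", seq_len(ncol(features)) - 1)
    df <- cbind(df, features)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a corpus as CSV + JSON
#'
#' The syllable table (with features) goes to CSV; the JSON sidecar holds
#' the schema version, alphabet, provenance and the sequences as lists of
#' 0-based row indices into the CSV.
#'
#' @param corpus a `usv_corpus`.
#' @param csv_path,json_path file paths.
#' @return `read_corpus()`: a `usv_corpus`.
#' @export
write_corpus <- function(corpus, csv_path, json_path) {
  df <- corpus$syllables
  write_syllables(df[, setdiff(names(df), "seq_id"), drop = FALSE],
                  csv_path, features = corpus$features)
  rows0 <- unname(split(seq_len(nrow(df)) - 1L, df$seq_id))
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION,
         alphabet = corpus$alphabet,
         provenance = corpus$provenance,
         sequences = rows0),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(json_path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(csv_path, json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  tab <- read_syllables(csv_path)
  df <- tab$syllables
  seq_id <- integer(nrow(df))
  for (i in seq_along(meta$sequences)) {
    seq_id[unlist(meta$sequences[[i]]) + 1L] <- i
  }
  df$seq_id <- seq_id
  alphabet <- if (is.null(meta$alphabet)) NULL else unlist(meta$alphabet)
  usv_corpus(df, alphabet = alphabet, features = tab$features,
             provenance = if (is.null(meta$provenance)) "" else meta$provenance)
}

#' Read / write a Markov ground-truth model as JSON
#'
#' @param model a `markov_model`.
#' @param path JSON file path.
#' @return `read_markov_model()`: a `markov_model`.
#' @export
write_markov_model <- function(model, path) {
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION,
         depth = model$depth,
         alphabet = model$alphabet,
         cond_probs = apply(model$cond_probs, 1, function(r)
           as.list(stats::setNames(r, model$alphabet)), simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_markov_model
#' @export
read_markov_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  alphabet <- unlist(j$alphabet)
  cond <- do.call(rbind, lapply(j$cond_probs, function(r) unlist(r)[alphabet]))
  markov_model(cond, alphabet = alphabet, depth = j$depth)
}

#' Read / write a suffix tree as JSON
#'
#' Counts are serialized exactly (integers when integral).
#'
#' @param tree a `suffix_tree`.
#' @param path JSON file path.
#' @return `read_suffix_tree()`: a `suffix_tree`.
#' @export
write_suffix_tree <- function(tree, path) {
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION,
         depth = tree$depth,
         alphabet = tree$alphabet,
         suffixes = rownames(tree$counts),
         counts = unname(apply(tree$counts, 1, as.list, simplify = FALSE)),
         zero_counts = as.list(tree$zero_counts),
         total_tuples = tree$total_tuples,
         n_syllables = tree$n_syllables),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_suffix_tree
#' @export
read_suffix_tree <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  alphabet <- unlist(j$alphabet)
  counts <- do.call(rbind, lapply(j$counts, function(r) unlist(r)[alphabet]))
  dimnames(counts) <- list(unlist(j$suffixes), alphabet)
  structure(
    list(depth = j$depth, alphabet = alphabet, counts = counts,
         zero_counts = stats::setNames(unlist(j$zero_counts)[alphabet], alphabet),
         total_tuples = j$total_tuples,
         n_syllables = if (is.null(j$n_syllables)) NA_integer_ else j$n_syllables),
    class = "suffix_tree")
}

#' Read / write a centroid set as JSON
#'
#' @param centroids a `usv_centroids`.
#' @param path JSON file path.
#' @return `read_centroids()`: a `usv_centroids`.
#' @export
write_centroids <- function(centroids, path) {
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION,
         k = nrow(centroids$centroids),
         metric = centroids$metric,
         labels = centroids$labels,
         centroids = unname(apply(centroids$centroids, 1, as.list,
                                  simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- do.call(rbind, lapply(j$centroids, function(r) unlist(r)))
  usv_centroids(m, labels = unlist(j$labels), metric = j$metric)
}
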