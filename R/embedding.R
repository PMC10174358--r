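# Word embedding tables, cosine similarity, and the synthetic clustered
# semantic space used when no pretrained embedding file is supplied.

#' Construct an embedding table
#'
#' An embedding table maps lowercase word strings to dense real vectors of a
#' common dimensionality. Lookups are case-folded, so `"Peanut"` and
#' `"peanut"` retrieve the same vector.
#'
#' @param vectors Numeric matrix, one row per word, with the words as row
#'   names. Row names are lowercased; no row may be the all-zeros vector
#'   (cosine similarity would be undefined for it).
#' @return An object of class `embedding_table` with elements `vectors`
#'   (the matrix) and `dim` (vector dimensionality).
#' @export
embedding_table <- function(vectors) {
  if (!is.matrix(vectors) || !is.numeric(vectors))
    stop("`vectors` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(vectors)))
    stop("`vectors` must have words as row names", call. = FALSE)
  if (ncol(vectors) < 1L)
    stop("embedding dimensionality must be positive", call. = FALSE)
  rownames(vectors) <- tolower(rownames(vectors))
  if (anyDuplicated(rownames(vectors)))
    stop("duplicate words after case folding", call. = FALSE)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0))
    stop("all-zeros vectors are not allowed in an embedding table",
         call. = FALSE)
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words, %d dimensions\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' @export
dim.embedding_table <- function(x) dim(x$vectors)

#' Words stored in an embedding table
#' @param table An `embedding_table`.
#' @return Character vector of (lowercase) words.
#' @export
vocabulary <- function(table) rownames(table$vectors)

#' Look up word vectors
#'
#' @param table An `embedding_table`.
#' @param words Character vector of words; lookup is case-insensitive.
#' @return For a single word, a numeric vector; otherwise a matrix with one
#'   row per word.
#' @details Absent words raise an error of class `oov_error`. Callers that
#'   want skip-and-log behaviour (e.g. [preprocess()]) filter beforehand
#'   with [has_word()].
#' @export
embedding <- function(table, words) {
  stopifnot(inherits(table, "embedding_table"))
  words <- tolower(words)
  miss <- setdiff(words, rownames(table$vectors))
  if (length(miss) > 0)
    stop(oov_error(miss))
  if (length(words) == 1L) table$vectors[words, ]
  else table$vectors[words, , drop = FALSE]
}

#' @param word Single word string.
#' @rdname embedding
#' @export
has_word <- function(table, word) {
  tolower(word) %in% rownames(table$vectors)
}

oov_error <- function(words) {
  structure(
    class = c("oov_error", "error", "condition"),
    list(message = paste0("word(s) not in embedding table: ",
                          paste(words, collapse = ", ")),
         call = NULL, words = words))
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length; neither may be all zeros.
#' @return The cosine of the angle between `u` and `v`, in \[-1, 1\].
#' @export
#' @examples
#' cosine(c(1, 0), c(0, 1))  # 0
cosine <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must have equal length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine is undefined for the zero vector", call. = FALSE)
  s <- sum(u * v) / (nu * nv)
  # guard against tiny floating-point excursions outside [-1, 1]
  max(-1, min(1, s))
}

#' Read embeddings in word2vec text format
#'
#' The format is a header line `"<vocab_count> <dim>"` followed by one line
#' per word: the word then `dim` whitespace-separated floats.
#'
#' @param path Path to a word2vec text file (UTF-8, uncompressed).
#' @return An [embedding_table()].
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L)
    stop("empty embedding file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header))))
    stop("malformed word2vec header at line 1: ", lines[[1L]], call. = FALSE)
  n_words <- as.integer(header[[1L]])
  d <- as.integer(header[[2L]])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_words)
    stop(sprintf("header declares %d words but file has %d data lines",
                 n_words, length(body)), call. = FALSE)
  words <- character(n_words)
  mat <- matrix(NA_real_, nrow = n_words, ncol = d)
  for (i in seq_len(n_words)) {
    fields <- strsplit(trimws(body[[i]]), "\\s+")[[1L]]
    if (length(fields) != d + 1L)
      stop(sprintf("line %d: expected %d floats after the word, found %d",
                   i + 1L, d, length(fields) - 1L), call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric vector component", i + 1L),
           call. = FALSE)
    words[[i]] <- fields[[1L]]
    mat[i, ] <- vals
  }
  rownames(mat) <- words
  embedding_table(mat)
}

#' Write embeddings in word2vec text format
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly. A load/save/load cycle reproduces the table
#'   bit-identically (components are printed with 17 significant digits).
#' @export
save_embeddings <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table$vectors), table$dim), con)
  rows <- apply(table$vectors, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = " "))
  writeLines(paste(rownames(table$vectors), rows), con)
  invisible(path)
}

#' Generate a synthetic clustered semantic space
#'
#' Stands in for a corpus-trained embedding model in self-contained runs.
#' Words are organised into clusters around random unit-norm centres;
#' within-cluster pairs have high expected cosine and between-cluster pairs
#' have expected cosine near zero. Word names encode the cluster
#' (`"c3_w17"` is word 17 of cluster 3) so that stimuli with known
#' relatedness structure can be assembled by name.
#'
#' @param dim Vector dimensionality (default 100, matching the embedding
#'   dimensionality used throughout the package).
#' @param n_clusters Number of clusters.
#' @param words_per_cluster Words per cluster.
#' @param within_cluster_noise Standard deviation, per component, of the
#'   isotropic Gaussian perturbation added to the cluster centre before
#'   renormalisation. The expected within-cluster cosine is roughly
#'   `1 / (1 + noise^2 * dim)`; the default 0.1 gives about 0.5 at
#'   `dim = 100`.
#' @param seed Integer seed; the space is a pure function of its arguments.
#' @return An [embedding_table()] whose vectors are unit-norm, with an
#'   integer attribute `cluster` giving each word's cluster index.
#' @export
generate_synthetic_space <- function(dim = 100, n_clusters, words_per_cluster,
                                     within_cluster_noise = 0.1, seed) {
  stopifnot(dim >= 1, n_clusters >= 1, words_per_cluster >= 1,
            within_cluster_noise >= 0)
  n <- n_clusters * words_per_cluster
  local_seed(seed)
  centres <- matrix(stats::rnorm(n_clusters * dim), n_clusters, dim)
  centres <- centres / sqrt(rowSums(centres^2))
  cluster <- rep(seq_len(n_clusters), each = words_per_cluster)
  mat <- centres[cluster, , drop = FALSE] +
    within_cluster_noise * matrix(stats::rnorm(n * dim), n, dim)
  mat <- mat / sqrt(rowSums(mat^2))
  rownames(mat) <- sprintf("c%d_w%d", cluster,
                           rep(seq_len(words_per_cluster), n_clusters))
  tab <- embedding_table(mat)
  attr(tab, "cluster") <- stats::setNames(cluster, rownames(mat))
  tab
}

#' Cluster index of synthetic words
#'
#' Parses the `"c<k>_w<j>"` naming convention of
#' [generate_synthetic_space()].
#'
#' @param words Character vector of synthetic word names.
#' @return Integer vector of cluster indices.
#' @export
word_cluster <- function(words) {
  m <- regmatches(words, regexec("^c([0-9]+)_w[0-9]+$", words))
  out <- vapply(m, function(g) if (length(g) == 2L) as.integer(g[[2L]])
                else NA_integer_, integer(1))
  stats::setNames(out, words)
}

#' Construct a token stream
#'
#' A token stream is an ordered list of documents, each an ordered character
#' vector of word tokens. Document boundaries are explicit; reservoir
#' training resets its state at each boundary.
#'
#' @param documents List of non-empty character vectors.
#' @return An object of class `token_stream`.
#' @export
token_stream <- function(documents) {
  if (!is.list(documents) ||
      !all(vapply(documents, is.character, logical(1))))
    stop("`documents` must be a list of character vectors", call. = FALSE)
  if (any(lengths(documents) == 0L))
    stop("empty documents are not allowed in a token stream", call. = FALSE)
  structure(documents, class = "token_stream")
}

#' @export
print.token_stream <- function(x, ...) {
  cat(sprintf("<token_stream> %d documents, %d tokens\n",
              length(x), n_tokens(x)))
  invisible(x)
}

#' Total token count of a stream
#' @param stream A `token_stream`.
#' @export
n_tokens <- function(stream) sum(lengths(stream))

#' Generate a topic-coherent synthetic token stream
#'
#' Emulates a corpus of topically coherent articles: each document picks a
#' primary cluster of the synthetic space and draws most of its tokens from
#' that cluster, the rest uniformly from the whole vocabulary.
#'
#' @param table A synthetic [embedding_table()] with a `cluster` attribute.
#' @param n_docs Number of documents.
#' @param doc_len_range Length-2 integer vector `(min, max)` of document
#'   lengths, sampled uniformly.
#' @param topic_concentration Non-negative odds of drawing from the primary
#'   cluster: a token comes from the primary cluster with probability
#'   `topic_concentration / (1 + topic_concentration)`. The default 9 gives
#'   90% topical tokens; as it tends to infinity every token of a document
#'   comes from one cluster.
#' @param seed Integer seed.
#' @return A [token_stream()].
#' @export
generate_training_stream <- function(table, n_docs,
                                     doc_len_range = c(80L, 200L),
                                     topic_concentration = 9, seed) {
  stopifnot(inherits(table, "embedding_table"), n_docs >= 0,
            topic_concentration >= 0)
  cluster <- attr(table, "cluster")
  if (is.null(cluster))
    stop("`table` must carry a `cluster` attribute ",
         "(see generate_synthetic_space)", call. = FALSE)
  if (length(doc_len_range) != 2L || doc_len_range[[1L]] < 1L ||
      doc_len_range[[2L]] < doc_len_range[[1L]])
    stop("invalid `doc_len_range`", call. = FALSE)
  if (n_docs == 0L)
    return(token_stream(list()))
  local_seed(seed)
  vocab <- vocabulary(table)
  by_cluster <- split(vocab, cluster)
  p_topic <- if (is.infinite(topic_concentration)) 1 else
    topic_concentration / (1 + topic_concentration)
  docs <- vector("list", n_docs)
  lens <- sample.int(doc_len_range[[2L]] - doc_len_range[[1L]] + 1L,
                     n_docs, replace = TRUE) + doc_len_range[[1L]] - 1L
  for (i in seq_len(n_docs)) {
    topic <- sample.int(length(by_cluster), 1L)
    topical <- stats::runif(lens[[i]]) < p_topic
    toks <- character(lens[[i]])
    toks[topical] <- sample(by_cluster[[topic]], sum(topical),
                            replace = TRUE)
    toks[!topical] <- sample(vocab, sum(!topical), replace = TRUE)
    docs[[i]] <- toks
  }
  token_stream(docs)
}

# Seed an expression locally: sets the RNG deterministically for the caller
# and restores the caller's RNG state on exit, so seeded constructors do not
# perturb user-level random sequences.
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  do.call(on.exit, list(quote(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  )), envir = envir)
  assign("old", old, envir = envir)
  set.seed(seed)
  invisible(seed)
}
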