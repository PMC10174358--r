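# Text preprocessing and the two discourse aggregation strategies
# (bag-of-words average and discourse reservoir) behind one stateful
# aggregator interface.

# Frozen English function-word list (articles, auxiliaries, pronouns,
# prepositions, conjunctions, common adverbial particles). Runs record the
# md5 of the active list so results are traceable to the exact set.
.stopwords <- c(
  "a", "an", "the",
  "i", "me", "my", "mine", "myself", "we", "us", "our", "ours", "ourselves",
  "you", "your", "yours", "yourself", "yourselves",
  "he", "him", "his", "himself", "she", "her", "hers", "herself",
  "it", "its", "itself", "they", "them", "their", "theirs", "themselves",
  "this", "that", "these", "those", "who", "whom", "whose", "which", "what",
  "am", "is", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing",
  "will", "would", "shall", "should", "can", "could", "may", "might",
  "must", "ought",
  "and", "or", "but", "nor", "so", "yet", "if", "because", "although",
  "while", "when", "where", "why", "how", "than", "whether",
  "of", "in", "on", "at", "by", "for", "with", "about", "against",
  "between", "into", "through", "during", "before", "after", "above",
  "below", "to", "from", "up", "down", "out", "off", "over", "under",
  "again", "further", "then", "once", "here", "there", "all", "any",
  "both", "each", "few", "more", "most", "other", "some", "such",
  "no", "not", "only", "own", "same", "too", "very",
  "just", "also", "as", "like")

#' Default stop-word list
#'
#' A fixed English function-word list used by [preprocess()]. The list is
#' frozen in the package; [stopword_hash()] gives its md5 for run manifests.
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function() .stopwords

#' md5 hash of a stop-word list
#' @param stopwords Character vector (default the packaged list).
#' @return Length-1 character md5 digest of the sorted, newline-joined list.
#' @export
stopword_hash <- function(stopwords = default_stopwords()) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sort(stopwords), f)
  unname(tools::md5sum(f))
}

#' Preprocessing specification
#'
#' @param stopwords Words removed from the token sequence.
#' @param lowercase Lowercase the text first (default `TRUE`).
#' @param strip_punctuation Remove punctuation characters (default `TRUE`).
#' @param neutral_prime Optional word prepended to the token list, used to
#'   give the reservoir a semantically bland first input before the
#'   discourse proper begins. Must be present in the embedding table.
#' @param truncate_after_last Optional word; the token list is cut
#'   immediately after the final occurrence of this word.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(stopwords = default_stopwords(),
                            lowercase = TRUE, strip_punctuation = TRUE,
                            neutral_prime = NULL,
                            truncate_after_last = NULL) {
  structure(list(stopwords = tolower(stopwords),
                 lowercase = isTRUE(lowercase),
                 strip_punctuation = isTRUE(strip_punctuation),
                 neutral_prime = neutral_prime,
                 truncate_after_last = truncate_after_last),
            class = "preprocess_spec")
}

preprocess_error <- function(msg) {
  structure(class = c("preprocess_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Turn a text into a token sequence
#'
#' Applies, in order: lowercasing, punctuation stripping, tokenisation on
#' whitespace, stop-word removal, truncation after the last occurrence of
#' `truncate_after_last`, out-of-vocabulary filtering against `table`
#' (dropped tokens are counted and warned about, never silently lost), and
#' prepending of the neutral prime word.
#'
#' @param text A single character string.
#' @param spec A [preprocess_spec()].
#' @param table Optional [embedding_table()]; when supplied, tokens absent
#'   from it are dropped (with a warning) and the neutral prime is checked
#'   for membership.
#' @return Character vector of tokens, with an attribute `report`: a list
#'   with `n_raw`, `n_stopword`, `dropped_oov` (the dropped words) and
#'   `n_tokens`.
#' @export
preprocess <- function(text, spec = preprocess_spec(), table = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  x <- text
  if (spec$lowercase) x <- tolower(x)
  if (spec$strip_punctuation) x <- gsub("[^[:alnum:][:space:]'_]", " ", x)
  x <- gsub("'", "", x)
  toks <- strsplit(trimws(x), "\\s+")[[1L]]
  n_raw <- length(toks)
  toks <- toks[nzchar(toks)]
  keep <- !(toks %in% spec$stopwords)
  n_stop <- sum(!keep)
  toks <- toks[keep]
  if (!is.null(spec$truncate_after_last)) {
    anchor <- tolower(spec$truncate_after_last)
    hits <- which(toks == anchor)
    if (length(hits) == 0L)
      stop(preprocess_error(sprintf(
        "truncation word '%s' does not occur in the text", anchor)))
    toks <- toks[seq_len(max(hits))]
  }
  dropped <- character(0)
  if (!is.null(table)) {
    present <- toks %in% rownames(table$vectors)
    dropped <- unique(toks[!present])
    if (length(dropped) > 0)
      warning(sprintf("dropping %d out-of-vocabulary token(s): %s",
                      sum(!present), paste(dropped, collapse = ", ")),
              call. = FALSE)
    toks <- toks[present]
  }
  if (!is.null(spec$neutral_prime)) {
    prime <- tolower(spec$neutral_prime)
    if (!is.null(table) && !has_word(table, prime))
      stop(preprocess_error(sprintf(
        "neutral prime word '%s' is not in the embedding table", prime)))
    toks <- c(prime, toks)
  }
  if (length(toks) == 0L)
    stop(preprocess_error("no tokens remain after preprocessing"))
  structure(toks, report = list(n_raw = n_raw, n_stopword = n_stop,
                                dropped_oov = dropped,
                                n_tokens = length(toks)))
}

# ---------------------------------------------------------------------------
# Aggregators. Stateful objects built on environments: feed() mutates the
# state in place, current() reads out the present context vector, reset()
# restores the initial state.

new_aggregator <- function(kind, env) {
  structure(list(kind = kind, env = env),
            class = c(paste0(kind, "_aggregator"), "aggregator"))
}

#' @export
print.aggregator <- function(x, ...) {
  cat(sprintf("<%s aggregator> fed %d vector(s)\n", x$kind, fed_count(x)))
  invisible(x)
}

#' Bag-of-words average aggregator
#'
#' Maintains the arithmetic mean of all vectors fed so far: the simple but
#' effective order-blind discourse representation.
#'
#' @return An `aggregator` of kind `"average"`.
#' @seealso [reservoir_aggregator()], [agg_feed()], [agg_current()],
#'   [agg_reset()]
#' @export
average_aggregator <- function() {
  env <- new.env(parent = emptyenv())
  env$sum <- NULL
  env$n <- 0L
  new_aggregator("average", env)
}

#' Discourse reservoir aggregator
#'
#' Wraps a trained reservoir: each feed applies one leaky echo-state update,
#' and the current context vector is the ridge readout of the present state.
#'
#' @param model A trained `reservoir_model`.
#' @return An `aggregator` of kind `"reservoir"`.
#' @export
reservoir_aggregator <- function(model) {
  if (!is_trained(model))
    stop("reservoir aggregator requires a trained model", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$model <- model
  env$state <- reservoir_zero_state(model)
  env$last_u <- NULL
  env$n <- 0L
  new_aggregator("reservoir", env)
}

#' Feed one vector into an aggregator
#' @param agg An `aggregator`.
#' @param v Numeric vector (a word embedding).
#' @return `agg`, invisibly; the aggregator state is updated in place.
#' @export
agg_feed <- function(agg, v) UseMethod("agg_feed")

#' Current context vector of an aggregator
#' @param agg An `aggregator` that has been fed at least once.
#' @return Numeric context vector.
#' @export
agg_current <- function(agg) UseMethod("agg_current")

#' Reset an aggregator to its initial state
#' @param agg An `aggregator`.
#' @return `agg`, invisibly.
#' @export
agg_reset <- function(agg) UseMethod("agg_reset")

#' Number of vectors fed since the last reset
#' @param agg An `aggregator`.
#' @export
fed_count <- function(agg) agg$env$n

#' @export
agg_feed.average_aggregator <- function(agg, v) {
  e <- agg$env
  e$sum <- if (is.null(e$sum)) as.numeric(v) else e$sum + as.numeric(v)
  e$n <- e$n + 1L
  invisible(agg)
}

#' @export
agg_current.average_aggregator <- function(agg) {
  if (agg$env$n < 1L)
    stop("aggregator has not been fed yet", call. = FALSE)
  agg$env$sum / agg$env$n
}

#' @export
agg_reset.average_aggregator <- function(agg) {
  agg$env$sum <- NULL
  agg$env$n <- 0L
  invisible(agg)
}

#' @export
agg_feed.reservoir_aggregator <- function(agg, v) {
  e <- agg$env
  u <- as.numeric(v)
  if (e$model$config$normalize_inputs) u <- u / sqrt(sum(u^2))
  e$state <- reservoir_step(e$model, e$state, u)
  e$last_u <- u
  e$n <- e$n + 1L
  invisible(agg)
}

#' @export
agg_current.reservoir_aggregator <- function(agg) {
  if (agg$env$n < 1L)
    stop("aggregator has not been fed yet", call. = FALSE)
  reservoir_output(agg$env$model, agg$env$state, agg$env$last_u)
}

#' @export
agg_reset.reservoir_aggregator <- function(agg) {
  agg$env$state <- reservoir_zero_state(agg$env$model)
  agg$env$last_u <- NULL
  agg$env$n <- 0L
  invisible(agg)
}

#' Context-vector trajectory over a token sequence
#'
#' Resets the aggregator, then feeds the tokens' embeddings in order,
#' recording the context vector after every token.
#'
#' @param agg An `aggregator`.
#' @param tokens Character vector of tokens, all present in `table`.
#' @param table An [embedding_table()].
#' @return Numeric matrix, one row per token, `table$dim` columns.
#' @export
trajectory <- function(agg, tokens, table) {
  stopifnot(length(tokens) >= 1L)
  agg_reset(agg)
  out <- matrix(NA_real_, length(tokens), table$dim)
  for (k in seq_along(tokens)) {
    agg_feed(agg, embedding(table, tokens[[k]]))
    out[k, ] <- agg_current(agg)
  }
  rownames(out) <- tokens
  out
}
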