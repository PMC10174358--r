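# The linking hypothesis: predicted N400 amplitude is one minus the cosine
# similarity between the current discourse context vector and the incoming
# target word's embedding.

#' Predicted N400 amplitude for a context/target pair
#'
#' Returns `1 - cosine(context, target)`: 0 for an identical direction,
#' 1 for orthogonal vectors, 2 for antiparallel ones. Values are reported
#' raw — no clamping or standardisation — as the proxy for N400 amplitude.
#'
#' @param context Context vector (a single word's embedding or a discourse
#'   aggregate).
#' @param target Target word's embedding.
#' @return Real value in \[0, 2\].
#' @export
#' @examples
#' predict_n400(c(1, 0), c(1, 0))   # 0
#' predict_n400(c(1, 0), c(0, 1))   # 1
predict_n400 <- function(context, target) {
  1 - cosine(context, target)
}

#' Construct an N400 results table
#'
#' Long-format records consumed by the statistics module: one row per
#' (subject, item, condition) measurement.
#'
#' @param subject,item,condition,target Character vectors (recycled to a
#'   common length).
#' @param position Integer within-discourse position of the measurement
#'   (NA where not applicable).
#' @param value Numeric predicted N400 values.
#' @return A data frame of class `n400_table` with columns `subject`,
#'   `item`, `condition`, `position`, `target`, `value`.
#' @export
n400_table <- function(subject, item, condition, position = NA_integer_,
                       target, value) {
  df <- data.frame(subject = as.character(subject),
                   item = as.character(item),
                   condition = as.character(condition),
                   position = as.integer(position),
                   target = as.character(target),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  class(df) <- c("n400_table", "data.frame")
  df
}

#' Write / read an N400 table as TSV
#'
#' @param x An `n400_table`.
#' @param path File path (tab-separated, header row).
#' @return `write_n400_table` returns `path` invisibly; `read_n400_table`
#'   returns the `n400_table`.
#' @export
write_n400_table <- function(x, path) {
  stopifnot(inherits(x, "n400_table"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_n400_table
#' @export
read_n400_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  n400_table(df$subject, df$item, df$condition, df$position, df$target,
             df$value)
}

#' Predicted N400 for word pairs (semantic priming design)
#'
#' The context is the first word of each pair (the prime), the target the
#' second; the predicted N400 is `1 - cosine` of their embeddings. Pairs
#' with an out-of-vocabulary member are excluded and reported.
#'
#' @param table An [embedding_table()].
#' @param pairs Data frame with columns `word1`, `word2`, `condition`.
#' @param subject Subject label recorded in the result (default `"pairs"`;
#'   the design has no model subjects).
#' @return An [n400_table()] with one row per retained pair; the attribute
#'   `excluded` lists dropped pair indices.
#' @export
pairwise_priming_n400 <- function(table, pairs, subject = "pairs") {
  stopifnot(is.data.frame(pairs),
            all(c("word1", "word2", "condition") %in% names(pairs)))
  w1 <- tolower(pairs$word1); w2 <- tolower(pairs$word2)
  ok <- w1 %in% rownames(table$vectors) & w2 %in% rownames(table$vectors)
  if (!all(ok))
    warning(sprintf("excluding %d pair(s) with out-of-vocabulary words",
                    sum(!ok)), call. = FALSE)
  if (!any(ok))
    stop("no pairs retained: all contain out-of-vocabulary words",
         call. = FALSE)
  idx <- which(ok)
  vals <- vapply(idx, function(i)
    predict_n400(embedding(table, w1[[i]]), embedding(table, w2[[i]])),
    numeric(1))
  out <- n400_table(subject = subject,
                    item = sprintf("pair%03d", idx),
                    condition = pairs$condition[idx],
                    position = NA_integer_,
                    target = w2[idx],
                    value = vals)
  attr(out, "excluded") <- which(!ok)
  out
}

#' Per-target N400 trajectory over a discourse
#'
#' Feeds `tokens` through the aggregator and, after every token, computes
#' the predicted N400 between the current context vector and each target
#' word.
#'
#' @param agg An `aggregator`.
#' @param tokens Character vector of discourse tokens (all in `table`).
#' @param targets Character vector of target words (all in `table`).
#' @param table An [embedding_table()].
#' @return Numeric matrix: one row per token position, one column per
#'   target.
#' @export
discourse_target_n400 <- function(agg, tokens, targets, table) {
  targets <- tolower(targets)
  tvecs <- lapply(targets, function(w) embedding(table, w))
  traj <- trajectory(agg, tokens, table)
  out <- matrix(NA_real_, nrow(traj), length(targets),
                dimnames = list(NULL, targets))
  for (j in seq_along(targets))
    out[, j] <- unname(apply(traj, 1L, predict_n400, target = tvecs[[j]]))
  out
}
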