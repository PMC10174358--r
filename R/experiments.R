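# End-to-end simulation harnesses: semantic priming over word pairs,
# discourse overrule over a single discourse, and event-knowledge rescue
# over three-completion scenarios, each analysed over a pool of reservoir
# "subjects".

#' Train a pool of reservoir subjects
#'
#' Each seed yields an independently initialised reservoir trained on the
#' same stream — the model analogue of different subjects in a human
#' experiment. Subject seeds seed nothing else: the space, stream and
#' stimuli carry their own seeds, so between-subject variability isolates
#' reservoir initialisation.
#'
#' @param table An [embedding_table()].
#' @param stream Shared training [token_stream()].
#' @param config Shared [reservoir_config()]; its `seed` field is replaced
#'   by each subject seed in turn.
#' @param seeds Distinct integer seeds, one per subject (default 0..49).
#' @return Named list of trained `reservoir_model`s (`"s00"`, `"s01"`, ...).
#' @export
train_subject_pool <- function(table, stream, config = reservoir_config(),
                               seeds = 0:49) {
  stopifnot(!anyDuplicated(seeds))
  models <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    train_discourse_reservoir(table, stream, cfg)
  })
  names(models) <- sprintf("s%02d", seq_along(seeds) - 1L)
  models
}

new_experiment_result <- function(kind, n400, condition_means, stats,
                                  ...) {
  # invariant: reported condition means are recomputable from the raw table
  recomputed <- tapply(n400$value, n400$condition, mean)
  stopifnot(all(abs(recomputed[names(condition_means)] -
                      condition_means) < 1e-12))
  structure(c(list(kind = kind, n400_table = n400,
                   condition_means = condition_means, stats = stats),
              list(...)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s>\n", x$kind))
  cat("condition means:\n")
  for (nm in names(x$condition_means))
    cat(sprintf("  %-24s %.4f\n", nm, x$condition_means[[nm]]))
  if (!is.null(x$stats$t)) print(x$stats$t)
  if (!is.null(x$stats$anova)) print(x$stats$anova)
  invisible(x)
}

#' Semantic priming simulation over word pairs
#'
#' Predicts the N400 for each (prime, target) pair as `1 - cosine` of their
#' embeddings and compares the related and unrelated conditions. With
#' matched condition sizes the comparison is a paired t across pair index;
#' otherwise a Welch two-sample t.
#'
#' @param table An [embedding_table()].
#' @param pairs Data frame with columns `word1`, `word2`, `condition`
#'   (exactly two condition labels).
#' @param paired `NULL` (auto: paired iff condition counts match), `TRUE`
#'   (error if counts differ) or `FALSE`.
#' @return An `experiment_result` with the raw [n400_table()], condition
#'   means, five-number box summaries per condition, and the t test.
#' @export
run_priming <- function(table, pairs, paired = NULL) {
  n400 <- pairwise_priming_n400(table, pairs)
  conds <- unique(n400$condition)
  if (length(conds) != 2L)
    stop("priming expects exactly two conditions, got: ",
         paste(conds, collapse = ", "), call. = FALSE)
  vals <- split(n400$value, factor(n400$condition, levels = conds))
  if (any(lengths(vals) < 2L))
    stop("need at least two retained pairs per condition", call. = FALSE)
  matched <- length(vals[[1L]]) == length(vals[[2L]])
  if (isTRUE(paired) && !matched)
    stop("paired test requested but condition counts differ",
         call. = FALSE)
  use_paired <- if (is.null(paired)) matched else isTRUE(paired)
  tt <- if (use_paired) paired_t(vals[[1L]], vals[[2L]])
  else stats::t.test(vals[[1L]], vals[[2L]])
  box <- lapply(vals, function(v)
    stats::setNames(stats::fivenum(v),
                    c("min", "q1", "median", "q3", "max")))
  new_experiment_result("priming", n400,
                        condition_means = vapply(vals, mean, numeric(1)),
                        stats = list(t = tt, paired = use_paired),
                        box_summary = box)
}

#' Generate matched related/unrelated word pairs from a synthetic space
#'
#' Related pairs are two distinct words from one cluster; unrelated pairs
#' take their words from two different clusters. The achieved construction
#' gap (mean within-pair cosine minus mean between-pair cosine) is recorded
#' as an attribute.
#'
#' @param space Synthetic [embedding_table()] with cluster-labelled words.
#' @param n_pairs Pairs per condition (default 40, matching the classic
#'   priming list size).
#' @param seed Integer seed.
#' @return Data frame `word1`, `word2`, `condition` with `2 * n_pairs`
#'   rows and attribute `construction_gap`.
#' @export
generate_priming_pairs <- function(space, n_pairs = 40L, seed) {
  cluster <- attr(space, "cluster")
  if (is.null(cluster)) stop("space must have cluster-labelled words",
                             call. = FALSE)
  by_cluster <- split(vocabulary(space), cluster)
  if (length(by_cluster) < 2L) stop("need at least two clusters",
                                    call. = FALSE)
  local_seed(seed)
  rel <- t(vapply(seq_len(n_pairs), function(i) {
    cl <- sample(names(by_cluster), 1L)
    sample(by_cluster[[cl]], 2L)
  }, character(2)))
  unrel <- t(vapply(seq_len(n_pairs), function(i) {
    cls <- sample(names(by_cluster), 2L)
    c(sample(by_cluster[[cls[[1L]]]], 1L),
      sample(by_cluster[[cls[[2L]]]], 1L))
  }, character(2)))
  pairs <- data.frame(word1 = c(rel[, 1L], unrel[, 1L]),
                      word2 = c(rel[, 2L], unrel[, 2L]),
                      condition = rep(c("related", "unrelated"),
                                      each = n_pairs),
                      stringsAsFactors = FALSE)
  coss <- vapply(seq_len(nrow(pairs)), function(i)
    cosine(embedding(space, pairs$word1[[i]]),
           embedding(space, pairs$word2[[i]])), numeric(1))
  attr(pairs, "construction_gap") <-
    mean(coss[seq_len(n_pairs)]) - mean(coss[-seq_len(n_pairs)])
  pairs
}

#' Generate a synthetic discourse-overrule fixture
#'
#' Builds the synthetic analogue of the "peanut in love" discourse: the
#' token sequence begins and ends with a critical word from one cluster,
#' while the intervening discourse is drawn from a second cluster. The
#' local target (a near neighbour of the critical word) starts with the
#' lower predicted N400; the discourse-aligned target (from the discourse
#' cluster) ends with the lower one.
#'
#' @param space Synthetic [embedding_table()] with cluster labels.
#' @param n_middle Number of discourse tokens between the two occurrences
#'   of the critical word (default 40, roughly the length of the
#'   preprocessed classic discourse).
#' @param seed Integer seed.
#' @return List with `tokens`, `local_target`, `discourse_target`,
#'   `critical_word`.
#' @export
generate_overrule_discourse <- function(space, n_middle = 40L, seed) {
  cluster <- attr(space, "cluster")
  if (is.null(cluster)) stop("space must have cluster-labelled words",
                             call. = FALSE)
  by_cluster <- split(vocabulary(space), cluster)
  if (length(by_cluster) < 2L || any(lengths(by_cluster) < 2L))
    stop("need >= 2 clusters with >= 2 words each", call. = FALSE)
  local_seed(seed)
  cls <- sample(names(by_cluster), 2L)
  critical_pair <- sample(by_cluster[[cls[[1L]]]], 2L)
  critical <- critical_pair[[1L]]
  local_target <- critical_pair[[2L]]
  middle_pool <- setdiff(by_cluster[[cls[[2L]]]], character(0))
  discourse_target <- sample(middle_pool, 1L)
  middle <- sample(setdiff(middle_pool, discourse_target), n_middle,
                   replace = n_middle > length(middle_pool) - 1L)
  list(tokens = c(critical, middle, critical),
       local_target = local_target,
       discourse_target = discourse_target,
       critical_word = critical)
}

#' Discourse-overrule simulation ("peanut in love" design)
#'
#' For each reservoir subject, feeds the discourse tokens through a
#' reservoir aggregator and records the predicted N400 against the local
#' and discourse-aligned targets at the first token (Beginning: the
#' critical word alone) and the last token (End: after the discourse). A
#' 2 x 2 repeated-measures ANOVA with factors phase (Beginning, End) and
#' target tests the overrule interaction; the per-subject reversal
#' indicator is `TRUE` when the discourse-aligned target's N400 exceeds
#' the local target's at the Beginning and falls below it at the End.
#'
#' @param table An [embedding_table()].
#' @param tokens Preprocessed discourse token vector (first and last token
#'   should be the critical word).
#' @param targets Length-2 character vector `c(local, discourse_aligned)`.
#' @param models Named list of trained reservoirs (see
#'   [train_subject_pool()]); pass a single-element list for a
#'   single-subject run.
#' @return An `experiment_result` with per-subject trajectories summarised
#'   at Beginning/End, the 2 x 2 ANOVA (when >= 2 subjects), reversal
#'   indicators and reversal rate.
#' @export
run_peanut <- function(table, tokens, targets, models) {
  stopifnot(length(targets) == 2L, length(models) >= 1L)
  targets <- tolower(targets)
  local_t <- targets[[1L]]; aligned_t <- targets[[2L]]
  rows <- list()
  reversal <- logical(length(models))
  for (i in seq_along(models)) {
    agg <- reservoir_aggregator(models[[i]])
    vals <- discourse_target_n400(agg, tokens, targets, table)
    b <- vals[1L, ]; e <- vals[nrow(vals), ]
    reversal[[i]] <- (b[[aligned_t]] > b[[local_t]]) &&
      (e[[aligned_t]] < e[[local_t]])
    rows[[i]] <- data.frame(
      subject = names(models)[[i]],
      phase = rep(c("Beginning", "End"), each = 2L),
      target = rep(targets, 2L),
      value = c(b[targets], e[targets]),
      stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  anova <- if (length(models) >= 2L)
    rm_anova(data, within = c("phase", "target")) else NULL
  n400 <- n400_table(subject = data$subject, item = "discourse",
                     condition = paste(data$phase, data$target, sep = ":"),
                     position = NA_integer_, target = data$target,
                     value = data$value)
  new_experiment_result(
    "peanut", n400,
    condition_means = tapply(n400$value, n400$condition, mean)[
      unique(n400$condition)],
    stats = list(anova = anova),
    data = data, reversal = stats::setNames(reversal, names(models)),
    reversal_rate = mean(reversal), targets = targets)
}

# ---------------------------------------------------------------------------
# Scenarios (three-completion event-knowledge design)

#' Construct a scenario
#'
#' A scenario is a short discourse: one or more context sentences, a final
#' sentence stem, and three completion targets — Expected,
#' Unexpected-Related (related to the described event but not the local
#' sentence) and Unexpected-Unrelated.
#'
#' @param item_id Identifier string.
#' @param context Character vector of context sentences.
#' @param stem Final sentence up to (excluding) the target word.
#' @param expected,related,unrelated The three target words (distinct; none
#'   may occur in the stem).
#' @return Object of class `scenario`.
#' @export
scenario <- function(item_id, context, stem, expected, related, unrelated) {
  targets <- tolower(c(expected, related, unrelated))
  if (anyDuplicated(targets))
    stop("scenario targets must be distinct", call. = FALSE)
  stem_words <- strsplit(tolower(stem), "\\s+")[[1L]]
  if (any(targets %in% stem_words))
    stop("the sentence stem may not contain a target word", call. = FALSE)
  structure(list(item_id = as.character(item_id),
                 context = as.character(context), stem = as.character(stem),
                 expected = targets[[1L]], related = targets[[2L]],
                 unrelated = targets[[3L]]),
            class = "scenario")
}

#' Read / write scenario corpora as JSON
#'
#' One JSON array per corpus; each element has keys `item_id`, `context`
#' (array of sentences), `sentence_stem`, `expected`, `related`,
#' `unrelated`.
#'
#' @param scenarios List of [scenario()] objects.
#' @param path JSON file path.
#' @export
write_scenarios <- function(scenarios, path) {
  payload <- lapply(scenarios, function(s)
    list(item_id = s$item_id, context = as.list(s$context),
         sentence_stem = s$stem, expected = s$expected,
         related = s$related, unrelated = s$unrelated))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(s)
    scenario(s$item_id, unlist(s$context), s$sentence_stem, s$expected,
             s$related, s$unrelated))
}

#' Generate a synthetic scenario corpus
#'
#' Each item picks three distinct clusters: an event cluster supplying the
#' context sentences, a neutral cluster supplying the sentence stem, and a
#' distant cluster. The Expected target is synthesised very near the
#' context-plus-stem mixture, the Unexpected-Related target near the event
#' cluster's centre (related to the event but absent from the stem's
#' neighbourhood), and the Unexpected-Unrelated target near the distant
#' cluster's centre. Target vectors are added to the returned space under
#' the item's name.
#'
#' @param space Synthetic [embedding_table()] with cluster labels.
#' @param n_items Number of scenarios.
#' @param seed Integer seed.
#' @param context_len,stem_len Tokens in the context sentences and the stem.
#' @param target_noise Per-component sd of the perturbation applied to each
#'   synthesised target before renormalisation.
#' @return List with `scenarios` (list of [scenario()]) and `table` (the
#'   input space augmented with the 3 x n_items target vectors). The
#'   attribute `margins` on `scenarios` records, per item, the construction
#'   margin `cos(context_mean, related) - cos(context_mean, unrelated)`.
#' @export
generate_synthetic_scenarios <- function(space, n_items, seed,
                                         context_len = 12L, stem_len = 6L,
                                         target_noise = 0.05) {
  stopifnot(n_items >= 1L)
  cluster <- attr(space, "cluster")
  if (is.null(cluster)) stop("space must have cluster-labelled words",
                             call. = FALSE)
  by_cluster <- split(vocabulary(space), cluster)
  if (length(by_cluster) < 3L)
    stop("need at least three clusters", call. = FALSE)
  local_seed(seed)
  d <- space$dim
  scen <- vector("list", n_items)
  margins <- numeric(n_items)
  extra <- matrix(NA_real_, 3L * n_items, d)
  extra_names <- character(3L * n_items)
  for (i in seq_len(n_items)) {
    cls <- sample(names(by_cluster), 3L)  # event, neutral, distant
    ev <- sample(by_cluster[[cls[[1L]]]], context_len,
                 replace = context_len > length(by_cluster[[cls[[1L]]]]))
    st <- sample(by_cluster[[cls[[2L]]]], stem_len,
                 replace = stem_len > length(by_cluster[[cls[[2L]]]]))
    half <- ceiling(context_len / 2)
    context <- c(paste(ev[seq_len(half)], collapse = " "),
                 paste(ev[-seq_len(half)], collapse = " "))
    context <- context[nzchar(context)]
    all_vecs <- space$vectors[c(ev, st), , drop = FALSE]
    mixture <- colMeans(all_vecs)
    ev_centre <- colMeans(space$vectors[by_cluster[[cls[[1L]]]], ,
                                        drop = FALSE])
    un_centre <- colMeans(space$vectors[by_cluster[[cls[[3L]]]], ,
                                        drop = FALSE])
    synth <- function(v) {
      v <- v + target_noise * stats::rnorm(d)
      v / sqrt(sum(v^2))
    }
    ids <- sprintf("s%03d_%s", i, c("expected", "related", "unrelated"))
    rows <- 3L * (i - 1L) + 1:3
    extra[rows, ] <- rbind(synth(mixture), synth(ev_centre),
                           synth(un_centre))
    extra_names[rows] <- ids
    ctx_mean <- colMeans(space$vectors[ev, , drop = FALSE])
    margins[[i]] <- cosine(ctx_mean, extra[rows[[2L]], ]) -
      cosine(ctx_mean, extra[rows[[3L]], ])
    scen[[i]] <- scenario(sprintf("item%03d", i), context,
                          paste(st, collapse = " "),
                          ids[[1L]], ids[[2L]], ids[[3L]])
  }
  rownames(extra) <- extra_names
  aug <- embedding_table(rbind(space$vectors, extra))
  attr(aug, "cluster") <- c(attr(space, "cluster"),
                            stats::setNames(rep(NA_integer_,
                                                nrow(extra)), extra_names))
  attr(scen, "margins") <- margins
  list(scenarios = scen, table = aug)
}

#' Event-knowledge rescue simulation over a scenario corpus
#'
#' For each scenario, subject and context mode, aggregates the input
#' tokens — the sentence stem alone (`"sentence"` mode) or the context
#' sentences followed by the stem (`"discourse"` mode) — and records the
#' predicted N400 of the aggregate at the stem's end against each of the
#' three targets. Per-subject condition means (over items) feed a 2 x 3
#' repeated-measures ANOVA with factors context and relatedness, pairwise
#' post-hoc contrasts within each context mode, and the "rescue
#' difference" statistic: per-subject Unrelated minus Related, compared
#' between discourse and sentence modes by paired t.
#'
#' @param table An [embedding_table()] containing every scenario token and
#'   target (for synthetic corpora, the augmented table returned by
#'   [generate_synthetic_scenarios()]).
#' @param scenarios List of [scenario()] objects. Scenarios with
#'   out-of-vocabulary targets are dropped with a warning.
#' @param models Named list of trained reservoirs, or `NULL` to use the
#'   bag-of-words average aggregator as a single deterministic subject.
#' @param modes Context modes to run (default both).
#' @param prep A [preprocess_spec()] applied to context sentences and stem
#'   (default: no stop-word removal, as synthetic tokens have no function
#'   words; pass a custom spec for natural-language corpora).
#' @return An `experiment_result`; `stats` holds the ANOVA, post-hocs and
#'   rescue paired t (ANOVA and t require >= 2 subjects and both modes),
#'   `cell` the per-subject cell means, `rescue` the per-subject rescue
#'   differences by mode.
#' @export
run_scenarios <- function(table, scenarios, models = NULL,
                          modes = c("sentence", "discourse"),
                          prep = preprocess_spec(stopwords = character(0))) {
  stopifnot(length(modes) >= 1L,
            all(modes %in% c("sentence", "discourse")))
  keep <- vapply(scenarios, function(s)
    all(vapply(c(s$expected, s$related, s$unrelated), has_word,
               logical(1), table = table)), logical(1))
  if (!all(keep))
    warning(sprintf("dropping %d scenario(s) with out-of-vocabulary targets",
                    sum(!keep)), call. = FALSE)
  scenarios <- scenarios[keep]
  if (length(scenarios) == 0L)
    stop("no scenarios retained", call. = FALSE)
  aggs <- if (is.null(models))
    list(average = average_aggregator())
  else lapply(models, reservoir_aggregator)
  conds <- c(expected = "Expected", related = "Unexpected-Related",
             unrelated = "Unexpected-Unrelated")
  rows <- list()
  for (s in scenarios) {
    toks <- list()
    if ("sentence" %in% modes)
      toks$sentence <- preprocess(s$stem, prep, table)
    if ("discourse" %in% modes)
      toks$discourse <- preprocess(paste(c(s$context, s$stem),
                                         collapse = " "), prep, table)
    tvec <- lapply(c(s$expected, s$related, s$unrelated),
                   function(w) embedding(table, w))
    for (subj in names(aggs)) {
      for (mode in names(toks)) {
        ctx <- {
          traj <- trajectory(aggs[[subj]], toks[[mode]], table)
          traj[nrow(traj), ]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, item = s$item_id, context = mode,
          relatedness = unname(conds),
          target = c(s$expected, s$related, s$unrelated),
          value = vapply(tvec, function(v) predict_n400(ctx, v),
                         numeric(1)),
          stringsAsFactors = FALSE)
      }
    }
  }
  data <- do.call(rbind, rows)
  # per-subject cell means over items
  cell <- stats::aggregate(value ~ subject + context + relatedness,
                           data = data, FUN = mean)
  n_subj <- length(aggs)
  anova <- posthoc <- rescue_t <- NULL
  rescue <- NULL
  if (length(modes) == 2L) {
    wide <- stats::reshape(
      cell[cell$relatedness != "Expected", ],
      idvar = c("subject", "context"), timevar = "relatedness",
      direction = "wide")
    rescue <- data.frame(
      subject = wide$subject, context = wide$context,
      difference = wide$`value.Unexpected-Unrelated` -
        wide$`value.Unexpected-Related`,
      stringsAsFactors = FALSE)
    if (n_subj >= 2L) {
      anova <- rm_anova(cell, within = c("context", "relatedness"))
      posthoc <- posthoc_pairwise(cell, within = "relatedness",
                                  by = "context")
      rs <- split(rescue$difference, rescue$context)
      rescue_t <- paired_t(rs$discourse, rs$sentence)
    }
  } else if (n_subj >= 2L) {
    posthoc <- posthoc_pairwise(cell, within = "relatedness")
  }
  n400 <- n400_table(subject = data$subject, item = data$item,
                     condition = paste(data$context, data$relatedness,
                                       sep = ":"),
                     position = NA_integer_, target = data$target,
                     value = data$value)
  cm <- tapply(n400$value, n400$condition, mean)
  new_experiment_result(
    "scenarios", n400, condition_means = cm[sort(names(cm))],
    stats = list(anova = anova, posthoc = posthoc, rescue_t = rescue_t),
    cell = cell, rescue = rescue, n_scenarios = length(scenarios),
    n_subjects = n_subj)
}

#' Write the inferential statistics of an experiment result as TSV
#'
#' Serialises ANOVA effects and/or t tests with columns
#' `effect`, `F`, `df1`, `df2`, `p` (t tests are reported as `F = t^2`
#' with `df1 = 1`).
#'
#' @param result An `experiment_result`.
#' @param path Output TSV path.
#' @export
write_stats_tsv <- function(result, path) {
  rows <- list()
  st <- result$stats
  if (!is.null(st$anova))
    rows[[length(rows) + 1L]] <-
      st$anova$table[, c("effect", "F", "df1", "df2", "p")]
  add_t <- function(tt, label) {
    if (is.null(tt) || inherits(tt, "htest")) {
      if (inherits(tt, "htest"))
        data.frame(effect = label, F = unname(tt$statistic)^2, df1 = 1,
                   df2 = unname(tt$parameter), p = tt$p.value)
    } else {
      data.frame(effect = label, F = tt$t^2, df1 = 1, df2 = tt$df,
                 p = tt$p)
    }
  }
  if (!is.null(st$t))
    rows[[length(rows) + 1L]] <- add_t(st$t, "condition")
  if (!is.null(st$rescue_t))
    rows[[length(rows) + 1L]] <- add_t(st$rescue_t, "rescue difference")
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
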