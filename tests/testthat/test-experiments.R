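test_that("priming pairs are matched and carry their construction gap", {
  space <- fx_small_space()
  pairs <- generate_priming_pairs(space, n_pairs = 20, seed = 51)
  expect_equal(as.vector(table(pairs$condition)), c(20L, 20L))
  expect_gt(attr(pairs, "construction_gap"), 0)
  pairs2 <- generate_priming_pairs(space, n_pairs = 20, seed = 51)
  expect_identical(pairs, pairs2)
})

test_that("the priming simulation separates related from unrelated pairs", {
  space <- fx_small_space()
  pairs <- generate_priming_pairs(space, n_pairs = 20, seed = 52)
  res <- run_priming(space, pairs)
  expect_s3_class(res$n400_table, "n400_table")
  expect_lt(res$condition_means[["related"]],
            res$condition_means[["unrelated"]])
  expect_true(res$stats$paired)
  expect_lt(res$stats$t$p, 0.01)
  # reported means are recomputable from the raw table (checked again here)
  expect_equal(res$condition_means[["related"]],
               mean(res$n400_table$value[
                 res$n400_table$condition == "related"]),
               tolerance = 1e-14)
  # box summaries span the data
  expect_equal(res$box_summary$related[["median"]],
               median(res$n400_table$value[
                 res$n400_table$condition == "related"]))

  # degenerate: identical words in every pair
  w <- vocabulary(space)[1:4]
  same <- data.frame(word1 = w, word2 = w,
                     condition = rep(c("related", "unrelated"), 2))
  deg <- run_priming(space, same)
  expect_equal(unname(deg$condition_means), c(0, 0), tolerance = 1e-12)
  expect_true(deg$stats$t$degenerate)

  # unmatched counts with paired requested is a contract error
  unm <- pairs[-1L, ]
  expect_error(run_priming(space, unm, paired = TRUE), "counts differ")
})

test_that("the overrule fixture reverses the target ordering across subjects", {
  space <- fx_small_space()
  stream <- generate_training_stream(space, n_docs = 40,
                                     doc_len_range = c(10L, 40L),
                                     seed = 53)
  models <- train_subject_pool(space, stream,
                               reservoir_config(n_units = 40L),
                               seeds = 0:7)
  fix <- generate_overrule_discourse(space, n_middle = 20, seed = 54)
  res <- run_peanut(space, fix$tokens,
                    c(fix$local_target, fix$discourse_target), models)
  expect_gte(res$reversal_rate, 0.75)
  inter <- res$stats$anova$table
  expect_lt(inter$p[inter$effect == "phase:target"], 0.01)
  expect_equal(res$stats$anova$n_subjects, 8L)

  # single-token "discourse": beginning and end coincide, interaction nil
  one <- run_peanut(space, fix$tokens[1L],
                    c(fix$local_target, fix$discourse_target), models)
  b <- one$data$value[one$data$phase == "Beginning"]
  e <- one$data$value[one$data$phase == "End"]
  expect_equal(b, e, tolerance = 1e-14)
  itab <- one$stats$anova$table
  expect_equal(itab$SS[itab$effect == "phase:target"], 0,
               tolerance = 1e-12)
})

test_that("synthetic scenario corpora have the advertised structure", {
  space <- fx_small_space()
  gen <- generate_synthetic_scenarios(space, n_items = 6, seed = 55)
  gen2 <- generate_synthetic_scenarios(space, n_items = 6, seed = 55)
  expect_identical(gen$table$vectors, gen2$table$vectors)
  expect_length(gen$scenarios, 6L)

  targets <- unlist(lapply(gen$scenarios, function(s)
    c(s$expected, s$related, s$unrelated)))
  expect_equal(length(unique(targets)), 18L)

  # construction margin, checked by brute force per item: the related
  # target is nearer the context mean than the unrelated one
  for (s in gen$scenarios) {
    ctx_tokens <- unlist(strsplit(paste(s$context, collapse = " "), " "))
    ctx_mean <- colMeans(gen$table$vectors[ctx_tokens, , drop = FALSE])
    expect_gt(cosine(ctx_mean, embedding(gen$table, s$related)),
              cosine(ctx_mean, embedding(gen$table, s$unrelated)))
  }
  expect_true(all(attr(gen$scenarios, "margins") > 0))

  expect_error(scenario("x", "a b", "c d", "t1", "t1", "t2"), "distinct")
  expect_error(scenario("x", "a b", "c t1", "t1", "t2", "t3"),
               "may not contain")
})

test_that("scenario corpora round-trip through JSON", {
  gen <- generate_synthetic_scenarios(fx_small_space(), n_items = 4,
                                      seed = 56)
  f <- withr::local_tempfile(fileext = ".json")
  write_scenarios(gen$scenarios, f)
  back <- read_scenarios(f)
  expect_equal(back, lapply(gen$scenarios, identity))
})

test_that("discourse context rescues the related target in scenarios", {
  space <- fx_small_space()
  stream <- generate_training_stream(space, n_docs = 40,
                                     doc_len_range = c(10L, 40L),
                                     seed = 57)
  models <- train_subject_pool(space, stream,
                               reservoir_config(n_units = 40L),
                               seeds = 0:3)
  gen <- generate_synthetic_scenarios(space, n_items = 8, seed = 58)
  res <- run_scenarios(gen$table, gen$scenarios, models)
  cm <- res$condition_means
  # expected is lowest in both context modes; related is rescued only
  # with the discourse present
  expect_lt(cm[["sentence:Expected"]], cm[["sentence:Unexpected-Related"]])
  expect_lt(cm[["discourse:Expected"]],
            cm[["discourse:Unexpected-Related"]])
  expect_lt(cm[["discourse:Unexpected-Related"]],
            cm[["discourse:Unexpected-Unrelated"]])
  rescue <- tapply(res$rescue$difference, res$rescue$context, mean)
  expect_gt(rescue[["discourse"]], rescue[["sentence"]])
  expect_s3_class(res$stats$anova, "rm_anova")
  expect_equal(nrow(res$stats$posthoc), 6L)

  # the average aggregator is a single deterministic subject
  avg <- run_scenarios(gen$table, gen$scenarios, models = NULL)
  expect_equal(avg$n_subjects, 1L)
  expect_null(avg$stats$anova)
  expect_lt(avg$condition_means[["discourse:Unexpected-Related"]],
            avg$condition_means[["discourse:Unexpected-Unrelated"]])

  # empty context: the two modes coincide
  s0 <- scenario("empty", character(0),
                 paste(vocabulary(space)[1:4], collapse = " "),
                 gen$scenarios[[1L]]$expected,
                 gen$scenarios[[1L]]$related,
                 gen$scenarios[[1L]]$unrelated)
  r0 <- run_scenarios(gen$table, list(s0), models = NULL)
  v <- r0$n400_table
  sent <- v$value[startsWith(v$condition, "sentence")]
  disc <- v$value[startsWith(v$condition, "discourse")]
  expect_equal(sent, disc, tolerance = 1e-14)

  # scenarios with OOV targets are dropped, empty corpus errors
  s_bad <- scenario("bad", "a", "b", "absent1", "absent2", "absent3")
  expect_warning(r1 <- run_scenarios(gen$table,
                                     c(gen$scenarios[1:2], list(s_bad)),
                                     models = NULL), "dropping 1")
  expect_equal(r1$n_scenarios, 2L)
  expect_error(suppressWarnings(run_scenarios(gen$table, list(s_bad))),
               "no scenarios")
})

test_that("experiment statistics serialise as TSV", {
  space <- fx_small_space()
  pairs <- generate_priming_pairs(space, n_pairs = 10, seed = 59)
  res <- run_priming(space, pairs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(res, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("effect", "F", "df1", "df2", "p"))
  expect_equal(tab$F[[1L]], res$stats$t$t^2, tolerance = 1e-9)
})
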