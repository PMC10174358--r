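# Shared fixtures, built lazily and cached for the whole test run.
# Seeds and sizes here define the simulated study conditions used across
# the suite; heavy objects (the full-scale tracking reservoir, the
# 50-subject pool) are constructed once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixtures, inherits = FALSE))
    assign(name, builder(), .fixtures)
  get(name, .fixtures, inherits = FALSE)
}

# Full-scale synthetic semantic space: 100-dim, 10 clusters x 500 words.
fx_space <- function() fixture("space", function() {
  generate_synthetic_space(dim = 100, n_clusters = 10,
                           words_per_cluster = 500, seed = 101)
})

# Paper-scale tracking setup: >= 5e4 training tokens, 60 held-out docs,
# 100-unit reservoir (leak 0.2, ridge 1e-2).
fx_tracking <- function() fixture("tracking", function() {
  space <- fx_space()
  train <- generate_training_stream(space, n_docs = 380,
                                    doc_len_range = c(80L, 200L),
                                    seed = 102)
  held <- generate_training_stream(space, n_docs = 60,
                                   doc_len_range = c(80L, 200L),
                                   seed = 103)
  model <- train_discourse_reservoir(space, train,
                                     reservoir_config(seed = 104))
  curve <- evaluate_average_tracking(model, held, space,
                                     max_position = 15L)
  list(space = space, train = train, held = held, model = model,
       curve = curve)
})

# Shared training stream for subject pools (shorter than tracking scale:
# pools trade stream length for number of subjects).
fx_pool_stream <- function() fixture("pool_stream", function() {
  generate_training_stream(fx_space(), n_docs = 120,
                           doc_len_range = c(40L, 120L), seed = 105)
})

# 50 reservoir subjects, seeds 0..49.
fx_pool50 <- function() fixture("pool50", function() {
  train_subject_pool(fx_space(), fx_pool_stream(), seeds = 0:49)
})

# Small space for cheap unit tests: 16-dim, 4 clusters x 12 words.
fx_small_space <- function() fixture("small_space", function() {
  generate_synthetic_space(dim = 16, n_clusters = 4,
                           words_per_cluster = 12, seed = 201)
})

# Small trained reservoir over the small space.
fx_small_model <- function() fixture("small_model", function() {
  space <- fx_small_space()
  stream <- generate_training_stream(space, n_docs = 60,
                                     doc_len_range = c(10L, 40L),
                                     seed = 202)
  train_discourse_reservoir(space, stream,
                            reservoir_config(n_units = 40L, seed = 203))
})

# Random embedding table over an arbitrary vocabulary (for text tests).
random_table_for <- function(words, dim = 24, seed = 301) {
  set.seed(seed)
  m <- matrix(rnorm(length(words) * dim), length(words), dim)
  rownames(m) <- words
  embedding_table(m)
}

peanut_text <- function() {
  paste(readLines(system.file("extdata", "peanut_discourse.txt",
                              package = "discourseN400")),
        collapse = " ")
}
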