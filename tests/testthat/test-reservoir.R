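test_that("configuration is validated", {
  expect_error(reservoir_config(leak_rate = 0), "leak_rate")
  expect_error(reservoir_config(leak_rate = 1.5), "leak_rate")
  expect_error(reservoir_config(ridge_penalty = -1), "ridge_penalty")
  expect_error(reservoir_config(feedback = TRUE), "feedback")
})

test_that("initialisation is deterministic with the requested spectral radius", {
  cfg <- reservoir_config(n_units = 30L, seed = 5)
  m1 <- init_reservoir(cfg, input_dim = 8, output_dim = 8)
  m2 <- init_reservoir(cfg, input_dim = 8, output_dim = 8)
  expect_identical(m1$W_in, m2$W_in)
  expect_identical(m1$W_rec, m2$W_rec)
  expect_identical(m1$bias, m2$bias)

  # eigenvalue oracle for the rescaling
  rho <- max(abs(eigen(m1$W_rec, only.values = TRUE)$values))
  expect_equal(rho, 0.95, tolerance = 1e-6)

  m3 <- init_reservoir(reservoir_config(n_units = 30L, seed = 6), 8, 8)
  expect_gt(max(abs(m3$W_rec - m1$W_rec)), 0)
})

test_that("the leaky update obeys its limiting cases and a hand computation", {
  cfg <- reservoir_config(n_units = 3L, leak_rate = 1, seed = 1)
  m <- init_reservoir(cfg, input_dim = 2, output_dim = 2)
  m$W_rec <- matrix(0, 3, 3)
  m$bias <- rep(0, 3)
  u <- c(0.3, -0.7)
  # memoryless limit: leak 1, no recurrence
  x1 <- reservoir_step(m, c(5, -5, 5), u)
  expect_equal(x1, unname(tanh(m$W_in %*% u)[, 1L]), tolerance = 1e-14)

  # pure decay: zero input, zero recurrence
  cfg2 <- reservoir_config(n_units = 3L, leak_rate = 0.25, seed = 1)
  m2 <- init_reservoir(cfg2, input_dim = 2, output_dim = 2)
  m2$W_rec <- matrix(0, 3, 3); m2$W_in <- matrix(0, 3, 2)
  m2$bias <- rep(0, 3)
  x <- c(0.4, -0.8, 0.2)
  expect_equal(reservoir_step(m2, x, c(0, 0)), 0.75 * x,
               tolerance = 1e-14)

  # three-step trajectory on a two-unit reservoir with hand-fixed weights
  cfg3 <- reservoir_config(n_units = 2L, leak_rate = 0.5, seed = 1,
                           spectral_radius = 0.5)
  m3 <- init_reservoir(cfg3, input_dim = 1, output_dim = 1)
  m3$W_in <- matrix(c(1, -1), 2, 1)
  m3$W_rec <- matrix(c(0.5, 0, 0.25, -0.5), 2, 2)
  m3$bias <- c(0.1, -0.1)
  a <- 0.5
  x <- c(0, 0)
  for (u in c(1, -0.5, 0.25)) {
    x_hand <- (1 - a) * x +
      a * tanh(m3$W_in %*% u + m3$W_rec %*% x + m3$bias)[, 1L]
    x <- reservoir_step(m3, x, u)
    expect_equal(x, x_hand, tolerance = 1e-12)
  }
  # tanh keeps components inside (-1, 1)
  expect_true(all(abs(x) < 1))

  expect_error(reservoir_step(m3, c(0, 0), c(1, 2)), "length")
})

test_that("state collection aligns running-average targets and resets per document", {
  space <- fx_small_space()
  w <- vocabulary(space)[1:5]
  model <- init_reservoir(reservoir_config(n_units = 10L, seed = 2),
                          space$dim, space$dim)

  one <- collect_states(model, token_stream(list(w[1L])), space)
  expect_equal(unname(one$targets[1L, ]), unname(embedding(space, w[1L])),
               tolerance = 1e-14)

  three <- collect_states(model, token_stream(list(w[1:3])), space)
  expect_equal(unname(three$targets[3L, ]),
               unname(colMeans(space$vectors[w[1:3], ])),
               tolerance = 1e-13)

  # document boundary reset: doc 2 is independent of doc 1
  both <- collect_states(model, token_stream(list(w[1:3], w[4:5])), space)
  alone <- collect_states(model, token_stream(list(w[4:5])), space)
  expect_equal(both$states[4:5, ], alone$states, tolerance = 1e-14)

  expect_error(collect_states(model, token_stream(list(c(w[1L], "zzz"))),
                              space), class = "oov_error")
})

test_that("ridge readout matches the closed-form solution and its limits", {
  set.seed(11)
  # interpolation: square invertible states, no penalty
  S <- matrix(rnorm(36), 6, 6)
  T_ <- matrix(rnorm(12), 6, 2)
  W <- train_readout(S, T_, 0)
  expect_lt(max(abs(S %*% t(W) - T_)), 1e-10)

  # closed-form oracle
  S <- matrix(rnorm(500), 50, 10)
  T_ <- matrix(rnorm(150), 50, 3)
  W <- train_readout(S, T_, 0.01)
  W_oracle <- t(solve(crossprod(S) + 0.01 * diag(10), crossprod(S, T_)))
  expect_lt(max(abs(W - W_oracle)) / max(abs(W_oracle)), 1e-8)

  # shrinkage: readout norm decreases in the penalty
  norms <- vapply(c(0.01, 1, 100), function(l)
    sqrt(sum(train_readout(S, T_, l)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))

  expect_error(train_readout(S, T_[1:10, ], 0.01), "same number of rows")
})

test_that("training is deterministic and tracking improves with position", {
  space <- fx_small_space()
  stream <- generate_training_stream(space, n_docs = 60,
                                     doc_len_range = c(10L, 40L),
                                     seed = 202)
  cfg <- reservoir_config(n_units = 40L, seed = 203)
  m1 <- train_discourse_reservoir(space, stream, cfg)
  m2 <- train_discourse_reservoir(space, stream, cfg)
  expect_identical(m1$W_out, m2$W_out)
  expect_error(train_discourse_reservoir(space, token_stream(list()), cfg),
               "empty")

  held <- generate_training_stream(space, n_docs = 30,
                                   doc_len_range = c(12L, 40L), seed = 205)
  curve <- evaluate_average_tracking(m1, held, space, max_position = 10L)
  expect_gt(curve$mean_cosine[curve$position == 10],
            curve$mean_cosine[curve$position == 1])

  # an untrained-random readout tracks worse than the trained one
  m_rand <- m1
  set.seed(1)
  m_rand$W_out <- matrix(rnorm(length(m1$W_out), sd = 0.1),
                         nrow(m1$W_out), ncol(m1$W_out))
  curve_rand <- evaluate_average_tracking(m_rand, held, space,
                                          max_position = 10L)
  expect_gt(curve$mean_cosine[curve$position == 10],
            curve_rand$mean_cosine[curve_rand$position == 10])
})

test_that("a toy low-dimensional reservoir still learns the running average", {
  toy <- generate_synthetic_space(dim = 4, n_clusters = 2,
                                  words_per_cluster = 10, seed = 21)
  stream <- generate_training_stream(toy, n_docs = 400,
                                     doc_len_range = c(5L, 20L), seed = 22)
  expect_gte(n_tokens(stream), 1e4 / 5)  # thousands of tokens suffice here
  model <- train_discourse_reservoir(toy, stream,
                                     reservoir_config(n_units = 50L,
                                                      seed = 23))
  held <- generate_training_stream(toy, n_docs = 50,
                                   doc_len_range = c(6L, 20L), seed = 24)
  curve <- evaluate_average_tracking(model, held, toy, max_position = 5L)
  expect_gt(curve$mean_cosine[curve$position == 5], 0.5)
})

test_that("a perfect readout scores cosine 1 at every position", {
  # single repeated token: the running-average target is constant, and 8
  # generic states in 12 dimensions admit an exactly interpolating
  # unpenalised readout -- an injected perfect predictor
  space <- fx_small_space()
  w <- vocabulary(space)[[1L]]
  model <- init_reservoir(reservoir_config(n_units = 12L, leak_rate = 1,
                                           seed = 3),
                          space$dim, space$dim)
  stream <- token_stream(list(rep(w, 8L)))
  st <- collect_states(model, stream, space)
  model$W_out <- train_readout(st$states, st$targets, 0)
  curve <- evaluate_average_tracking(model, stream, space,
                                     max_position = 8L, min_docs = 1L)
  expect_equal(curve$mean_cosine, rep(1, 8), tolerance = 1e-8)
})

test_that("tracking is non-decreasing on average across early positions", {
  fx <- fx_tracking()
  curve <- fx$curve
  early <- curve$mean_cosine[curve$position <= 10]
  expect_true(all(diff(early) > -0.02))
  expect_gt(curve$mean_cosine[curve$position == 10],
            curve$mean_cosine[curve$position == 1])
})

test_that("models serialise bit-identically", {
  model <- fx_small_model()
  f <- withr::local_tempfile(fileext = ".rds")
  write_reservoir(model, f)
  expect_identical(read_reservoir(f), model)
})
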