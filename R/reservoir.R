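# The discourse reservoir: a leaky echo state network whose ridge readout is
# trained to emit the running average of its input word vectors.

#' Reservoir hyperparameters
#'
#' Defaults follow the discourse-reservoir configuration used throughout the
#' package: 100 leaky tanh units, leak rate 0.2, ridge penalty 1e-2,
#' spectral radius 0.95, full recurrent density, no output feedback.
#'
#' @param n_units Number of reservoir units.
#' @param leak_rate Leaky-integration coefficient in (0, 1]; the state moves
#'   this fraction of the way toward the instantaneous activation each step.
#' @param ridge_penalty Non-negative L2 penalty of the readout regression.
#' @param spectral_radius Largest absolute eigenvalue the recurrent matrix
#'   is rescaled to; values below 1 preserve the echo-state property.
#' @param input_scaling Multiplier on the input weights.
#' @param bias_scaling Multiplier on the per-unit bias.
#' @param recurrent_density Fraction of non-zero recurrent weights in (0, 1].
#' @param washout Number of initial steps per document excluded from readout
#'   training.
#' @param seed Integer seed; all weights are a pure function of the seed and
#'   this configuration.
#' @param feedback Must be `FALSE`: the discourse reservoir has no feedback
#'   from readout to reservoir.
#' @param concat_input If `TRUE` the readout regresses on the concatenation
#'   of reservoir state and raw input; the default regresses on the state
#'   alone.
#' @param normalize_inputs If `TRUE` input vectors are scaled to unit norm
#'   before entering the reservoir (targets are averages of the normalised
#'   vectors). Default off: embeddings are fed raw.
#' @return An object of class `reservoir_config`.
#' @export
reservoir_config <- function(n_units = 100L, leak_rate = 0.2,
                             ridge_penalty = 1e-2, spectral_radius = 0.95,
                             input_scaling = 1.0, bias_scaling = 0.1,
                             recurrent_density = 1.0, washout = 0L,
                             seed = 1L, feedback = FALSE,
                             concat_input = FALSE,
                             normalize_inputs = FALSE) {
  stopifnot(n_units >= 1, leak_rate > 0, leak_rate <= 1,
            ridge_penalty >= 0, spectral_radius > 0, input_scaling > 0,
            bias_scaling >= 0, recurrent_density > 0, recurrent_density <= 1,
            washout >= 0)
  if (isTRUE(feedback))
    stop("output feedback is not part of the discourse reservoir model",
         call. = FALSE)
  structure(list(n_units = as.integer(n_units), leak_rate = leak_rate,
                 ridge_penalty = ridge_penalty,
                 spectral_radius = spectral_radius,
                 input_scaling = input_scaling, bias_scaling = bias_scaling,
                 recurrent_density = recurrent_density,
                 washout = as.integer(washout), seed = as.integer(seed),
                 feedback = FALSE, concat_input = isTRUE(concat_input),
                 normalize_inputs = isTRUE(normalize_inputs)),
            class = "reservoir_config")
}

#' Initialise a reservoir with fixed random weights
#'
#' Input weights and biases are drawn uniformly from a symmetric interval;
#' the recurrent matrix is drawn the same way (with optional sparsity) and
#' rescaled so its spectral radius equals `config$spectral_radius`.
#' Everything is a pure function of `config` (including its seed), so a
#' model can be regenerated from its configuration alone.
#'
#' @param config A [reservoir_config()].
#' @param input_dim,output_dim Dimensionality of input and readout vectors.
#' @return An object of class `reservoir_model` with weight matrices
#'   `W_in`, `W_rec`, `bias`, and (after training) `W_out`.
#' @export
init_reservoir <- function(config, input_dim, output_dim) {
  stopifnot(inherits(config, "reservoir_config"),
            input_dim >= 1, output_dim >= 1)
  n <- config$n_units
  local_seed(config$seed)
  W_in <- matrix(stats::runif(n * input_dim, -1, 1), n, input_dim) *
    config$input_scaling
  W_rec <- matrix(stats::runif(n * n, -1, 1), n, n)
  if (config$recurrent_density < 1) {
    mask <- matrix(stats::runif(n * n) < config$recurrent_density, n, n)
    W_rec <- W_rec * mask
  }
  rho <- max(abs(eigen(W_rec, only.values = TRUE)$values))
  if (rho == 0)
    stop("degenerate recurrent matrix (spectral radius 0)", call. = FALSE)
  W_rec <- W_rec * (config$spectral_radius / rho)
  bias <- stats::runif(n, -1, 1) * config$bias_scaling
  structure(list(config = config, input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 W_in = W_in, W_rec = W_rec, bias = bias,
                 W_out = NULL, training_mse = NULL),
            class = "reservoir_model")
}

#' @export
print.reservoir_model <- function(x, ...) {
  cat(sprintf(paste0("<reservoir_model> %d units, input %d, output %d, ",
                     "leak %.3g, ridge %.3g, seed %d (%s)\n"),
              x$config$n_units, x$input_dim, x$output_dim,
              x$config$leak_rate, x$config$ridge_penalty, x$config$seed,
              if (is.null(x$W_out)) "untrained" else "trained"))
  invisible(x)
}

is_trained <- function(model) !is.null(model$W_out)

#' One leaky echo-state update
#'
#' Computes `x' = (1 - a) * x + a * tanh(W_in u + W_rec x + bias)` with
#' `a` the leak rate — leaky integration applied after the nonlinearity,
#' the standard echo-state convention.
#'
#' @param model A `reservoir_model`.
#' @param state Numeric vector of length `n_units` (use zeros at a document
#'   boundary).
#' @param u Input vector of length `input_dim`.
#' @return The updated state vector.
#' @export
reservoir_step <- function(model, state, u) {
  stopifnot(inherits(model, "reservoir_model"))
  if (length(u) != model$input_dim)
    stop(sprintf("input has length %d, expected %d",
                 length(u), model$input_dim), call. = FALSE)
  if (length(state) != model$config$n_units)
    stop("state has the wrong length", call. = FALSE)
  a <- model$config$leak_rate
  act <- tanh(drop(model$W_in %*% u) + drop(model$W_rec %*% state) +
                model$bias)
  (1 - a) * state + a * act
}

#' Initial (zero) reservoir state
#' @param model A `reservoir_model`.
#' @export
reservoir_zero_state <- function(model) numeric(model$config$n_units)

#' Readout output for a given state
#'
#' @param model A trained `reservoir_model`.
#' @param state Current state vector.
#' @param u Last input vector; only required when the model was trained with
#'   `concat_input = TRUE`.
#' @return Numeric vector of length `output_dim`.
#' @export
reservoir_output <- function(model, state, u = NULL) {
  if (!is_trained(model))
    stop("reservoir readout has not been trained", call. = FALSE)
  feat <- if (model$config$concat_input) {
    if (is.null(u)) stop("model uses concat_input; supply `u`",
                         call. = FALSE)
    c(state, u)
  } else state
  drop(model$W_out %*% feat)
}

# Run the reservoir over a T x input_dim matrix from the zero state.
# Returns the T x n_units matrix of post-update states. The input drive
# W_in %*% u is precomputed for all rows in one BLAS call.
run_reservoir_states <- function(model, U) {
  n <- model$config$n_units
  a <- model$config$leak_rate
  drive <- U %*% t(model$W_in)      # T x n
  drive <- sweep(drive, 2L, model$bias, "+")
  W <- model$W_rec
  X <- matrix(0, nrow(U), n)
  x <- numeric(n)
  for (t in seq_len(nrow(U))) {
    x <- (1 - a) * x + a * tanh(drive[t, ] + drop(W %*% x))
    X[t, ] <- x
  }
  X
}

# Embedding matrix for one document's tokens, honouring normalize_inputs.
doc_input_matrix <- function(model_or_config, tokens, table) {
  U <- table$vectors[tolower(tokens), , drop = FALSE]
  cfg <- if (inherits(model_or_config, "reservoir_model"))
    model_or_config$config else model_or_config
  if (cfg$normalize_inputs)
    U <- U / sqrt(rowSums(U^2))
  U
}

# Running-mean rows of a T x d matrix: row k is the mean of rows 1..k.
running_mean_rows <- function(U) {
  if (nrow(U) == 1L) return(U)
  apply(U, 2L, cumsum) / seq_len(nrow(U))
}

#' Collect training states and running-average targets
#'
#' Runs the reservoir over every document of a stream, resetting the state
#' to zero at each document boundary. The target row aligned with the k-th
#' token of a document is the arithmetic mean of that document's first k
#' input vectors (current token included). Rows during the configured
#' washout are excluded from both matrices.
#'
#' @param model A `reservoir_model` (trained or not).
#' @param stream A [token_stream()]; every token must be in `table`.
#' @param table An [embedding_table()].
#' @return List with `states` (rows x state features) and `targets`
#'   (rows x output_dim) matrices.
#' @export
collect_states <- function(model, stream, table) {
  stopifnot(inherits(model, "reservoir_model"),
            inherits(stream, "token_stream"),
            inherits(table, "embedding_table"))
  miss <- setdiff(tolower(unlist(stream)), rownames(table$vectors))
  if (length(miss) > 0)
    stop(oov_error(miss))
  wash <- model$config$washout
  states <- vector("list", length(stream))
  targets <- vector("list", length(stream))
  for (i in seq_along(stream)) {
    U <- doc_input_matrix(model, stream[[i]], table)
    X <- run_reservoir_states(model, U)
    if (model$config$concat_input) X <- cbind(X, U)
    Tm <- running_mean_rows(U)
    keep <- seq_len(nrow(U)) > wash
    states[[i]] <- X[keep, , drop = FALSE]
    targets[[i]] <- Tm[keep, , drop = FALSE]
  }
  list(states = do.call(rbind, states), targets = do.call(rbind, targets))
}

#' Train a ridge-regression readout
#'
#' Finds `W` minimising `||S W' - T||^2 + lambda ||W||^2` via the singular
#' value decomposition of the state matrix (numerically stable for
#' ill-conditioned state ensembles).
#'
#' @param states Numeric matrix `S` (rows = time steps).
#' @param targets Numeric matrix `T` with the same row count.
#' @param ridge_penalty Non-negative penalty `lambda`.
#' @return The readout matrix `W` (output_dim x state features).
#' @export
train_readout <- function(states, targets, ridge_penalty) {
  if (!is.matrix(states)) states <- as.matrix(states)
  if (!is.matrix(targets)) targets <- as.matrix(targets)
  if (nrow(states) != nrow(targets))
    stop("states and targets must have the same number of rows",
         call. = FALSE)
  if (nrow(states) == 0L)
    stop("cannot train a readout on zero rows", call. = FALSE)
  stopifnot(ridge_penalty >= 0)
  sv <- svd(states)
  shrink <- sv$d / (sv$d^2 + ridge_penalty)
  if (ridge_penalty == 0) shrink[sv$d == 0] <- 0
  # W' = V diag(shrink) U' T
  t(sv$v %*% (shrink * (t(sv$u) %*% targets)))
}

#' Train the discourse reservoir on a token stream
#'
#' Initialises the reservoir from `config`, collects states with
#' document-boundary resets and running-average targets, and fits the ridge
#' readout.
#'
#' @inheritParams collect_states
#' @param config A [reservoir_config()].
#' @return A trained `reservoir_model`; `training_mse` holds the mean
#'   squared training error of the readout.
#' @export
train_discourse_reservoir <- function(table, stream, config = reservoir_config()) {
  stopifnot(inherits(stream, "token_stream"))
  if (length(stream) == 0L)
    stop("cannot train on an empty stream", call. = FALSE)
  model <- init_reservoir(config, input_dim = table$dim,
                          output_dim = table$dim)
  st <- collect_states(model, stream, table)
  model$W_out <- train_readout(st$states, st$targets, config$ridge_penalty)
  resid <- st$states %*% t(model$W_out) - st$targets
  model$training_mse <- mean(resid^2)
  model
}

#' Evaluate running-average tracking by within-document position
#'
#' For each document of `stream`, runs the trained reservoir from the zero
#' state and computes the cosine similarity between the readout and the
#' true running-average vector at every token position, then averages
#' across documents per position. Positions supported by fewer than
#' `min_docs` documents are omitted.
#'
#' @inheritParams collect_states
#' @param max_position Largest within-document position reported.
#' @param min_docs Minimum number of supporting documents per position.
#' @return Data frame with columns `position`, `mean_cosine`, `n_docs`.
#' @export
evaluate_average_tracking <- function(model, stream, table,
                                      max_position = 20L, min_docs = 5L) {
  if (!is_trained(model))
    stop("model must be trained before evaluation", call. = FALSE)
  stopifnot(inherits(stream, "token_stream"))
  sums <- numeric(max_position)
  counts <- integer(max_position)
  for (doc in stream) {
    U <- doc_input_matrix(model, doc, table)
    X <- run_reservoir_states(model, U)
    if (model$config$concat_input) X <- cbind(X, U)
    P <- X %*% t(model$W_out)
    Tm <- running_mean_rows(U)
    upto <- min(nrow(U), max_position)
    for (k in seq_len(upto)) {
      sums[k] <- sums[k] + cosine(P[k, ], Tm[k, ])
      counts[k] <- counts[k] + 1L
    }
  }
  keep <- counts >= min_docs
  data.frame(position = which(keep), mean_cosine = sums[keep] / counts[keep],
             n_docs = counts[keep])
}

#' Serialise / restore a reservoir model
#'
#' The archive holds the configuration (including the seed) and all weight
#' matrices; restoring yields a bit-identical model.
#'
#' @param model A `reservoir_model`.
#' @param path File path for the archive.
#' @return `write_reservoir` returns `path` invisibly; `read_reservoir`
#'   returns the restored `reservoir_model`.
#' @export
write_reservoir <- function(model, path) {
  stopifnot(inherits(model, "reservoir_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_reservoir
#' @export
read_reservoir <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "reservoir_model"))
    stop("file does not contain a reservoir model", call. = FALSE)
  model
}
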