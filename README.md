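# discourseN400

An R package for simulating N400 amplitudes during discourse
comprehension with word embeddings and reservoir computing.

## The scientific problem

The N400 is a scalp-recorded event-related potential that peaks about
400 ms after a word and grows with the word's semantic unexpectedness.
Two robust phenomena constrain any computational account of it:

* **Immediacy** — every available information source (lexical semantics,
  the prior discourse, world knowledge) influences the N400 with no
  measurable time penalty.
* **Discourse overrule** — prior discourse can reverse the N400 pattern
  expected from local lexical semantics. In the classic demonstration, a
  story that frames a peanut as an animate, love-struck agent makes
  *"the peanut was salted"* elicit the N400 rather than *"the peanut was
  in love"*.

This package implements a model in which both effects follow from
*temporal-to-spatial integration*: serially arriving experience is folded
into a distributed spatial representation that can be read out
immediately.

* **Lifetime timescale** — word meaning is a dense embedding vector
  (100-dimensional, word2vec-style), loadable from standard word2vec text
  files or generated synthetically with controlled cluster structure.
* **Discourse timescale** — the discourse context is accumulated online,
  either by the bag-of-words **average** of the word vectors seen so far,
  or by a **discourse reservoir**: a leaky echo state network (ESN) with
  fixed random recurrent weights whose ridge-regression readout is
  trained to emit the running average
  `avg(w1), avg(w1,w2), …, avg(w1…wN)` of its input sequence.

The linking hypothesis mapping model state to brain response is

```
N400(context, target) = 1 − cos(context vector, target embedding)
```

so an incoming word that is far from the current discourse vector
predicts a large N400. The reservoir state update is the standard leaky
ESN equation

```
x(t+1) = (1 − a) x(t) + a tanh(W_in u(t+1) + W_rec x(t) + b)
```

with leak rate `a = 0.2`, 100 tanh units, spectral radius 0.95 and a
readout trained by ridge regression (penalty `1e-2`).

Three simulation harnesses reproduce the model's behavioural signatures,
each analysed over a pool of independently initialised reservoirs
("subjects") with paired t tests and within-subject two-factor ANOVAs:

1. **Semantic priming** (`run_priming`) — related word pairs predict a
   smaller N400 than unrelated pairs.
2. **Discourse overrule** (`run_peanut`) — the N400 ordering of a
   locally related vs. a discourse-aligned target reverses between the
   first and last word of the discourse.
3. **Event-knowledge rescue** (`run_scenarios`) — an unexpected
   completion that is related to the described event has its N400
   reduced only when the discourse context is present.

## Worked example

```r
library(discourseN400)

# a synthetic semantic space: 10 clusters of 500 words in 100 dimensions
space <- generate_synthetic_space(dim = 100, n_clusters = 10,
                                  words_per_cluster = 500, seed = 11)

# train the discourse reservoir to emit the running-average vector
stream <- generate_training_stream(space, n_docs = 380,
                                   doc_len_range = c(80, 200), seed = 12)
model <- train_discourse_reservoir(space, stream, reservoir_config(seed = 13))

held <- generate_training_stream(space, n_docs = 60,
                                 doc_len_range = c(80, 200), seed = 14)
evaluate_average_tracking(model, held, space, max_position = 10)[c(1, 5, 10), ]
#>    position mean_cosine n_docs
#> 1         1   0.7973758     60
#> 5         5   0.9198659     60
#> 10       10   0.9513913     60
```

The readout tracks the true running average ever more closely as the
discourse unfolds — above 0.9 cosine by the fifth word here.

```r
# semantic priming: related pairs predict a smaller N400
pairs <- generate_priming_pairs(space, n_pairs = 40, seed = 15)
run_priming(space, pairs)
#> <experiment_result: priming>
#> condition means:
#>   related                  0.4911
#>   unrelated                1.0060
#> Paired t: t(39) = -32.56, p = 6.82e-30, mean diff = -0.5149

# discourse overrule across a 10-subject reservoir pool
pool_stream <- generate_training_stream(space, n_docs = 120,
                                        doc_len_range = c(40, 120), seed = 16)
models <- train_subject_pool(space, pool_stream, seeds = 0:9)
fix <- generate_overrule_discourse(space, seed = 17)
res <- run_peanut(space, fix$tokens,
                  c(fix$local_target, fix$discourse_target), models)
res$reversal_rate
#> [1] 1
res$stats$anova
#> Repeated-measures ANOVA (10 subjects)
#>   phase                F(1, 9) = 60.13, p = 2.837e-05
#>   target               F(1, 9) = 2.676, p = 0.1363
#>   phase:target         F(1, 9) = 2057, p = 6.154e-12
```

Every subject shows the reversal (`reversal_rate = 1`): the
discourse-aligned target starts with the higher predicted N400 and ends
with the lower one, and the phase-by-target interaction — the signature
of discourse overrule — is decisive.

A command-line interface wrapping the same functions lives at
`inst/cli/discourse-n400.R` (subcommands `make-space`, `make-stream`,
`train-reservoir`, `eval-tracking`, `priming`, `peanut`, `scenarios`,
`make-fixtures`, `rerun`); every run writes a YAML manifest from which it
can be re-executed byte-identically.

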