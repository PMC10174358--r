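---
title: "Modeling the N400 with discourse reservoirs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the N400 with discourse reservoirs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discourseN400)
```

# The model

The package models the N400 event-related potential during discourse
comprehension as a mismatch between two distributed representations:

* the **target word**, a dense embedding vector encoding lexical meaning
  accumulated over a lifetime of linguistic experience, and
* the **discourse context**, a vector of the same dimensionality
  accumulated online over the words of the current discourse.

The linking hypothesis is

$$\mathrm{N400} = 1 - \cos(\mathbf{c}, \mathbf{w}),$$

where $\mathbf{c}$ is the current context vector and $\mathbf{w}$ the
incoming word's embedding. Values lie in $[0, 2]$: 0 for a word
pointing exactly along the context, 1 for an orthogonal word, 2 for an
antiparallel one. Predicted N400 values are reported raw — no clamping,
standardisation or baselining — because the quantity of interest in all
analyses is a *within-design contrast* (related vs. unrelated,
beginning vs. end, sentence vs. discourse), which is invariant to any
monotone rescaling.

## Context aggregation

Two aggregators sit behind one stateful interface
(`agg_feed()` / `agg_current()` / `agg_reset()`):

* **Average** (`average_aggregator()`): the arithmetic mean of all word
  vectors fed so far — the bag-of-words discourse representation. It is
  order-blind and exact.
* **Discourse reservoir** (`reservoir_aggregator()`): a leaky echo
  state network. The state update after input $\mathbf{u}$ is
  $$\mathbf{x}' = (1-a)\,\mathbf{x} +
    a \tanh(W_{in}\mathbf{u} + W_{rec}\mathbf{x} + \mathbf{b}),$$
  and the context vector is a trained linear readout
  $\mathbf{c} = W_{out}\mathbf{x}$. $W_{in}$, $W_{rec}$ and
  $\mathbf{b}$ are fixed at initialisation; only $W_{out}$ is learned,
  by ridge regression against **running-average targets**: when the
  reservoir has seen the first $k$ words of a document, the target is
  $\tfrac1k\sum_{i\le k}\mathbf{w}_i$. A reservoir that solves this
  task implements the bag-of-words representation as a recurrent
  network with instantaneous access to the accumulated discourse —
  temporal-to-spatial integration.

The readout is deliberately imperfect, and that imperfection is part of
the model's behaviour: at position 1 the readout cannot copy its input
exactly (the contrast between targets is compressed early in a
discourse), and tracking fidelity grows with position.

## Reservoir parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_units` | 100 | reservoir size; matches the 100-dimensional embeddings |
| `leak_rate` | 0.2 | fraction of the distance to the instantaneous activation covered per step; small values give slow, smooth state dynamics |
| `ridge_penalty` | 1e-2 | L2 penalty of the readout regression |
| `spectral_radius` | 0.95 | largest \|eigenvalue\| of $W_{rec}$ after rescaling; below 1 preserves the echo-state property (fading memory) |
| `input_scaling` | 1.0 | multiplier on $W_{in}$ |
| `bias_scaling` | 0.1 | multiplier on the per-unit bias; kept small so units stay in the responsive region of tanh |
| `recurrent_density` | 1.0 | fully dense recurrent matrix |
| `washout` | 0 | no training rows discarded: with per-document state resets the early, transient rows are exactly the ones that carry the position-1..5 behaviour we analyse |
| `feedback` | FALSE (fixed) | no readout-to-reservoir feedback |

The leak rate, ridge penalty, unit count and absence of feedback define
the discourse-reservoir configuration; the remaining values are this
package's explicit defaults where the underlying toolkit convention
leaves them unstated, and all of them are recorded in every run
manifest. Two further flags are exposed and **off** by default, as the
minimal reading of the model: `concat_input` (readout sees the raw input
alongside the state) and `normalize_inputs` (unit-norm inputs). Cosine
similarity is scale-free, so normalisation mostly matters for the
reservoir's internal operating point.

Leaky integration is applied *after* the nonlinearity (the standard
echo-state convention). The training solver is an SVD-based ridge
solution; any solver is acceptable that matches the closed-form
$(S^\top S + \lambda I)^{-1} S^\top T$ to $10^{-8}$ relative error, and
the test suite holds the implementation to exactly that oracle.

**Document-boundary resets.** The running-average target
$\mathrm{avg}(w_1 \dots w_k)$ is only meaningful within a document, so
during training both the reservoir state and the target accumulator are
reset at every document boundary. The same convention applies at
evaluation: each discourse, scenario or document starts from the zero
state.

# The synthetic semantic space

Self-contained runs use a generated space instead of a pretrained
embedding file. `generate_synthetic_space()` places `n_clusters` unit
centres at random in $d$ dimensions (random Gaussian directions are
nearly orthogonal in high $d$) and draws each word as
$\mathbf{v} = (\mathbf{c} + \sigma\mathbf{z}) / \lVert\cdot\rVert$ with
$\mathbf{z}$ standard normal. The expected within-cluster cosine is
approximately $1/(1 + \sigma^2 d)$ while between-cluster cosines
concentrate near 0. The default $\sigma = 0.1$ at $d = 100$ gives
within-cluster cosines around $0.5$ — comparable to strongly related
word pairs in corpus-trained embeddings — and a related/unrelated
cosine gap of about 0.5, comfortably above the 0.3 construction gap the
priming simulation requires.

`generate_training_stream()` emulates a corpus of topically coherent
articles: each document draws a primary cluster and samples each token
from it with probability
$\theta/(1+\theta)$ (`topic_concentration` $\theta$, default 9, i.e.
90% topical tokens), otherwise uniformly from the vocabulary. Topical
coherence is what makes the running average informative and the
tracking task learnable at realistic stream sizes.

**What the generator does not emulate.** Zipfian token frequencies,
syntax and word order regularities, polysemy, morphology, stop-word
distributions, and the graded (non-cluster) similarity structure of
real corpus embeddings. Passing simulations therefore show that the
*mechanism* — averaging, reservoir tracking, overrule by accumulated
context — behaves as described, not that any particular natural-language
stimulus set would yield particular values. Paper-exact numbers require
the original pretrained embeddings and stimulus corpora, which the
package accepts through `load_embeddings()` and the scenario/pair file
formats but does not ship.

## Stimulus generators

* **Priming pairs** (`generate_priming_pairs()`): 40 same-cluster and
  40 cross-cluster pairs, matched 1:1 by index for the paired t.
* **Overrule discourse** (`generate_overrule_discourse()`): a critical
  word from cluster A opens and closes the token sequence; 40
  intervening tokens come from cluster B. The *local* target is another
  cluster-A word (high similarity to the critical word alone); the
  *discourse-aligned* target is a cluster-B word. At the first token
  the context is the critical word and the local target wins; by the
  last token the accumulated context points at cluster B and the
  ordering reverses. No neutral prime is prepended, so that the first
  measurement is taken at the critical word itself, mirroring the
  "first and last word" design of the classic discourse. For
  natural-language texts, `preprocess()` supports a configurable
  `neutral_prime` (default suggestion `"thing"`: concrete, semantically
  bland) to give the reservoir a first input before the discourse
  proper.
* **Scenarios** (`generate_synthetic_scenarios()`): each item samples
  an *event* cluster (context sentences), a *neutral* cluster (the
  sentence stem) and a *distant* cluster. The three targets are
  synthesised vectors rather than existing words: Expected sits next to
  the context-plus-stem mixture, Unexpected-Related next to the event
  cluster's centre, Unexpected-Unrelated next to the distant cluster's
  centre, each nudged by a small perturbation ($\sigma = 0.05$) and
  added to the space under the item's name. Construction from controlled
  positions — rather than selection from the vocabulary — is what makes
  Expected the lowest-N400 completion in *both* context modes while
  leaving Related rescued only when the event context is present, the
  defining pattern of the design.

# Experiments and statistics

Reservoir **subject pools** (`train_subject_pool()`) hold everything
fixed except the initialisation seed: one space seed, one stream seed,
one stimulus seed, and per-subject reservoir seeds, so between-subject
variability isolates the network's random wiring, as in the
multi-instance analyses this design models.

* Priming: paired t across pair index (Welch t if conditions are
  unmatched), plus box summaries per condition.
* Overrule: per subject, predicted N400 for both targets at the first
  and last token; 2 × 2 within-subject ANOVA (phase × target); the
  per-subject *reversal indicator* requires the aligned target to be
  higher at the Beginning and lower at the End.
* Scenarios: per subject × context mode × condition, item-averaged
  means; 2 × 3 within-subject ANOVA (context × relatedness), pairwise
  post-hoc paired t tests within each mode (unadjusted p values, with a
  Bonferroni column provided), and the *rescue difference*
  (Unrelated − Related per subject and mode) compared between modes by
  paired t.

`rm_anova()` implements the fully-within two-factor partitioning:
sums of squares for subject, $A$, $A{\times}S$, $B$, $B{\times}S$,
$A{\times}B$ and $A{\times}B{\times}S$, each effect tested against its
own effect-by-subject stratum, no sphericity correction. Degrees of
freedom follow the conventional partitioning — for $a \times b$ levels
and $n$ subjects, $F_{A}(a-1, (a-1)(n-1))$ and
$F_{A\times B}((a-1)(b-1), (a-1)(b-1)(n-1))$. Published analyses of
this design sometimes print other denominator conventions for the main
effects; the conventional stratified partitioning is used here
throughout and is cross-checked in the tests against
`aov(y ~ A*B + Error(S/(A*B)))`.

## Numerical choices and degenerate inputs

* Cosine values are clipped to $[-1, 1]$ against floating-point
  excursions; zero vectors are a domain error everywhere (and are
  excluded from embedding tables at construction).
* The recurrent matrix is rescaled by its exact largest-magnitude
  eigenvalue; the test suite verifies the achieved spectral radius to
  $10^{-6}$.
* Ridge training uses the SVD with shrinkage factors
  $d_i/(d_i^2+\lambda)$; at $\lambda = 0$ zero singular values get zero
  weight (minimum-norm solution).
* `paired_t()` flags constant differences as `degenerate` instead of
  erroring: all-zero differences report $t = 0, p = 1$; constant
  non-zero differences report $t = \pm\infty, p = 0$.
* `rm_anova()` flags effects whose error stratum is exactly zero
  (noise-free constructions): $F = \infty$ when the effect sum of
  squares is positive, $F = 0$ when it is zero.
* Preprocessing never drops data silently: out-of-vocabulary tokens are
  warned about and counted in the token report, out-of-vocabulary pairs
  and scenarios are excluded with warnings, and empty results are
  typed errors (`preprocess_error`).
* Every seeded generator restores the caller's RNG state, so package
  calls do not perturb user-level random sequences.

## Problem sizes

The simulated study conditions used by the test suite and the
reproduction script: a 100-dimensional space of 10 × 500 words
($\sigma = 0.1$); a 380-document training stream (80–200 tokens per
document, ≈ 53,000 tokens) with 60 held-out documents for
running-average tracking; a 120-document (≈ 12,000-token) shared stream
for subject pools, which measure condition *contrasts* rather than
asymptotic tracking accuracy and are run with 50 subjects for the
overrule design and 10 subjects × 24 scenarios for the rescue design.
Priming uses 40 + 40 matched pairs. These sizes give decisive effects
(interaction p-values far below $10^{-5}$) at a few tens of seconds of
compute.

# Known limitations

* The reservoir learns to *approximate* the running average; all
  discourse-level predictions inherit that approximation, which is the
  point of the model but means single-subject values at early positions
  are noisy.
* The bag-of-words target ignores word order entirely; the reservoir
  aggregator is order-sensitive only through its approximation error.
* Synthetic spaces have block-like similarity structure; graded
  semantic relations (e.g. the partial relatedness of an event to a
  merely plausible completion) are only coarsely represented by the
  cluster mixture constructions.
* No latency, topography or single-trial variability of the N400 is
  modeled — only condition-level amplitude contrasts.
* Natural-language preprocessing is deliberately minimal (lowercasing,
  punctuation stripping, a frozen stop-word list, optional truncation):
  no lemmatisation, sentence segmentation or parsing.
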