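Package: discourseN400
Title: Temporal-Spatial Discourse Integration and N400 Prediction with
    Echo State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the N400 event-related potential during discourse
    comprehension as the dissimilarity between an online discourse
    representation and the embedding of an incoming word. Discourse
    context is accumulated either by a bag-of-words running average of
    word embeddings or by a leaky echo state network (the "discourse
    reservoir") whose linear readout is trained by ridge regression to
    emit the running-average vector of its input sequence. Includes a
    word2vec text format reader, a synthetic clustered semantic space
    and token-stream generator, harnesses for semantic priming,
    discourse-overrule and event-knowledge rescue simulations over
    pools of reservoir "subjects", and the within-subject statistics
    (paired t tests, repeated-measures ANOVA with post-hoc contrasts)
    used to analyse them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
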