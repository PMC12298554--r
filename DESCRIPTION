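Package: mignn
Title: Multiple-Instance Temporal Graph Networks for Severity Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates continuous clinical severity scores (BDI- or PHQ-8-style)
    from sessions of pre-extracted utterance-level multimodal features
    (audio, visual, text). Each session is treated as a bag of utterance
    instances: per-modality bidirectional gated recurrent encoders produce
    contextual embeddings, a windowed temporal graph with dual
    forward/backward relation types is built over the utterances, relational
    graph convolution and multi-head graph attention update the node
    features, and a linear head scores every utterance with the bag mean as
    the subject-level prediction, trained under a concordance-correlation
    loss. Includes exact hand-derived reverse-mode gradients, an Adam
    trainer with ablation variants and window/head sweeps, a seeded
    synthetic-cohort generator with a planted chronic-trend plus
    intermittent-burst severity signal, cohort readers/writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
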