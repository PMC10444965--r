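Package: fewner
Title: Few-Shot Biomedical Named Entity Recognition with Knowledge-Graph
    Augmentation and Prompt Contrastive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for few-shot biomedical named entity recognition (BioNER).
    Training data are augmented by knowledge-guided instance generation:
    candidate concepts in a sentence are matched against a biomedical knowledge
    graph (e.g. a UMLS Metathesaurus extract), a relation-filtered knowledge
    sub-graph is built around each candidate, and candidates are replaced by
    their neighbour concepts with BIO labels adjusted automatically.
    Recognition is cast as question answering: an entity-type question prompt
    is concatenated to the sentence and a token-level BIO classifier answers
    it. A prompt contrastive loss based on a Jensen-Shannon mutual-information
    lower bound ties entity representations to the matching prompt. The package
    ships a seedable K-shot sentence sampler, entity-level micro-averaged
    precision/recall/F1 evaluation with multi-seed aggregation, synthetic
    corpus and knowledge-graph generators, and a desk-scale trainable encoder
    so the whole pipeline runs on one CPU without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
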