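Package: ribodesign
Title: Secondary-Structure-Informed RNA Inverse Design with Relational Geometric Graph Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fixed-backbone RNA sequence design (inverse folding) from 3D
    structures, with explicit support for conformational switches such as
    riboswitches. RNA chains are converted into typed geometric graphs with
    mutually exclusive primary-structure, secondary-structure (canonical and
    non-canonical base pairs) and DBSCAN-derived spatial edge sets. A
    relational geometric-vector-perceptron message-passing encoder with
    learned per-edge-type pooling and multi-conformation averaging feeds
    one-shot or autoregressive decoders that emit per-position nucleotide
    probabilities. Includes sequence sampling, evaluation metrics
    (perplexity, accuracy, native sequence recovery, secondary-structure
    self-consistency), cluster-aware data splitting, and deterministic
    synthetic structure generators so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
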