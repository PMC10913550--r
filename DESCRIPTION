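Package: molae
Title: Recurrent Autoencoders for Molecular String Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sequence autoencoders for small-molecule string representations
    (SMILES and SELFIES). Implements a configurable family of GRU- and
    LSTM-based encoder-decoder architectures with latent bridging, optional
    additive attention and an optional variational head, trained with teacher
    forcing, Adam and early stopping. Includes SMILES tokenization and
    enumeration, an organic-subset SELFIES codec, reconstruction metrics
    (Mean Similarity, token-level Levenshtein similarity, Full Reconstruction
    rate), latent-space utilization typing and chemical-similarity
    diagnostics, plus a synthetic molecule generator so the whole pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    withr,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
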