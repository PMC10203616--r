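Package: tcrbinder
Title: Peptide-TCR Interaction Prediction with Fused Sequence Encodings
Version: 0.1.0
Authors@R: person("Repertoire", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a T cell receptor beta-chain CDR3 sequence
    recognizes a given MHC class I peptide. Pairs are encoded twice: a
    one-hot (or physicochemical) map of the concatenated peptide-CDR3
    sequence, and a distribution map built either from amino acid
    composition or from per-epitope amino acid position preference (AAPP)
    matrices computed over the epitope's cognate CDR3 repertoire. The two
    maps feed a dual-input convolutional network fused at the dense
    layers; unseen peptides are routed to their nearest training peptide
    by Levenshtein distance. Includes dataset curation, negative-pair
    sampling against a background repertoire, repeated cross-validation
    with leakage-safe AAPP construction, a synthetic motif-planting data
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
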