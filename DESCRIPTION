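Package: goembed
Title: Protein Function Prediction from Attributed Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) term annotations for proteins by
    embedding two attributed protein networks -- a protein-protein interaction
    network thresholded from interaction confidence scores and a sequence
    similarity network thresholded from pairwise alignment e-values -- with
    variational graph auto-encoders, concatenating the per-protein latent mean
    vectors, and training one multi-label feed-forward classifier per GO
    namespace. Includes conjoint-triad sequence encoding, bag-of-words
    encodings for subcellular locations and protein domains, evidence-code
    filtering and ancestor propagation of GO annotations, CAFA-style
    evaluation (F-max, macro- and micro-averaged AUPR), a best-BLAST-hit
    annotation transfer baseline with homolog removal, and a seed-reproducible
    synthetic data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
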