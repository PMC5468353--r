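Package: wsmd
Title: Weakly-Supervised Discriminative Motif Discovery from ChIP-Seq Sequence Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns position weight matrices (PWMs) that discriminate foreground
    sequences (e.g. ChIP-seq peaks) from background sequences by minimizing an
    L2-regularized hinge surrogate of the sequence-level classification error.
    The motif is treated as a linear classifier over one-hot encoded sequence
    windows and trained as a latent support vector machine by alternating
    latent binding-site updates with exact soft-margin quadratic programming
    steps solved by a compiled SMO solver. Includes k-mer seeding by substring
    minimal distance, unified and greedy motif extension, masking for
    multi-motif discovery, reference-free evaluation metrics (ROC AUC,
    Fisher's exact test score, minimal hypergeometric enrichment score),
    nucleotide- and site-level accuracy metrics against known site
    annotations, stratified cross-validation, and a synthetic benchmark
    generator that implants signal and decoy motif instances at controlled
    information content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
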