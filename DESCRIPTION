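Package: tRNAidentity
Title: Identity Nucleotides and Binding Free Energies of tRNA-Synthetase
    Recognition via Simple Logistic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the recognition of transfer RNAs by their
    aminoacyl-tRNA synthetases. Aligned tRNA strands over the 77 canonical
    positions (-1, 1..76) are one-hot encoded into Boolean position-by-
    nucleoside attributes and classified into amino-acid-load classes with a
    from-scratch multiclass simple-logistic (LogitBoost) learner that selects
    a sparse set of attributes per class. The fitted linear predictors are
    mapped onto Gibbs free energies of binding (in units of kT), decomposed
    into nucleotide-independent forward and nucleotide-dependent reverse
    parts with an anticodon-tandem split, and summarised per class.
    Downstream analyses extract per-class identity nucleotides, occurrence
    and coverage statistics, consensus strands, consensus agreement,
    universal class markers and unique ensembles. A configurable synthetic
    alignment generator with planted identity nucleotides makes the whole
    pipeline testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), nnet, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
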