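Package: nologo
Title: Variable-Spacer Probabilistic Modelling of Nuclear Export Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative probabilistic modelling of Crm1-dependent nuclear
    export signals (NESs) and other short variable-length protein motifs.
    Implements a mixture model over spacer configurations in which four
    hydrophobic anchor residues share one residue distribution and the
    variable-length spacers between them share another, so that motifs of
    length 7 to 13 residues are scored under a single 44-parameter model.
    Provides supervised parameter estimation from annotated alignments,
    unsupervised expectation-maximization from unaligned windows,
    log-likelihood-ratio scanning of protein sequences, posterior decoding
    of spacer configurations, start positions and per-residue hydrophobic
    anchor probabilities, a fixed-length PSSM baseline, an overlap-based
    ROC evaluation harness, and a generative simulator for planted-motif
    proteomes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
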