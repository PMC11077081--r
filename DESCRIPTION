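Package: switchjoin
Title: Repair-Pathway Analysis of Class Switch Recombination Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dissects how class switch recombination (CSR) junctions were
    repaired. Provides a deterministic split-alignment caller that locates
    the donor/acceptor breakpoint in Sanger-scale switch-junction reads and
    measures blunt joins, microhomology, and insertions; a classifier that
    assigns each junction to classical non-homologous end joining (C-NHEJ)
    or alternative end joining (A-EJ) and detects ectopic capture of
    chromosomal sequences (ECS); cohort summaries with two-tailed exact
    contingency tests; the restriction-protection qPCR calculus for
    single-stranded DNA resection (ssDNA%), relative expression (delta-Cq),
    and ChIP percent-input; and a synthetic-data generator that builds
    switch-like repetitive references, junction cohorts with exact ground
    truth, decoy genomes, and noisy Cq panels so the whole pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
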