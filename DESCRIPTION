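Package: nucpioneer
Title: Nucleosome Dyad Profiling and Tandem GAT Motif Geometry at
    Pioneer-Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the interplay between the pioneer
    transcription factor GATA3 and nucleosomes. Builds motif-anchored
    nucleosome dyad-frequency profiles from MNase fragment midpoints with
    sonicated-control normalization, scans peak windows for tandem
    5'-GAT-3' trinucleotide pairs across spacers and strand orientations
    with analytic and Monte Carlo nulls, models nucleosome superhelical
    location and rotational setting to classify motif solvent
    accessibility, and designs Widom-601-style nucleosome constructs.
    Includes a seeded synthetic-data generator emulating the class-specific
    dyad and motif-spacing structure of GATA3-bound loci so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
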