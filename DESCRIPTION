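Package: nuptscan
Title: Detection and Characterization of Plastid DNA Insertions in Nuclear Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects nuclear insertions of plastid DNA (NUPTs) by aligning a
    plastome against a nuclear assembly with a seed-and-extend local aligner
    (x-drop gapped extension, Karlin-Altschul E-value filtering), bins hits by
    percent identity and length, attributes insertions to exons, introns and
    intergenic space, profiles GC and transposable-element content inside
    insertions and in their flanking windows, and compares NUPT landscapes
    across assembly versions of the same taxon via a bp-per-Mb recovery index.
    Includes a synthetic-genome simulator that implants plastome fragments of
    controlled identity, length and placement, with matching gene and TE
    annotations and a ground-truth table, so the whole pipeline is testable
    without external data. Mitogenome queries (NUMTs) are supported generically.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
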