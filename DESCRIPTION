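Package: kmertag
Title: Content-Derived Stable Gene Identifiers from Representative k-mers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns stable, content-derived identifiers (UniqTags) to
    annotated genes. Each gene is labelled by the lexicographically minimal
    k-mer among the k-mers of its sequence that occur in the fewest genes of
    the catalog, with a numeric suffix disambiguating collisions. Because the
    identifier is derived from sequence content alone, it survives
    re-assembly and re-annotation of the same data without alignment-based
    lift-over. Includes Ensembl-style peptide FASTA handling with
    representative-protein selection, build-vs-build stability reports
    (common identifiers, common accessions, identical sequences, k-sweeps),
    a seeded synthetic mutation generator emulating successive annotation
    builds, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
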