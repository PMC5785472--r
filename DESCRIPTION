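Package: pksline
Title: Genome Mining of Type I Modular Polyketide Synthase Assembly Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signature-based annotation of type I modular polyketide
    synthase (PKS) catalytic domains, collinear assembly-line construction
    across multi-protein gene clusters, polyketide backbone and
    monoisotopic mass prediction, and auditing of the collinearity rule
    against a target product. When an assembly line falls short of the
    module count a product demands, the package searches the genome for
    stand-alone trans-acting module candidates and exhaustively enumerates
    programmed-iteration hypotheses in which one module catalyses two
    successive chain extensions with different reductive outcomes. Also
    computes biosynthetic gene cluster (BGC) landscape statistics from
    antiSMASH-style cluster coordinate tables, and ships a synthetic-data
    generator that emits PKS fixtures with embedded ground truth for
    testing. Readers for GenBank flat files, protein FASTA and TSV cluster
    tables are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
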