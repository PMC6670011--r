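Package: amplicall
Title: Low-Frequency Somatic Variant Calling for Custom Amplicon
    Sequencing of Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for detecting low-frequency somatic
    mutations in cell-free DNA sequenced with custom multiplex amplicon
    panels. Reads are quality-trimmed and assigned to panel amplicons,
    per-position base counts are converted to allele frequencies, and a
    per-amplicon robust linear model of logit allele frequencies separates
    true mutations from PCR and sequencing noise. Calls are annotated
    against a somatic-mutation catalogue and tracked longitudinally across
    serial patient samples. A synthetic-data module simulates count tables,
    FASTQ reads, two-genotype dilution series and serial-sample cohorts
    with the error structure the noise model assumes, so every stage can
    be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    IRanges,
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
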