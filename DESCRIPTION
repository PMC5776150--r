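Package: taxkmer
Title: Taxon-Specific k-mer Discovery and Alignment-Free Detection in
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers taxon-specific k-mers from panels of assembled
    genomes (designed around chloroplast genome panels) and detects them
    directly in raw sequencing reads without alignment, mapping or
    assembly.  Provides exact canonical k-mer counting from FASTA/FASTQ,
    a sorted k-mer list file format, set algebra over k-mer lists with a
    minimum-presence (universality) threshold, the end-to-end specific
    k-mer selection pipeline with two-step removal of non-specific
    k-mers, read-set detection with frequency cutoffs, deterministic
    every-Nth-read FASTQ subsampling, localization of a k-mer panel as
    clustered regions on a reference genome, and a synthetic
    plastome-panel simulator with an exhaustive ground-truth oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
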