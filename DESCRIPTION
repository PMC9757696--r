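Package: targetasm
Title: Reference-Guided Recovery of Target Genes from High-Throughput
    Sequencing Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers target nuclear genes (Angiosperms353-style loci) from
    genome skimming, RNA-seq, or target-enrichment reads. Reads are binned
    per gene by exact k-mer sharing against a reference hash table, then each
    bin is assembled on a weighted de Bruijn graph in which extension
    candidates are scored by abundance discounted by their positional
    consistency with the reference (W = count^(1 - pos)). Includes a
    paired-end Illumina-like read simulator with per-base substitution
    errors, and recovery evaluation statistics: the T50 gene count and
    alignment-based base-calling and indel error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
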