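Package: tandemfill
Title: Reference-Guided Local Reassembly of Long Tandem Repeat Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reassembles long tandem-repeat regions (centromeric satellite
    arrays, subtelomeric repeats) in draft genome assemblies from PacBio HiFi
    and Hi-C data, guided by a high-quality reference genome of the same
    species. Reads belonging to the target region are recruited by partial
    alignment plus a rare-k-mer hypothesis test; contigs are generated from a
    unitig graph by support-aware traversal; contig positions on the
    reference are selected with a genetic algorithm over chained-alignment
    scores; diploid contigs are phased with a restart hill-climbing search
    over Hi-C, HiFi and homology signals. Also provides assembly
    completeness and correctness metrics, higher-order-repeat (HOR)
    detection and monomer-level population analyses, and a deterministic
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
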