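Package: symrad
Title: Dual-Genome ddRAD-Seq Analysis of a Fish Host and Its Luminous
    Bacterial Symbiont
Version: 0.1.0
Authors@R:
    person("symrad", "developers", email = "symrad@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for double-digest RAD-Seq
    libraries prepared from whole light organs, in which reads from a
    diploid fish host and its intracellular population of luminous
    bacterial symbionts are sequenced together.  Provides an in-silico
    restriction digest read simulator with full truth tables, read
    demultiplexing, quality filtering and host/symbiont partitioning, a
    Stacks-style locus and haplotype caller with the associated
    missing-data filter cascade, distance-based population statistics
    (Bray-Curtis, PCoA, PERMANOVA, Mantel, Weir-Cockerham F_ST) with
    permutation engines implemented from first principles, constrained
    ordination (db-RDA/CAP) outlier-haplotype discovery, and a simplified
    variant-effect annotator for outlier loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
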