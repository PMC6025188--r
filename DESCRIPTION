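Package: isopir
Title: Detection, Classification and Annotation of piRNA Isoforms from
    Small RNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects PIWI-interacting RNA (piRNA) isoforms in collapsed
    small RNA sequencing libraries by ungapped matching of read tags
    against a registry of canonical piRNAs with at most one internal
    mismatch, classifies 5' and 3' end variation as templated extension
    (NE), non-templated addition (NA) or trimming (TR) against the 15 nt
    genomic flanks of each locus, quantifies isoforms as reads per
    million (RPM) with cumulative and divided cross-sample summaries,
    annotates loci by genome origin (repeat, coding gene, H3K9me3,
    intergenic unannotated), and predicts piRNA-mRNA target sites with
    rule-based duplex pairing followed by hypergeometric enrichment
    testing with Bonferroni correction. Includes a seeded synthetic
    fixture generator producing ground-truthed genomes, canonical sets,
    read libraries, transcripts and term maps, and a pipeline runner
    with a command line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
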