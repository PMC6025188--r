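# isopir

Detection, classification, quantification and target analysis of piRNA
isoforms from small RNA sequencing libraries.

PIWI-interacting RNAs (piRNAs) are 26–31 nt germline small RNAs. Sequencing
libraries contain, alongside each canonical piRNA, a cloud of *isoforms*
that differ at the 5′ or 3′ end — products of imperfect precursor cleavage,
exonucleolytic trimming and non-templated tailing. `isopir` is the
analytical engine for calling and annotating these isoforms: it is aimed at
small-RNA bioinformaticians who have a canonical piRNA registry (piRBase /
piRNABank / NCBI style BED6 + genome) and collapsed read libraries, and
want per-isoform classification, expression, genome-origin annotation and
rule-based mRNA target comparison without a web service in the loop.

## The method

**Detection.** Collapsed tags (unique sequence + read count) are length
filtered to the window [15, 45] nt, optionally screened against exclusion
sets (miRNA, circRNA, lncRNA, Rfam, repeats, mRNA — a tag contained in any
of those sequences on either strand is removed), and then matched ungapped
against every canonical piRNA allowing **at most one internal mismatch**
within the canonical body, with a minimum body overlap of 14 nt. Matching
tags are isoforms; tags identical to a canonical sequence are reported
separately as canonical expression.

**Classification.** Each locus stores 15 nt of genomic flank per side.
Per end, an isoform is

| label | meaning |
|-------|---------|
| 5NE / 3NE | longer than canonical; extension matches the genomic flank (templated) |
| 5NA / 3NA | longer than canonical; at least one added nucleotide is non-genomic |
| 5TR / 3TR | shorter than canonical (trimmed) |
| SUB | same ends, one internal substitution |

A single isoform can carry one 5′ and one 3′ label simultaneously
(e.g. `5NE,3TR`).

**Quantification.** Per sample, `RPM = N_isoform / N_all × 1e6` with
`N_all` the sample's total mapped reads; across samples, `Cumulative RPM =
Σ RPM_i` and `Divided RPM = Σ RPM_i / n` over the n samples in which the
isoform was detected.

**Genome origin.** Loci are intersected with repeat (Dfam-style), coding
gene and H3K9me3 peak tracks; a locus overlapping none of repeat/coding is
`intergenic_unannotated`. H3K9me3 is an additive flag.

**Target analysis.** piRNAs with the 1U/10A bias are scanned antisense
against transcripts: a site requires (i) a continuous Watson–Crick run of
≥ 16 nt starting at piRNA position 2, and (ii) ≤ 3 mismatches within the
20 nt window of positions 2–21. Site counts of 2–6 selected isoforms are
compared per transcript (`delta` ≥ 1 = isoform-affected target), and
affected targets are tested for term over-representation with the
hypergeometric (one-sided Fisher) test, fold enrichment `(k/n)/(K/N)`, and
Bonferroni correction.

A seeded synthetic-fixture generator (`simulate_fixture()`) produces a
genome, canonical registry, read libraries with known planted isoform
classes, transcripts with planted/decoy target sites and a term map, so
the entire pipeline is testable with known ground truth.

## Worked example

```r
library(isopir)
m <- simulate_fixture(tempfile(), seed = 42, n_canonicals = 50, depth = 10000)
res <- run_pipeline(list(genome = m$genome, canonical = m$canonical,
                         reads = as.list(m$reads),
                         sample_sheet = m$sample_sheet,
                         tracks = m$tracks), "out")
cat(res$log, sep = "\n")
#> loaded genome: 1 contig(s), 6000 nt
#> loaded 50 canonical piRNAs
#> loaded 800 tag records (20000 reads) from 2 sample(s)
#> length filter [15,45]: kept 800, rejected 0
#> no exclusion sets supplied; exclusion stage skipped
#> matching: 350 isoform calls, 50 canonical-equal tags, 0 unmatched
#> annotation: 31/50 loci intergenic_unannotated
#> built 350 isoform records
```

350 isoform calls: the fixture plants one tag per class for each of the
50 canonicals (7 isoform classes; the 8th class is the unmodified
canonical read, which lands in the canonical-expression bin). The
expression table gives per-sample RPM plus the cross-sample summaries:

```r
head(res$expression[, c("tag_sequence", "canonical_id", "labels",
                        "offset5", "offset3", "rpm_s1", "rpm_s2",
                        "cumulative_rpm", "divided_rpm")], 4)
#>                      tag_sequence canonical_id labels offset5 offset3 rpm_s1
#>     AAAACTCTACCGCGCCCCAAAGAGCCTAT    piR-s0045    5NE      -2       0    700
#>       AAACCTAAGATAAGGGGAGCCCACCAT    piR-s0020    3TR       0      -3   5000
#>   AAACCTAAGATAAGGGGAGCCCACCATGCCA    piR-s0020    3NA       0       1   4400
#>  AAACCTAAGATAAGGGGAGCCCACCATGCCGT    piR-s0020    3NE       0       2   2800
#>  rpm_s2 cumulative_rpm divided_rpm
#>    1200           1900         950
#>    4300           9300        4650
#>    4400           8800        4400
#>    3500           6300        3150
```

`offset3 = 2` with label `3NE` means the tag runs two nucleotides past the
canonical 3′ end and both match the genomic flank; `3TR` with
`offset3 = -3` is a 3 nt 3′ trim. RPM values are exact:
e.g. 5000 = 50 reads / 10 000 mapped × 1e6.

A command line wrapper with subcommands (`load-check`, `detect`,
`quantify`, `annotate`, `targets`, `compare`, `enrich`, `simulate`,
`run`) is installed at `inst/cli/isopir.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/isopir.R", package="isopir"))')" \
    simulate --seed 42 --out fixtures/
```

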