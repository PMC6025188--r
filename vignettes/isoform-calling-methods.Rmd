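---
title: "Calling and annotating piRNA isoforms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and annotating piRNA isoforms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopir)
```

## The problem

A canonical piRNA is a reference sequence with a genomic locus. Small RNA
libraries carry, around each canonical, sequence variants produced during
biogenesis and turnover: 5′/3′ templated extensions from imperfect
precursor cleavage, non-templated 3′ additions (uridylation/adenylation by
nucleotidyl transferases), exonucleolytic trimming, and occasional internal
substitutions. `isopir` calls these isoforms against a canonical registry
and annotates them. This vignette records the model, the parameter
choices, and the design decisions that were genuinely open.

## Detection model

A collapsed tag is matched ungapped against the *context string* of each
canonical: `upstream_flank + body + downstream_flank`, with 15 nt of
genomic flank stored per side in piRNA orientation. For every offset at
which the tag overlaps the body by at least `min_overlap` nucleotides, the
placement is valid when

* body mismatches ≤ 1 (`max_body_mismatch`), and
* any body mismatch is *internal*: not at the first or last tag position.

The terminal-mismatch exclusion is a modelling choice, not a numerical
convenience: a mismatch at the very end of a tag is indistinguishable from
a 1 nt non-templated addition combined with a 1 nt trim, and admitting it
would make the end-variation classes ill-defined. Such tags are still
reachable as isoforms through those end-variation placements when one
exists.

`N` never matches anything — neither in the body nor in a flank — so
ambiguous bases can only produce the single tolerated mismatch or a
non-templated call, never a spurious templated one.

### Per-end classification

With `offset5` = tag start minus canonical start and `offset3` = tag end
minus canonical end (piRNA orientation):

* offset toward the interior → **TR** (trimmed);
* extension with *every* nucleotide matching the flank contiguously
  outward from the body → **NE** (templated extension);
* extension with any non-genomic nucleotide → **NA** (non-templated
  addition). Mixed extensions (a templated run followed by non-genomic
  bases) are NA for the end as a whole — any non-genomic base implies a
  tailing event, the convention used for isomiRs — with the templated run
  length retained in the output (`templated3`/`templated5`);
* both offsets zero with one internal mismatch → **SUB**. The six
  end-variation classes cover only end differences, but a
  single-substitution tag still satisfies the matcher; dropping it would
  silently lose data, so it is reported under this explicit extra label.

Templated extensions are assessed only against the 15 nt stored flank;
a longer extension is non-templated from the 16th nucleotide onward by
definition. Flanks truncated by a contig edge are never N-padded — absent
positions simply cannot match, so edge loci can only yield NA calls on
that side, which is conservative.

### Best placement and ties

Among all valid placements across all canonicals the call keeps the one
with (1) maximal body matches, (2) minimal `|offset5| + |offset3|`,
(3) minimal `|offset5|`, (4) lexicographically smallest canonical id.
Preferring minimal 5′ variation at step (3) encodes the empirical
dominance of 3′ variation in real libraries: when a tag can be explained
either way, the 3′-variant explanation is the likelier one. Ties that
survive steps 1–3 across distinct canonicals (identical or repeated
sequences) set `multi_mapped = TRUE` and all tied ids are reported.

Tags equal to a canonical sequence are never isoforms; they are routed to
a separate canonical-expression table. Together with the unmatched bin,
the three outputs partition the filtered input exactly.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_len`, `max_len` | 15, 45 | nt | tags longer than 14 nt and shorter than 46 nt; strict bounds, configurable |
| `flank` | 15 | nt | genomic flank stored per side; also caps templated extension length |
| `min_overlap` | 14 | nt | minimum tag/body overlap, one below `min_len` so a fully trimmed 15-mer can still anchor |
| `max_body_mismatch` | 1 | — | one internal mismatch |
| `min_run` (targets) | 16 | nt | minimal continuous pairing from piRNA position 2 |
| `max_window_mismatches` | 3 | — | within the 20 nt window, positions 2–21 |
| eligibility | 1U **or** 10A | — | the two biased populations form a union; an AND mode is provided |
| G:U wobble | mismatch | — | plain Watson–Crick pairing; a wobble-as-pair flag is provided |
| Divided RPM `n` | detected samples | — | the sum ranges over samples contributing RPM terms; an all-samples mode is provided |
| annotation overlap | ≥ 1 bp, strand-agnostic | — | least-assuming overlap reading; configurable |

The length bounds are read strictly (14 and 46 excluded). Whether the
window includes its endpoints is genuinely ambiguous in prose form;
both bounds are exposed in `detection_config()` so either reading costs
one argument.

## Target model

Pairing is antisense and anchored at piRNA position 2 — position 1 is
buried in the PIWI protein's 5′ pocket and never required to pair.
`site_start` is the transcript position pairing position 2; the duplex
runs 3′-ward on the piRNA and 5′-ward on the transcript. Rules (i)
(run ≥ 16 from position 2) and (ii) (≤ 3 mismatches in positions 2–21)
are **conjunctive**; a disjunctive mode exists for exploration. The
20 nt window truncates at the 3′ end of piRNAs shorter than 21 nt while
the ≥16 run requirement stays absolute, so piRNAs shorter than 17 nt can
never have sites. The run must start exactly at position 2: a ≥16 run
beginning further 3′ after an early mismatch does not qualify. All
window positions must lie within the transcript.

Enrichment of isoform-affected targets uses the one-sided hypergeometric
upper tail (`k` or more of `n` targets in a term of `K` background genes
out of `N`), fold `(k/n)/(K/N)`, Bonferroni `min(1, p·m)` with `m` the
number of terms tested. The background defaults to all genes in the term
map (the usual over-representation-tool convention); supplying an explicit
measured universe is better practice and supported.

## The synthetic fixture generator

`simulate_fixture()` builds the entire study from one seed: a uniform
random genome, disjoint canonical loci (26–31 nt, full 15 nt flanks,
random strands), one planted tag per (canonical, class), multinomial read
counts, random annotation tracks, transcripts with planted duplexes, and
a term map with one constructed enriched term.

Two constructions make ground truth *identifiable* rather than merely
likely:

* **NA plants** draw every added nucleotide from the 3-letter alphabet
  excluding the flank base at that position. A uniformly random addition
  would be templated by chance with probability ~0.25 per base, so a
  planted "non-templated" label would sometimes be genuinely templated
  and a 100%-recovery test would be impossible by construction, not by
  implementation error.
* **Decoy target sites** pair piRNA positions 2–16 (run 15) and force a
  mismatch at position 17, exercising the run boundary from below.

The default class composition (canonical 10%, 3NE 20%, 3NA 25%, 3TR 25%,
5NE 5%, 5NA 5%, 5TR 6%, SUB 4%) gives 3′ classes 70% of the reads,
mirroring the dominance of 3′ variation in real libraries; planted
extensions and trims span 1–3 nt.

What the generator does **not** emulate: sequencing error, PCR duplication
structure, the heavy-tailed abundance distribution of real piRNA loci,
clustered locus geometry (piRNA clusters), ping-pong 10 nt 5′ overlap
signatures, and cross-mapping between near-identical loci. Passing the
planted-recovery tests therefore demonstrates correctness of the
classification logic under identifiable conditions, not robustness to
noisy real data; on real libraries, ambiguous placements (multi-mapping,
chance-templated additions) are expected and are surfaced via
`multi_mapped` and the recorded templated/non-templated split rather than
resolved silently.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open (BED convention) everywhere
  internally; only reports are 1-based. One convention, no off-by-one
  drift.
* Soft-masked genome bases are uppercased on load (masked fraction is
  logged); repeat status comes from the repeat track, not from case.
* `N_all` comes from the sample sheet's `total_mapped`; when absent it
  falls back to the summed tag counts of the sample, and values below the
  summed counts are rejected.
* Empty inputs are valid where they are meaningful (empty BED track,
  empty exclusion list) and fatal where they are not (empty sample,
  empty background, empty target set).
* RPM conservation holds to < 1e-6 relative (plain double summation of
  ≤ 1e6-scale terms; no compensated summation needed at these sizes).
* The pipeline draws no random numbers, so reruns are byte-identical;
  fixture generation is deterministic per seed.

## Problem sizes

The test suite and the acceptance script run the study at: 50 canonical
loci on a 6 kb genome, 8 planted classes, 10 000 reads per sample over
2 samples; 1000 random tag/canonical pairs against the brute-force
placement oracle; 500 random piRNA/transcript pairs against the
per-position site oracle; 1000 random loci against the pairwise overlap
oracle; 200 random contingency tables against direct tail summation and
the exact test. These sizes give well over a thousand non-trivial checks
per oracle while keeping a full run in well under a minute on one core.

## Known limitations

* Ungapped matching only: isoforms arising from internal indels (rare in
  piRNA data) are not modelled and will land in the unmatched bin.
* One internal mismatch maximum; hyper-edited or heavily modified tags
  are not recovered.
* Templated extensions are capped at the stored 15 nt flank.
* Annotation inherits the canonical locus; an isoform whose 3′ extension
  crosses an annotation boundary is not re-annotated.
* Target rules are sequence-only; no duplex thermodynamics, no
  conservation weighting.
* The matcher is exhaustive over a small registry (seconds for hundreds
  of tags × dozens of canonicals; the per-tag cost is linear in registry
  size). For genome-scale registries a seed index would be the natural
  extension.
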