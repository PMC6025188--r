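#' Annotate canonical piRNA loci by genome origin
#'
#' Assigns each locus to the four origin categories by interval
#' intersection: `repeat_element` (overlap with the repeat track),
#' `coding_gene` (overlap with exon/coding-region track), `h3k9me3`
#' (overlap with H3K9me3 peaks — an additive functional flag, a locus can
#' carry it together with either origin class) and
#' `intergenic_unannotated`, assigned exactly when neither repeat nor
#' coding-gene overlap exists. Overlap is strand-agnostic and requires at
#' least `min_overlap_bp` shared base pairs (default 1). Isoforms inherit
#' the annotation of their canonical locus; end variation of a few nt is
#' ignored for annotation purposes.
#'
#' @param canonicals A `canonical_set` (or any data.frame with `id`,
#'   `contig`, `start`, `end` in 0-based half-open coordinates).
#' @param tracks Named list of `interval_track`s; recognised names are
#'   `"repeat"`, `"coding_gene"`, `"h3k9me3"` (any subset; additional
#'   tracks, e.g. piRNA clusters, are reported as extra logical columns).
#' @param min_overlap_bp Minimum overlap in bp for a hit.
#' @return Data.frame with `canonical_id`, one logical column per track
#'   (`repeat` reported as `repeat_element`), `intergenic_unannotated`,
#'   a comma-joined `categories` string, and per-track overlap fractions
#'   (`frac_<track>`: fraction of the locus covered by the track).
#' @export
annotate_loci <- function(canonicals, tracks = list(), min_overlap_bp = 1L) {
  n <- nrow(canonicals)
  loci <- GenomicRanges::GRanges(
    seqnames = canonicals$contig,
    ranges = IRanges::IRanges(start = canonicals$start + 1L,
                              end = canonicals$end))
  track_names <- names(tracks)
  flags <- list()
  fracs <- list()
  for (nm in track_names) {
    tr <- tracks[[nm]]
    if (!nrow(tr)) {
      flags[[nm]] <- rep(FALSE, n)
      fracs[[nm]] <- rep(0, n)
      next
    }
    gr <- GenomicRanges::GRanges(
      seqnames = tr$contig,
      ranges = IRanges::IRanges(start = tr$start + 1L, end = tr$end))
    suppressWarnings({
      hits <- GenomicRanges::findOverlaps(loci, gr,
                                          minoverlap = min_overlap_bp,
                                          ignore.strand = TRUE)
      flags[[nm]] <- seq_len(n) %in% S4Vectors::queryHits(hits)
      cov <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
      ch <- GenomicRanges::findOverlaps(loci, cov, ignore.strand = TRUE)
    })
    ov <- IRanges::pintersect(IRanges::ranges(loci)[S4Vectors::queryHits(ch)],
                              IRanges::ranges(cov)[S4Vectors::subjectHits(ch)])
    covered <- rep(0, n)
    if (length(ch)) {
      agg <- tapply(IRanges::width(ov), S4Vectors::queryHits(ch), sum)
      covered[as.integer(names(agg))] <- as.numeric(agg)
    }
    fracs[[nm]] <- covered / (canonicals$end - canonicals$start)
  }
  has_repeat <- if ("repeat" %in% track_names) flags[["repeat"]]
                else rep(FALSE, n)
  has_coding <- if ("coding_gene" %in% track_names) flags[["coding_gene"]]
                else rep(FALSE, n)
  intergenic <- !has_repeat & !has_coding
  out <- data.frame(canonical_id = canonicals$id,
                    stringsAsFactors = FALSE)
  for (nm in track_names) {
    col <- if (nm == "repeat") "repeat_element" else nm
    out[[col]] <- flags[[nm]]
  }
  out$intergenic_unannotated <- intergenic
  out$categories <- vapply(seq_len(n), function(i) {
    cats <- character(0)
    if (has_repeat[i]) cats <- c(cats, "repeat")
    if (has_coding[i]) cats <- c(cats, "coding_gene")
    if ("h3k9me3" %in% track_names && flags[["h3k9me3"]][i])
      cats <- c(cats, "h3k9me3")
    if (intergenic[i]) cats <- c(cats, "intergenic_unannotated")
    paste(cats, collapse = ",")
  }, character(1))
  for (nm in track_names) {
    col <- if (nm == "repeat") "repeat_element" else nm
    out[[paste0("frac_", col)]] <- fracs[[nm]]
  }
  out
}

#' Annotate a single locus
#'
#' Convenience wrapper around [annotate_loci()] for one canonical piRNA.
#'
#' @param canonical One row of a `canonical_set`.
#' @param tracks Named list of `interval_track`s.
#' @param min_overlap_bp Minimum overlap in bp.
#' @return One-row annotation data.frame.
#' @export
annotate_locus <- function(canonical, tracks = list(), min_overlap_bp = 1L) {
  annotate_loci(canonical, tracks, min_overlap_bp)
}
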