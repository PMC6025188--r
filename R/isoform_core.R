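#' Detection configuration
#'
#' Parameters of the isoform detection cascade. The length window defaults
#' to \[15, 45\] nt (tags longer than 14 nt and shorter than 46 nt), the
#' stored genomic flank to 15 nt, the minimum ungapped overlap with the
#' canonical body to 14 nt, and at most one internal body mismatch is
#' tolerated; mismatches at the first or last tag position are never
#' accepted (a terminal mismatch is indistinguishable from a 1 nt
#' addition plus 1 nt trim, so it is excluded from the body-match model).
#'
#' @param min_len,max_len Inclusive tag length window in nt.
#' @param flank Genomic flank stored per side of each canonical locus.
#' @param min_overlap Minimum tag/body overlap in nt.
#' @param max_body_mismatch Maximum internal mismatches within the body.
#' @return A `detection_config` list.
#' @export
detection_config <- function(min_len = 15L, max_len = 45L, flank = 15L,
                             min_overlap = 14L, max_body_mismatch = 1L) {
  stopifnot(min_len <= max_len, min_overlap <= min_len, flank >= 0L,
            max_body_mismatch >= 0L)
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 flank = as.integer(flank),
                 min_overlap = as.integer(min_overlap),
                 max_body_mismatch = as.integer(max_body_mismatch)),
            class = "detection_config")
}

#' Length-filter read tags
#'
#' Partitions tags into those within the configured length window and
#' those outside it. The partition is exhaustive and disjoint.
#'
#' @param tags Tag data.frame (`sequence`, `sample_id`, `count`).
#' @param cfg A [detection_config()].
#' @return List with elements `kept` and `rejected`.
#' @export
apply_length_filter <- function(tags, cfg = detection_config()) {
  len <- nchar(tags$sequence)
  keep <- len >= cfg$min_len & len <= cfg$max_len
  list(kept = tags[keep, , drop = FALSE],
       rejected = tags[!keep, , drop = FALSE])
}

#' Exclude tags matching other ncRNA classes
#'
#' A tag is excluded when its full sequence occurs as an exact substring of
#' any sequence in an exclusion set, on either strand. Sets are checked in
#' the order given; the first matching set names the exclusion reason.
#' Typical sets: precursor/mature miRNA, circRNA, lncRNA, Rfam, repeats,
#' mRNA.
#'
#' @param tags Tag data.frame (`sequence`, `sample_id`, `count`).
#' @param exclusion_sets Named list of character vectors of sequences
#'   (may be empty or NULL).
#' @return List with `kept` (tag data.frame) and `excluded` (tag
#'   data.frame with an extra `reason` column).
#' @export
exclusion_filter <- function(tags, exclusion_sets = NULL) {
  if (is.null(exclusion_sets) || !length(exclusion_sets)) {
    ex <- tags[0, , drop = FALSE]
    ex$reason <- character(0)
    return(list(kept = tags, excluded = ex))
  }
  if (is.null(names(exclusion_sets)) || any(!nzchar(names(exclusion_sets))))
    stop("exclusion sets must be named", call. = FALSE)
  uniq <- unique(tags$sequence)
  reason <- rep(NA_character_, length(uniq))
  for (nm in names(exclusion_sets)) {
    seqs <- norm_dna(as.character(exclusion_sets[[nm]]))
    haystack <- paste(c(seqs, dna_revcomp(seqs)), collapse = "#")
    todo <- which(is.na(reason))
    if (!length(todo)) break
    hit <- vapply(uniq[todo], function(s) grepl(s, haystack, fixed = TRUE),
                  logical(1), USE.NAMES = FALSE)
    reason[todo[hit]] <- nm
  }
  tag_reason <- reason[match(tags$sequence, uniq)]
  ex <- tags[!is.na(tag_reason), , drop = FALSE]
  ex$reason <- tag_reason[!is.na(tag_reason)]
  list(kept = tags[is.na(tag_reason), , drop = FALSE], excluded = ex)
}

# Context string and body geometry for one canonical registry row.
canonical_context <- function(canonical) {
  paste0(canonical$upstream_flank, canonical$sequence,
         canonical$downstream_flank)
}

#' Enumerate valid placements of a tag against one canonical piRNA
#'
#' Scans every ungapped offset of the tag against the canonical context
#' (upstream flank + body + downstream flank). A placement is valid iff
#' the overlap with the body is at least `cfg$min_overlap`, body
#' mismatches do not exceed `cfg$max_body_mismatch`, and any body mismatch
#' is internal (not the first or last tag position). `templated5` and
#' `templated3` give the longest contiguous run of extension nucleotides
#' matching the genomic flank outward from the body; extension beyond the
#' stored flank is non-templated by definition. `N` never matches.
#'
#' @param tag A DNA string (one tag sequence).
#' @param canonical One row of a `canonical_set`.
#' @param cfg A [detection_config()].
#' @return Data.frame of placements with columns `offset5`, `offset3`,
#'   `body_matches`, `body_mismatch_pos` (1-based tag position or NA),
#'   `templated5`, `templated3`. Zero rows when no valid placement.
#' @export
enumerate_placements <- function(tag, canonical, cfg = detection_config()) {
  tag <- norm_dna(tag)
  scan_placements_cpp(tag, canonical_context(canonical),
                      nchar(canonical$upstream_flank),
                      nchar(canonical$sequence),
                      cfg$min_overlap, cfg$max_body_mismatch)
}

#' Classify the end variation of a placement
#'
#' Applies the per-end taxonomy: an end where the tag stops short of the
#' canonical is trimmed (`5TR`/`3TR`); an end where the tag extends past
#' the canonical is a templated extension (`5NE`/`3NE`) iff every
#' extension nucleotide matches the genomic flank, otherwise a
#' non-templated addition (`5NA`/`3NA`) — mixed extensions count as NA,
#' with the templated run length retained in the placement. A tag with
#' both offsets zero and a single internal substitution is labelled
#' `SUB`. A tag identical to the canonical carries no label and is not an
#' isoform.
#'
#' @param placement One placement row from [enumerate_placements()].
#' @param tag The tag sequence the placement refers to.
#' @return List with `labels` (character vector, possibly empty),
#'   `variant5`, `variant3` (extension nucleotide strings, `""` when the
#'   end is trimmed or equal).
#' @export
classify_ends <- function(placement, tag) {
  tag <- norm_dna(tag)
  L <- nchar(tag)
  o5 <- placement$offset5; o3 <- placement$offset3
  labels <- character(0)
  variant5 <- ""; variant3 <- ""
  if (o5 > 0) {
    labels <- c(labels, "5TR")
  } else if (o5 < 0) {
    e5 <- -o5
    variant5 <- substr(tag, 1L, e5)
    labels <- c(labels, if (placement$templated5 == e5) "5NE" else "5NA")
  }
  if (o3 < 0) {
    labels <- c(labels, "3TR")
  } else if (o3 > 0) {
    e3 <- o3
    variant3 <- substr(tag, L - e3 + 1L, L)
    labels <- c(labels, if (placement$templated3 == e3) "3NE" else "3NA")
  }
  if (o5 == 0 && o3 == 0) {
    if (!is.na(placement$body_mismatch_pos)) labels <- "SUB"
    # else: identical to canonical; labels stays empty
  }
  list(labels = labels, variant5 = variant5, variant3 = variant3)
}

#' Call piRNA isoforms for a tag library against a canonical registry
#'
#' For every unique tag sequence, finds all valid placements against all
#' canonical piRNAs and keeps the best one: maximal body matches, then
#' minimal total end variation, then minimal 5' variation, then the
#' lexicographically smallest canonical id. Ties across distinct
#' canonicals at the top rank mark the call `multi_mapped` and all tied
#' canonical ids are recorded. Tags whose sequence equals a canonical
#' sequence are routed to a separate canonical-expression bin, not called
#' as isoforms; tags with no valid placement are returned as unmatched.
#' The three bins partition the input exactly.
#'
#' @param tags Tag data.frame (`sequence`, `sample_id`, `count`), already
#'   length-filtered and exclusion-filtered.
#' @param canonicals A `canonical_set`.
#' @param cfg A [detection_config()].
#' @return List with `calls` (one row per isoform: `tag_sequence`,
#'   `canonical_id`, `labels` (comma-joined), `offset5`, `offset3`,
#'   `templated5`, `templated3`, `variant5`, `variant3`, `mismatch_pos`,
#'   `multi_mapped`, `all_canonical_ids`), `canonical_hits` (tags equal
#'   to a canonical sequence, with `canonical_id`), and `unmatched`.
#' @export
call_isoforms <- function(tags, canonicals, cfg = detection_config()) {
  uniq <- unique(tags$sequence)
  contexts <- paste0(canonicals$upstream_flank, canonicals$sequence,
                     canonicals$downstream_flank)
  ulens <- nchar(canonicals$upstream_flank)
  blens <- nchar(canonicals$sequence)
  canon_of_seq <- match(uniq, canonicals$sequence)

  n_u <- length(uniq)
  bin <- character(n_u)
  r_canon <- character(n_u); r_labels <- character(n_u)
  r_off5 <- integer(n_u); r_off3 <- integer(n_u)
  r_t5 <- integer(n_u); r_t3 <- integer(n_u)
  r_var5 <- character(n_u); r_var3 <- character(n_u)
  r_mm <- integer(n_u); r_multi <- logical(n_u)
  r_all <- character(n_u)
  for (k in seq_len(n_u)) {
    s <- uniq[k]
    if (!is.na(canon_of_seq[k])) {
      bin[k] <- "canonical"
      next
    }
    pl <- scan_registry_cpp(s, contexts, ulens, blens,
                            cfg$min_overlap, cfg$max_body_mismatch)
    if (!nrow(pl)) {
      bin[k] <- "unmatched"
      next
    }
    ids <- canonicals$id[pl$canonical_idx]
    a5 <- abs(pl$offset5)
    tot <- a5 + abs(pl$offset3)
    o <- order(-pl$body_matches, tot, a5, ids)
    b <- o[1]
    top <- list(offset5 = pl$offset5[b], offset3 = pl$offset3[b],
                body_mismatch_pos = pl$body_mismatch_pos[b],
                templated5 = pl$templated5[b],
                templated3 = pl$templated3[b])
    # placements tied with the top on every criterion except canonical id
    tied_ids <- sort(unique(ids[pl$body_matches == pl$body_matches[b] &
                                  tot == tot[b] & a5 == a5[b]]))
    cls <- classify_ends(top, s)
    if (!length(cls$labels)) {
      # equal-length perfect duplicate of a canonical body reached through
      # the scanner (possible when sequences repeat in the genome)
      bin[k] <- "canonical"
      canon_of_seq[k] <- pl$canonical_idx[b]
      next
    }
    bin[k] <- "isoform"
    r_canon[k] <- tied_ids[1]
    r_labels[k] <- paste(cls$labels, collapse = ",")
    r_off5[k] <- top$offset5; r_off3[k] <- top$offset3
    r_t5[k] <- top$templated5; r_t3[k] <- top$templated3
    r_var5[k] <- cls$variant5; r_var3[k] <- cls$variant3
    r_mm[k] <- top$body_mismatch_pos
    r_multi[k] <- length(tied_ids) > 1L
    r_all[k] <- paste(tied_ids, collapse = ",")
  }

  iso <- bin == "isoform"
  calls <- data.frame(
    tag_sequence = uniq[iso], canonical_id = r_canon[iso],
    labels = r_labels[iso], offset5 = r_off5[iso], offset3 = r_off3[iso],
    templated5 = r_t5[iso], templated3 = r_t3[iso],
    variant5 = r_var5[iso], variant3 = r_var3[iso],
    mismatch_pos = r_mm[iso], multi_mapped = r_multi[iso],
    all_canonical_ids = r_all[iso], stringsAsFactors = FALSE)
  canonical_hits <- data.frame(
    tag_sequence = uniq[bin == "canonical"],
    canonical_id = canonicals$id[canon_of_seq[bin == "canonical"]],
    stringsAsFactors = FALSE)
  unmatched <- data.frame(tag_sequence = uniq[bin == "unmatched"],
                          stringsAsFactors = FALSE)
  list(calls = calls, canonical_hits = canonical_hits,
       unmatched = unmatched)
}
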