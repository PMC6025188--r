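#' Target-competence eligibility of a piRNA
#'
#' piRNAs with mRNA-targeting potential show strong biases for U at
#' position 1 and A at position 10. Eligibility is `1U OR 10A` by default
#' (the two biased populations form a union); `mode = "both"` requires
#' both. Positions are 1-based on the piRNA; `U` and `T` are equivalent.
#'
#' @param pirna piRNA sequence(s), DNA or RNA alphabet.
#' @param mode `"either"` (default) or `"both"`.
#' @return Logical vector. Sequences shorter than 10 nt are ineligible
#'   (with a warning).
#' @export
is_target_eligible <- function(pirna, mode = c("either", "both")) {
  mode <- match.arg(mode)
  pirna <- norm_dna(pirna)
  short <- nchar(pirna) < 10L
  if (any(short))
    warning("piRNA(s) shorter than 10 nt are never target-eligible")
  p1 <- substr(pirna, 1L, 1L) == "T"
  p10 <- substr(pirna, 10L, 10L) == "A"
  out <- if (mode == "either") p1 | p10 else p1 & p10
  out & !short
}

#' Find piRNA target sites on a transcript
#'
#' Scans every transcript position for an antisense piRNA:mRNA duplex
#' anchored at piRNA position 2 (position 1 is never required to pair).
#' A site qualifies iff both rules hold: (i) the continuous Watson-Crick
#' paired stretch starting at piRNA position 2 is at least `min_run` nt
#' (default 16); and (ii) at most `max_window_mismatches` (default 3)
#' mismatches occur within the 20 nt window of piRNA positions 2-21
#' (truncated at the piRNA 3' end for shorter piRNAs). G:U wobble counts
#' as a mismatch unless `wobble_pairs = TRUE`. piRNAs shorter than
#' `min_run + 1` nt can never have sites.
#'
#' `site_start` is the 0-based transcript position of the nucleotide
#' pairing with piRNA position 2; the duplex runs 3'-ward on the piRNA
#' and 5'-ward on the transcript. All positions required by the mismatch
#' window must lie within the transcript.
#'
#' @param pirna One piRNA sequence.
#' @param transcript One transcript sequence.
#' @param min_run Minimum continuous pairing run from position 2.
#' @param max_window_mismatches Mismatch cap within positions 2-21.
#' @param wobble_pairs Count G:U as a pair instead of a mismatch.
#' @param rule_mode `"and"` (both rules, default) or `"or"`.
#' @return Data.frame with `site_start`, `run_length`,
#'   `window_mismatches`; zero rows when no site. Overlapping sites are
#'   all reported.
#' @export
find_sites <- function(pirna, transcript, min_run = 16L,
                       max_window_mismatches = 3L, wobble_pairs = FALSE,
                       rule_mode = c("and", "or")) {
  rule_mode <- match.arg(rule_mode)
  pirna <- norm_dna(pirna)
  transcript <- norm_dna(transcript)
  L <- nchar(pirna)
  Tn <- nchar(transcript)
  empty <- data.frame(site_start = integer(), run_length = integer(),
                      window_mismatches = integer())
  wmax <- min(21L, L)            # last piRNA position in the window
  if (L < 2L || Tn < wmax - 1L) return(empty)
  pv <- strsplit(pirna, "", fixed = TRUE)[[1]]
  tv <- strsplit(transcript, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "#")  # N never pairs
  pc <- unname(comp[pv])
  # paired[i, s1] : does piRNA position i pair the transcript base at
  # 0-based position (s1 - 1) - (i - 2)?  Build per-position rows over all
  # candidate anchors s (0-based site_start), window positions in bounds.
  s_all <- (wmax - 2L):(Tn - 1L)           # candidate anchors, 0-based
  if (!length(s_all) || s_all[1] < 0L) return(empty)
  imax <- L                                 # run may extend past the window
  keep <- logical(length(s_all))
  run_len <- integer(length(s_all))
  win_mm <- integer(length(s_all))
  # pair matrix rows: piRNA positions 2..L; columns: anchors
  pairm <- matrix(FALSE, nrow = imax - 1L, ncol = length(s_all))
  for (i in 2L:imax) {
    tpos <- s_all - (i - 2L) + 1L          # 1-based transcript index
    inb <- tpos >= 1L & tpos <= Tn
    row <- rep(FALSE, length(s_all))
    row[inb] <- tv[tpos[inb]] == pc[i]
    if (wobble_pairs) {
      wob <- rep(FALSE, length(s_all))
      wob[inb] <- (pv[i] == "G" & tv[tpos[inb]] == "T") |
                  (pv[i] == "T" & tv[tpos[inb]] == "G")
      row <- row | wob
    }
    pairm[i - 1L, ] <- row
  }
  for (k in seq_along(s_all)) {
    col <- pairm[, k]
    r <- 0L
    while (r < length(col) && col[r + 1L]) r <- r + 1L
    run_len[k] <- r
    win_mm[k] <- sum(!col[seq_len(wmax - 1L)])
    ok_run <- r >= min_run
    ok_win <- win_mm[k] <= max_window_mismatches
    keep[k] <- if (rule_mode == "and") ok_run && ok_win else ok_run || ok_win
  }
  data.frame(site_start = s_all[keep], run_length = run_len[keep],
             window_mismatches = win_mm[keep])
}

#' Count target sites of several isoforms across a transcript set
#'
#' For 2 to 6 isoform sequences, counts qualifying sites per transcript
#' and flags transcripts whose counts differ between isoforms
#' (isoform-affected targets — the points off the diagonal in a
#' target-comparison scatter). Ineligible isoforms are scored with zero
#' sites and flagged.
#'
#' @param isoforms Character vector of 2-6 piRNA isoform sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param eligibility_mode Passed to [is_target_eligible()].
#' @param ... Passed to [find_sites()].
#' @return Data.frame with `transcript_id`, one `sites_<i>` column per
#'   isoform, `delta` (max - min count) and `affected` (`delta >= 1`),
#'   sorted by decreasing `delta` then `transcript_id`. The
#'   `ineligible` attribute lists indices of ineligible isoforms.
#' @export
compare_isoform_targets <- function(isoforms, transcripts,
                                    eligibility_mode = "either", ...) {
  if (length(isoforms) < 2L || length(isoforms) > 6L)
    stop("between 2 and 6 isoform sequences are required", call. = FALSE)
  if (is.null(names(transcripts)))
    stop("transcripts must be named", call. = FALSE)
  isoforms <- norm_dna(isoforms)
  elig <- suppressWarnings(is_target_eligible(isoforms,
                                              mode = eligibility_mode))
  counts <- sapply(seq_along(isoforms), function(j) {
    if (!elig[j]) return(rep(0L, length(transcripts)))
    vapply(transcripts, function(tx)
      nrow(find_sites(isoforms[j], tx, ...)), integer(1))
  })
  counts <- matrix(counts, nrow = length(transcripts))
  delta <- apply(counts, 1L, max) - apply(counts, 1L, min)
  out <- data.frame(transcript_id = names(transcripts),
                    stringsAsFactors = FALSE)
  for (j in seq_along(isoforms)) out[[paste0("sites_", j)]] <- counts[, j]
  out$delta <- as.integer(delta)
  out$affected <- delta >= 1L
  out <- out[order(-out$delta, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ineligible") <- which(!elig)
  out
}

#' Over-representation test for target gene sets
#'
#' For each term with at least `min_k` target genes, computes the
#' one-sided hypergeometric upper-tail probability that `k` or more of
#' the `n` tested targets fall into a term of `K` background genes out of
#' `N` total, the fold enrichment `(k/n)/(K/N)`, and the
#' Bonferroni-adjusted p-value `min(1, p * m)` with `m` the number of
#' terms tested.
#'
#' @param target_genes Character vector of target gene ids (the isoform-
#'   affected targets).
#' @param term_map Named list: term id -> character vector of gene ids.
#' @param background Background gene universe; defaults to all genes in
#'   the term map. Target genes outside the background are dropped.
#' @param min_k Minimum target hits for a term to be tested.
#' @return Data.frame sorted by `p` ascending with columns `term_id`,
#'   `k`, `n`, `K`, `N`, `fold`, `p`, `p_bonferroni`.
#' @export
fisher_enrichment <- function(target_genes, term_map, background = NULL,
                              min_k = 1L) {
  if (is.null(background)) background <- unique(unlist(term_map))
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  targets <- unique(intersect(target_genes, background))
  if (!length(targets)) stop("empty target set", call. = FALSE)
  N <- length(background)
  n <- length(targets)
  rows <- lapply(names(term_map), function(term) {
    genes <- intersect(unique(term_map[[term]]), background)
    K <- length(genes)
    k <- length(intersect(targets, genes))
    if (k < min_k) return(NULL)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      p = numeric(), p_bonferroni = numeric()))
  out$p_bonferroni <- p.adjust(out$p, method = "bonferroni")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a term-to-gene map (2-column TSV or GMT)
#'
#' A `.gmt` file (or any file whose rows have a description column and
#' >= 3 fields) is read as GMT: `term <tab> description <tab> gene...`.
#' Otherwise a 2-column TSV `term_id <tab> gene_id` (no header required;
#' a `term_id`/`gene_id` header row is skipped) is expected.
#'
#' @param path Path to the term map file.
#' @return Named list: term id -> character vector of gene ids.
#' @export
read_term_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty term map", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gmt <- grepl("\\.gmt$", path, ignore.case = TRUE) ||
    all(lengths(fields) >= 3L)
  if (gmt) {
    out <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
    names(out) <- vapply(fields, `[`, character(1), 1L)
  } else {
    if (any(lengths(fields) < 2L))
      stop("term map line ", which(lengths(fields) < 2L)[1],
           " has fewer than 2 fields", call. = FALSE)
    term <- vapply(fields, `[`, character(1), 1L)
    gene <- vapply(fields, `[`, character(1), 2L)
    if (term[1] == "term_id" && gene[1] == "gene_id") {
      term <- term[-1]; gene <- gene[-1]
    }
    out <- split(gene, term)
    out <- lapply(out, unique)
  }
  out
}
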