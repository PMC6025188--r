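#' Load a reference genome from FASTA
#'
#' Reads a genome FASTA into an in-memory reference. Sequences are
#' uppercased; the fraction of soft-masked (lowercase) bases per contig is
#' recorded as a statistic but masking is otherwise ignored — repeat status
#' is annotated from interval tracks, not from case. All coordinates in the
#' package are 0-based half-open (BED convention).
#'
#' @param path Path to a FASTA file.
#' @return A `genome_ref` object: list with `contigs` (named character
#'   vector of uppercase sequences) and `masked_fraction` (named numeric).
#' @export
load_genome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate contig name '%s' in %s",
                 nm[duplicated(nm)][1], path), call. = FALSE)
  }
  seqs <- as.character(raw)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for contig '", nm[nchar(seqs) == 0L][1], "'",
         call. = FALSE)
  masked <- vapply(seqs, function(s) {
    n <- nchar(s)
    lengths(regmatches(s, gregexpr("[a-z]", s))) / n
  }, numeric(1), USE.NAMES = FALSE)
  seqs <- toupper(seqs)
  check_alphabet(seqs, what = "contig")
  names(seqs) <- nm
  structure(list(contigs = seqs,
                 masked_fraction = setNames(masked, nm)),
            class = "genome_ref")
}

#' Build a genome reference from in-memory sequences
#'
#' @param contigs Named character vector of uppercase DNA sequences.
#' @return A `genome_ref` object.
#' @export
genome_ref <- function(contigs) {
  stopifnot(!is.null(names(contigs)), !anyDuplicated(names(contigs)),
            all(nchar(contigs) > 0L))
  contigs <- toupper(contigs)
  check_alphabet(contigs, what = "contig")
  structure(list(contigs = contigs,
                 masked_fraction = setNames(numeric(length(contigs)),
                                            names(contigs))),
            class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("genome_ref: %d contig(s), %s nt total\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

# Parse a BED-like TSV with validation; returns a data.frame with at least
# contig/start/end, plus name/score/strand when present.
read_bed <- function(path, min_cols = 3L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(),
                      score = character(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < min_cols))
    stop(sprintf("BED line %d of %s has %d field(s); %d required",
                 which(ncol < min_cols)[1], path,
                 ncol[which(ncol < min_cols)[1]], min_cols), call. = FALSE)
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("non-integer coordinate at BED line %d of %s",
                 which(is.na(start) | is.na(end))[1], path), call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("start >= end at BED line %d of %s", bad[1], path),
         call. = FALSE)
  if (any(start < 0L))
    stop(sprintf("negative start at BED line %d of %s",
                 which(start < 0L)[1], path), call. = FALSE)
  data.frame(contig = get(1), start = start, end = end,
             name = get(4), score = get(5), strand = get(6),
             stringsAsFactors = FALSE)
}

# Extract strand-oriented sequence and <=flank nt flanks for one registry of
# loci from a genome. Core shared by load_canonical_set() and the fixture
# generator. Flanks at contig edges are truncated, never padded.
canonicals_from_intervals <- function(df, genome, flank = 15L) {
  stopifnot(inherits(genome, "genome_ref"), flank >= 0L)
  contigs <- genome$contigs
  unknown <- setdiff(unique(df$contig), names(contigs))
  if (length(unknown))
    stop("unknown contig '", unknown[1], "' in canonical set", call. = FALSE)
  clen <- nchar(contigs)[df$contig]
  if (any(df$end > clen))
    stop(sprintf("interval %s:%d-%d exceeds contig length %d",
                 df$contig[df$end > clen][1],
                 df$start[df$end > clen][1], df$end[df$end > clen][1],
                 clen[df$end > clen][1]), call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for canonical piRNAs", call. = FALSE)
  n <- nrow(df)
  seq <- character(n); up <- character(n); down <- character(n)
  for (i in seq_len(n)) {
    ctg <- contigs[[df$contig[i]]]
    s <- df$start[i]; e <- df$end[i]
    body <- substr(ctg, s + 1L, e)
    left <- substr(ctg, max(0L, s - flank) + 1L, s)        # genomic 5' side
    right <- substr(ctg, e + 1L, min(nchar(ctg), e + flank))
    if (df$strand[i] == "+") {
      seq[i] <- body; up[i] <- left; down[i] <- right
    } else {
      seq[i] <- dna_revcomp(body)
      up[i] <- dna_revcomp(right)
      down[i] <- dna_revcomp(left)
    }
  }
  out <- data.frame(id = df$name, contig = df$contig, start = df$start,
                    end = df$end, strand = df$strand, sequence = seq,
                    upstream_flank = up, downstream_flank = down,
                    short_flank_5 = nchar(up) < flank,
                    short_flank_3 = nchar(down) < flank,
                    stringsAsFactors = FALSE)
  class(out) <- c("canonical_set", "data.frame")
  attr(out, "flank") <- as.integer(flank)
  out
}

#' Load a canonical piRNA registry from BED6
#'
#' Each BED6 record is resolved against the genome: the piRNA sequence is
#' the strand-oriented genome slice, and up to `flank` nt of genomic
#' sequence on each side (in piRNA orientation) are stored as the upstream
#' and downstream flanks used for templated/non-templated classification.
#' Flanks truncated by a contig edge are flagged (`short_flank_5`/`_3`);
#' absent flank positions never match, so they can only yield non-templated
#' calls.
#'
#' @param bed Path to a BED6 file (`chrom start end name score strand`).
#' @param genome A `genome_ref` from [load_genome()].
#' @param flank Flank length in nt stored per side (default 15).
#' @return A `canonical_set` data.frame with columns `id`, `contig`,
#'   `start`, `end`, `strand`, `sequence`, `upstream_flank`,
#'   `downstream_flank`, `short_flank_5`, `short_flank_3`.
#' @export
load_canonical_set <- function(bed, genome, flank = 15L) {
  df <- read_bed(bed, min_cols = 6L)
  if (anyDuplicated(df$name))
    stop("duplicate canonical piRNA id '",
         df$name[duplicated(df$name)][1], "'", call. = FALSE)
  canonicals_from_intervals(df, genome, flank)
}

#' Read a collapsed small RNA FASTA
#'
#' Collapsed libraries encode the read count of each unique sequence in the
#' FASTA header. Two common dialects are supported: `<name>_x<count>`
#' (e.g. `t1_x532`) and `<name>-<count>` (e.g. `t1-532`). By default the
#' dialect is auto-detected from the headers; duplicate sequences are
#' merged by summing counts.
#'
#' @param path Path to the collapsed FASTA.
#' @param sample_id Sample identifier attached to every tag.
#' @param dialect One of `"auto"`, `"underscore_x"`, `"dash"`.
#' @return A data.frame with columns `sequence`, `sample_id`, `count`
#'   (one row per unique sequence).
#' @export
read_collapsed_fasta <- function(path, sample_id,
                                 dialect = c("auto", "underscore_x", "dash")) {
  dialect <- match.arg(dialect)
  fa <- Biostrings::readBStringSet(path)
  headers <- names(fa)
  re_x <- "_x([0-9]+)$"
  re_d <- "-([0-9]+)$"
  if (dialect == "auto") {
    if (all(grepl(re_x, headers))) dialect <- "underscore_x"
    else if (all(grepl(re_d, headers))) dialect <- "dash"
    else {
      bad <- headers[!grepl(re_x, headers) & !grepl(re_d, headers)]
      stop("cannot parse read count from header '",
           if (length(bad)) bad[1] else headers[1],
           "' (expected '<name>_x<count>' or '<name>-<count>')",
           call. = FALSE)
    }
  }
  re <- if (dialect == "underscore_x") re_x else re_d
  m <- regmatches(headers, regexpr(re, headers))
  ok <- grepl(re, headers)
  if (!all(ok))
    stop("cannot parse read count from header '", headers[!ok][1], "'",
         call. = FALSE)
  counts <- as.integer(sub(re, "\\1", m))
  if (any(counts <= 0L))
    stop("non-positive read count in header '",
         headers[counts <= 0L][1], "'", call. = FALSE)
  seqs <- norm_dna(as.character(fa))
  check_alphabet(seqs, what = "read")
  agg <- tapply(counts, seqs, sum)
  out <- data.frame(sequence = names(agg), sample_id = sample_id,
                    count = as.integer(agg), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$sequence), , drop = FALSE]
}

#' Load an annotation interval track from BED3+
#'
#' @param path Path to a BED file (3 or more columns).
#' @param name Track label, e.g. `"repeat"`, `"coding_gene"`, `"h3k9me3"`.
#' @return An `interval_track` data.frame with columns `contig`, `start`,
#'   `end`, `strand` (`"."` when absent). Overlapping intervals are kept
#'   as supplied; no merging.
#' @export
load_bed_track <- function(path, name) {
  df <- read_bed(path, min_cols = 3L)
  interval_track(df$contig, df$start, df$end,
                 ifelse(is.na(df$strand), ".", df$strand), name = name)
}

#' Construct an interval track in memory
#' @param contig,start,end,strand Vectors defining 0-based half-open
#'   intervals; `strand` defaults to `"."`.
#' @param name Track label.
#' @return An `interval_track` data.frame.
#' @export
interval_track <- function(contig, start, end, strand = ".", name) {
  stopifnot(all(start < end), all(start >= 0L))
  out <- data.frame(contig = as.character(contig),
                    start = as.integer(start), end = as.integer(end),
                    strand = rep_len(as.character(strand), length(contig)),
                    stringsAsFactors = FALSE)
  class(out) <- c("interval_track", "data.frame")
  attr(out, "track_name") <- name
  out
}

#' Load a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `species`, `tissue`,
#' `stage`, `genotype`, `sex` and optionally `total_mapped` (the
#' per-sample total mapped read count used as the RPM denominator). When
#' `total_mapped` is absent or NA it is later filled with the sum of tag
#' counts for that sample.
#'
#' @param path Path to the TSV sample sheet.
#' @return A data.frame, one row per sample.
#' @export
load_sample_sheet <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "species", "tissue", "stage", "genotype", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id '",
         df$sample_id[duplicated(df$sample_id)][1], "'", call. = FALSE)
  if (is.null(df$total_mapped)) df$total_mapped <- NA_integer_
  df
}

#' Fill missing total_mapped values from tag counts
#'
#' @param samples Sample sheet data.frame.
#' @param tags Long tag data.frame (`sequence`, `sample_id`, `count`).
#' @return The sample sheet with `total_mapped` completed.
#' @export
complete_totals <- function(samples, tags) {
  sums <- tapply(tags$count, tags$sample_id, sum)
  idx <- is.na(samples$total_mapped)
  samples$total_mapped[idx] <-
    as.integer(sums[samples$sample_id[idx]])
  if (anyNA(samples$total_mapped))
    stop("no reads and no total_mapped for sample '",
         samples$sample_id[is.na(samples$total_mapped)][1], "'",
         call. = FALSE)
  bad <- which(!is.na(sums[samples$sample_id]) &
                 samples$total_mapped < sums[samples$sample_id])
  if (length(bad))
    stop("total_mapped for sample '", samples$sample_id[bad[1]],
         "' is smaller than its summed tag counts", call. = FALSE)
  samples
}

#' Write a canonical set back to BED6
#' @param canonicals A `canonical_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_canonical_bed <- function(canonicals, path) {
  df <- data.frame(canonicals$contig, canonicals$start, canonicals$end,
                   canonicals$id, ".", canonicals$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Write a named character vector as FASTA (used by fixtures and tests).
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
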