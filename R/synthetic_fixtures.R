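#' Generate a random genome
#'
#' Uniform random A/C/G/T contigs, deterministic per seed.
#'
#' @param seed Integer RNG seed.
#' @param n_contigs Number of contigs.
#' @param length Length of each contig in nt (>= 200).
#' @return A `genome_ref`.
#' @export
make_genome <- function(seed, n_contigs = 1L, length = 5000L) {
  stopifnot(length >= 200L)
  set.seed(seed)
  contigs <- setNames(random_dna(n_contigs, length),
                      paste0("chrS", seq_len(n_contigs)))
  genome_ref(contigs)
}

#' Plant non-overlapping canonical piRNA loci in a genome
#'
#' Draws `n` disjoint loci with lengths uniform in `length_range`
#' (canonical piRNAs are 26-31 nt), random strands, at least `min_gap` nt
#' apart and at least `flank` nt from every contig edge, so every locus
#' has full flanks.
#'
#' @param genome A `genome_ref`.
#' @param n Number of loci.
#' @param length_range Length range `c(min, max)` in nt.
#' @param min_gap Minimum gap between loci in nt.
#' @param flank Flank length to reserve at contig edges.
#' @param seed Integer RNG seed.
#' @return A `canonical_set` with ids `piR-s0001`...
#' @export
plant_canonicals <- function(genome, n, length_range = c(26L, 31L),
                             min_gap = 40L, flank = 15L, seed = 1L) {
  set.seed(seed)
  contigs <- genome$contigs
  # sequential packing over concatenated usable space, then shuffled strands
  slots <- list()
  for (ctg in names(contigs)) {
    clen <- nchar(contigs[[ctg]])
    pos <- flank
    while (pos + length_range[2] + flank <= clen) {
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      slots[[length(slots) + 1L]] <- list(contig = ctg, start = pos,
                                          end = pos + len)
      pos <- pos + len + min_gap
    }
  }
  if (length(slots) < n)
    stop(sprintf(paste("cannot place %d non-overlapping loci (room for %d);",
                       "use a longer genome"), n, length(slots)),
         call. = FALSE)
  pick <- sort(sample(length(slots), n))
  df <- do.call(rbind, lapply(slots[pick], as.data.frame))
  df$strand <- sample(c("+", "-"), n, replace = TRUE)
  df$name <- sprintf("piR-s%04d", seq_len(n))
  canonicals_from_intervals(df, genome, flank)
}

#' Default planted class composition
#'
#' 3' classes carry 70% of the mass, mirroring the observation that
#' 3'-end variants dominate real libraries; 10% canonical reads.
#'
#' @return Named numeric vector of class proportions summing to 1.
#' @export
default_composition <- function() {
  c(canonical = 0.10, `3NE` = 0.20, `3NA` = 0.25, `3TR` = 0.25,
    `5NE` = 0.05, `5NA` = 0.05, `5TR` = 0.06, SUB = 0.04)
}

# Build one planted tag of a given class from a canonical registry row.
# A class is either "canonical", "SUB", a single end class (3NE/3NA/3TR/
# 5NE/5NA/5TR) or a both-end combination joined with "+", e.g. "5NE+3TR".
# NA additions draw each nucleotide from the 3-letter alphabet excluding
# the flank base at that position, so a planted NA can never be templated.
build_planted_tag <- function(canon, cls, ext_max = 3L, trim_max = 3L) {
  seq <- canon$sequence
  up <- canon$upstream_flank
  down <- canon$downstream_flank
  not_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  parts <- strsplit(cls, "+", fixed = TRUE)[[1]]
  known5 <- c("5NE", "5NA", "5TR")
  known3 <- c("3NE", "3NA", "3TR")
  if (!all(parts %in% c("canonical", "SUB", known5, known3)) ||
      sum(parts %in% known5) > 1L || sum(parts %in% known3) > 1L ||
      (any(parts %in% c("canonical", "SUB")) && length(parts) > 1L))
    stop("unknown planted class '", cls, "'", call. = FALSE)
  offset5 <- 0L; offset3 <- 0L
  mism <- NA_integer_
  tag <- seq
  # 5' op first, then 3' op: the two touch opposite ends of the tag
  for (p in parts[order(!(parts %in% known5))]) {
    if (p == "canonical") {
      # as is
    } else if (p == "3NE") {
      e <- sample(seq_len(min(ext_max, nchar(down))), 1L)
      tag <- paste0(tag, substr(down, 1L, e))
      offset3 <- e
    } else if (p == "3NA") {
      e <- sample(seq_len(ext_max), 1L)
      add <- vapply(seq_len(e), function(j)
        not_base(substr(down, j, j)), character(1))
      tag <- paste0(tag, paste(add, collapse = ""))
      offset3 <- e
    } else if (p == "3TR") {
      t <- sample(seq_len(trim_max), 1L)
      tag <- substr(tag, 1L, nchar(tag) - t)
      offset3 <- -t
    } else if (p == "5NE") {
      e <- sample(seq_len(min(ext_max, nchar(up))), 1L)
      fl <- nchar(up)
      tag <- paste0(substr(up, fl - e + 1L, fl), tag)
      offset5 <- -e
    } else if (p == "5NA") {
      e <- sample(seq_len(ext_max), 1L)
      fl <- nchar(up)
      add <- vapply(seq_len(e), function(j)
        not_base(substr(up, fl - e + j, fl - e + j)), character(1))
      tag <- paste0(paste(add, collapse = ""), tag)
      offset5 <- -e
    } else if (p == "5TR") {
      t <- sample(seq_len(trim_max), 1L)
      tag <- substr(tag, t + 1L, nchar(tag))
      offset5 <- t
    } else if (p == "SUB") {
      L <- nchar(tag)
      pos <- sample(2L:(L - 1L), 1L)
      old <- substr(tag, pos, pos)
      substr(tag, pos, pos) <- not_base(old)
      mism <- pos
    }
  }
  list(sequence = tag, offset5 = offset5, offset3 = offset3,
       mismatch_pos = mism,
       labels = if (identical(parts, "canonical")) ""
                else paste(parts[order(!(parts %in% known5))],
                           collapse = ","))
}

#' Synthesise collapsed read libraries with a ground-truth manifest
#'
#' Plants one tag per (canonical, class) pair according to `composition`
#' (which must sum to 1 over the classes `canonical`, `3NE`, `3NA`,
#' `3TR`, `5NE`, `5NA`, `5TR`, `SUB`), then distributes `depth` reads per
#' sample over the planted tags by multinomial sampling with
#' probabilities proportional to the class proportions. NE plants copy
#' flank nucleotides; NA plants draw every added nucleotide from the
#' 3-letter alphabet excluding the corresponding flank base, so planted
#' additions are never accidentally templated and every planted label is
#' recoverable. Planted tags that collide with a canonical sequence or
#' with a previously planted tag are redrawn (up to 20 attempts).
#'
#' @param canonicals A `canonical_set` with full flanks.
#' @param composition Named class proportions summing to 1; default
#'   [default_composition()] (3' classes 70%).
#' @param depth Reads per sample.
#' @param n_samples Number of samples (`s1`, `s2`, ...).
#' @param seed Integer RNG seed.
#' @param ext_max,trim_max Maximal planted extension/trim length in nt.
#' @return List with `truth` (data.frame: `sequence`, `canonical_id`,
#'   `labels` (planted class, `""` for canonical reads), `offset5`,
#'   `offset3`, `mismatch_pos`, one `count_<sample>` column per sample)
#'   and `tags` (long data.frame `sequence`/`sample_id`/`count`, zero
#'   counts dropped).
#' @export
synth_reads <- function(canonicals, composition = default_composition(),
                        depth = 10000L, n_samples = 2L, seed = 1L,
                        ext_max = 3L, trim_max = 3L) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition proportions must sum to 1", call. = FALSE)
  if (any(composition < 0))
    stop("composition proportions must be non-negative", call. = FALSE)
  set.seed(seed)
  classes <- names(composition)[composition > 0]
  planted <- list()
  seen <- canonicals$sequence
  for (i in seq_len(nrow(canonicals))) {
    canon <- canonicals[i, ]
    for (cls in classes) {
      for (attempt in 1:20) {
        p <- build_planted_tag(canon, cls, ext_max, trim_max)
        if (cls == "canonical" || !(p$sequence %in% seen)) break
        if (attempt == 20L)
          stop("could not plant a unique tag for ", canon$id, " class ",
               cls, call. = FALSE)
      }
      if (cls != "canonical") seen <- c(seen, p$sequence)
      planted[[length(planted) + 1L]] <- data.frame(
        sequence = p$sequence, canonical_id = canon$id,
        labels = p$labels, offset5 = p$offset5, offset3 = p$offset3,
        mismatch_pos = p$mismatch_pos, class_prob = composition[[cls]],
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, planted)
  prob <- truth$class_prob / sum(truth$class_prob)
  samples <- paste0("s", seq_len(n_samples))
  counts <- rmultinom(n_samples, depth, prob)
  colnames(counts) <- samples
  truth$class_prob <- NULL
  for (s in samples) truth[[paste0("count_", s)]] <- counts[, s]
  tag_rows <- lapply(samples, function(s) {
    cnt <- counts[, s]
    keep <- cnt > 0L
    data.frame(sequence = truth$sequence[keep], sample_id = s,
               count = as.integer(cnt[keep]), stringsAsFactors = FALSE)
  })
  list(truth = truth, tags = do.call(rbind, tag_rows))
}

#' Plant target sites in synthetic transcripts
#'
#' Generates random transcripts and embeds, for each planted site, the
#' reverse complement of piRNA positions 2..min(21, L) — a perfect duplex
#' with pairing run `min(20, L - 1)` and zero window mismatches. Decoy
#' transcripts carry near-miss sites: the duplex pairs only at piRNA
#' positions 2..16 (run 15) and is forced to mismatch at position 17, so
#' rule (i) fails and the site must not be called.
#'
#' @param isoform_seqs Character vector of eligible piRNA sequences
#'   (length >= 21 nt recommended).
#' @param n_transcripts Number of transcripts carrying one planted site
#'   each (isoforms assigned round-robin).
#' @param tx_length Transcript length in nt.
#' @param n_decoys Number of decoy transcripts with a run-15 near-miss.
#' @param seed Integer RNG seed.
#' @return List with `transcripts` (named character vector,
#'   `tx0001`...) and `registry` (data.frame: `transcript_id`,
#'   `isoform`, `site_start`, `kind` = planted/decoy).
#' @export
plant_targets <- function(isoform_seqs, n_transcripts = 20L,
                          tx_length = 300L, n_decoys = 10L, seed = 1L) {
  set.seed(seed)
  isoform_seqs <- norm_dna(isoform_seqs)
  stopifnot(all(nchar(isoform_seqs) >= 18L), tx_length >= 60L)
  base4 <- c("A", "C", "G", "T")
  txs <- character(0)
  reg <- list()
  embed <- function(tx, insert, at) {
    # at: 1-based position of the insert's first base
    paste0(substr(tx, 1L, at - 1L), insert,
           substr(tx, at + nchar(insert), nchar(tx)))
  }
  n_all <- n_transcripts + n_decoys
  for (t in seq_len(n_all)) {
    id <- sprintf("tx%04d", t)
    pir <- isoform_seqs[(t - 1L) %% length(isoform_seqs) + 1L]
    L <- nchar(pir)
    tx <- random_dna(1L, tx_length)
    if (t <= n_transcripts) {
      w <- min(21L, L)
      insert <- dna_revcomp(substr(pir, 2L, w))      # pairs positions 2..w
      at <- sample(seq(1L, tx_length - nchar(insert) + 1L), 1L)
      tx <- embed(tx, insert, at)
      site_start <- at - 1L + nchar(insert) - 1L     # pairs position 2
      kind <- "planted"
    } else {
      insert <- dna_revcomp(substr(pir, 2L, 16L))    # run 15: positions 2..16
      at <- sample(seq(2L, tx_length - nchar(insert) + 1L), 1L)
      tx <- embed(tx, insert, at)
      site_start <- at - 1L + nchar(insert) - 1L
      # force a mismatch at piRNA position 17 (transcript base just 5' of
      # the insert) and break any chance >=16 run
      p17 <- substr(pir, 17L, 17L)
      comp17 <- dna_comp(p17)
      substr(tx, at - 1L, at - 1L) <-
        sample(setdiff(base4, comp17), 1L)
      kind <- "decoy"
    }
    txs[id] <- tx
    reg[[t]] <- data.frame(transcript_id = id, isoform = pir,
                           site_start = site_start, kind = kind,
                           stringsAsFactors = FALSE)
  }
  list(transcripts = txs, registry = do.call(rbind, reg))
}

#' Build a synthetic term map with one enriched term
#'
#' Random gene universe `g0001...`; `n_terms` random terms of size
#' `term_size`, plus one planted term (`TERM_ENRICHED`) constructed to
#' contain most of the supplied target genes, so over-representation is
#' detectable by construction.
#'
#' @param targets Character vector of target gene ids (subset of the
#'   universe, or new ids which are added to it).
#' @param n_background Universe size.
#' @param n_terms Number of random terms.
#' @param term_size Genes per random term.
#' @param seed Integer RNG seed.
#' @return List with `term_map` (named list) and `background`.
#' @export
make_term_map <- function(targets, n_background = 500L, n_terms = 20L,
                          term_size = 25L, seed = 1L) {
  set.seed(seed)
  background <- unique(c(sprintf("g%04d", seq_len(n_background)), targets))
  term_map <- lapply(seq_len(n_terms), function(i)
    sample(background, term_size))
  names(term_map) <- sprintf("TERM_%04d", seq_len(n_terms))
  n_hit <- max(1L, ceiling(0.8 * length(targets)))
  term_map$TERM_ENRICHED <- unique(c(
    sample(targets, n_hit),
    sample(setdiff(background, targets),
           max(0L, term_size - n_hit))))
  list(term_map = term_map, background = background)
}

#' Write a complete ground-truthed fixture to disk
#'
#' Generates and writes every input the pipeline consumes: genome FASTA,
#' canonical BED6, per-sample collapsed read FASTAs (headers
#' `tag<N>_x<count>`), sample sheet TSV, truth table TSV, annotation
#' track BEDs (repeat / coding_gene / h3k9me3 over random intervals),
#' transcripts FASTA with a planted-site registry TSV, and a term map
#' TSV. Byte-identical across runs with the same seed.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer RNG seed driving every stage.
#' @param n_canonicals Number of canonical loci.
#' @param genome_length Genome contig length in nt.
#' @param depth Reads per sample.
#' @param n_samples Number of samples.
#' @param composition Planted class composition.
#' @return Invisibly, a manifest list of all paths plus the in-memory
#'   truth objects.
#' @export
simulate_fixture <- function(dir, seed = 42L, n_canonicals = 50L,
                             genome_length = 6000L, depth = 10000L,
                             n_samples = 2L,
                             composition = default_composition()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(seed, n_contigs = 1L, length = genome_length)
  canonicals <- plant_canonicals(genome, n_canonicals, seed = seed + 1L)
  reads <- synth_reads(canonicals, composition, depth = depth,
                       n_samples = n_samples, seed = seed + 2L)

  genome_fa <- file.path(dir, "genome.fa")
  write_fasta(genome$contigs, genome_fa)
  canonical_bed <- file.path(dir, "canonical.bed")
  write_canonical_bed(canonicals, canonical_bed)

  samples <- paste0("s", seq_len(n_samples))
  read_paths <- character(0)
  for (s in samples) {
    sub <- reads$tags[reads$tags$sample_id == s, , drop = FALSE]
    seqs <- setNames(sub$sequence,
                     sprintf("tag%05d_x%d", seq_len(nrow(sub)), sub$count))
    p <- file.path(dir, paste0("reads_", s, ".fa"))
    write_fasta(seqs, p)
    read_paths[s] <- p
  }
  sheet <- data.frame(sample_id = samples, species = "synthetic",
                      tissue = "testis", stage = "adult",
                      genotype = "WT",
                      sex = rep_len(c("M", "F"), n_samples),
                      total_mapped = as.integer(
                        tapply(reads$tags$count, reads$tags$sample_id,
                               sum)[samples]))
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(reads$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  # annotation tracks: random intervals + guaranteed hits on a few loci
  set.seed(seed + 3L)
  clen <- nchar(genome$contigs[[1]])
  ctg <- names(genome$contigs)[1]
  rnd_track <- function(n, width) {
    st <- sort(sample(seq(0L, clen - width), n))
    interval_track(rep(ctg, n), st, st + width, name = "t")
  }
  tracks <- list(
    "repeat" = rnd_track(8L, 120L),
    coding_gene = rnd_track(8L, 200L),
    h3k9me3 = rnd_track(6L, 150L))
  track_paths <- list()
  for (nm in names(tracks)) {
    p <- file.path(dir, paste0("track_", gsub("\\W", "_", nm), ".bed"))
    write.table(tracks[[nm]][, c("contig", "start", "end")], p,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    track_paths[[nm]] <- p
  }

  # transcripts with planted sites for eligible planted isoforms
  elig_idx <- which(suppressWarnings(
    is_target_eligible(canonicals$sequence)))
  target_fix <- NULL
  tx_path <- NULL; sites_path <- NULL
  if (length(elig_idx)) {
    target_fix <- plant_targets(canonicals$sequence[elig_idx][1:min(4, length(elig_idx))],
                                n_transcripts = 12L, tx_length = 300L,
                                n_decoys = 6L, seed = seed + 4L)
    tx_path <- file.path(dir, "transcripts.fa")
    write_fasta(target_fix$transcripts, tx_path)
    sites_path <- file.path(dir, "sites_truth.tsv")
    write.table(target_fix$registry, sites_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # term map over synthetic gene ids
  tm <- make_term_map(sprintf("g%04d", 1:40), seed = seed + 5L)
  terms_path <- file.path(dir, "terms.tsv")
  rows <- data.frame(
    term_id = rep(names(tm$term_map), lengths(tm$term_map)),
    gene_id = unlist(tm$term_map, use.names = FALSE))
  write.table(rows, terms_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(
    seed = seed, dir = dir, genome = genome_fa,
    canonical = canonical_bed, reads = read_paths,
    sample_sheet = sheet_path, truth = truth_path,
    tracks = track_paths, transcripts = tx_path,
    sites_truth = sites_path, term_map = terms_path,
    truth_df = reads$truth, canonicals = canonicals,
    target_registry = if (!is.null(target_fix)) target_fix$registry))
}
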