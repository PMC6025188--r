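#' Run the full isoform pipeline
#'
#' Wires the stages in fixed order: load inputs, length filter, exclusion
#' filter, canonical matching and end classification, quantification,
#' genome annotation, and the merged per-isoform record. Missing optional
#' inputs (exclusion sets, annotation tracks, transcripts, term map) skip
#' their stage with a logged notice. The pipeline is deterministic: no
#' stage draws random numbers, so reruns on the same inputs are
#' byte-identical.
#'
#' @param config Either a path to a YAML config file or a list with keys
#'   `genome`, `canonical`, `reads` (named list/vector `sample_id ->
#'   collapsed FASTA path`), `sample_sheet`, and optionally `exclude`
#'   (named list `set_name -> FASTA path`), `tracks` (named list
#'   `track_name -> BED path`; names among `repeat`, `coding_gene`,
#'   `h3k9me3` or custom), and `params` (any of `min_len`, `max_len`,
#'   `flank`, `min_overlap`, `max_body_mismatch`, `n_mode`).
#' @param out_dir Output directory for the stage TSVs and `pipeline.log`.
#' @return Invisibly, a list with the stage outputs (`calls`,
#'   `canonical_hits`, `unmatched`, `expression`, `annotation`,
#'   `records`, `samples`, `log`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  need <- c("genome", "canonical", "reads", "sample_sheet")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logs <- character(0)
  note <- function(...) {
    logs <<- c(logs, sprintf(...))
  }

  params <- config$params
  cfg <- detection_config(
    min_len = params$min_len %||% 15L,
    max_len = params$max_len %||% 45L,
    flank = params$flank %||% 15L,
    min_overlap = params$min_overlap %||% 14L,
    max_body_mismatch = params$max_body_mismatch %||% 1L)
  n_mode <- params$n_mode %||% "detected"

  genome <- load_genome(config$genome)
  note("loaded genome: %d contig(s), %d nt", length(genome$contigs),
       sum(nchar(genome$contigs)))
  canonicals <- load_canonical_set(config$canonical, genome,
                                   flank = cfg$flank)
  note("loaded %d canonical piRNAs", nrow(canonicals))
  reads <- config$reads
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("config$reads must map sample ids to FASTA paths", call. = FALSE)
  tags <- do.call(rbind, lapply(names(reads), function(s)
    read_collapsed_fasta(reads[[s]], s)))
  note("loaded %d tag records (%d reads) from %d sample(s)",
       nrow(tags), sum(tags$count), length(reads))
  samples <- load_sample_sheet(config$sample_sheet)
  samples <- complete_totals(samples, tags)

  lf <- apply_length_filter(tags, cfg)
  note("length filter [%d,%d]: kept %d, rejected %d", cfg$min_len,
       cfg$max_len, nrow(lf$kept), nrow(lf$rejected))

  exclusion_sets <- NULL
  if (!is.null(config$exclude) && length(config$exclude)) {
    exclusion_sets <- lapply(config$exclude, function(p)
      as.character(Biostrings::readBStringSet(p)))
    names(exclusion_sets) <- names(config$exclude)
  } else {
    note("no exclusion sets supplied; exclusion stage skipped")
  }
  ef <- exclusion_filter(lf$kept, exclusion_sets)
  if (!is.null(exclusion_sets))
    note("exclusion filter: kept %d, excluded %d", nrow(ef$kept),
         nrow(ef$excluded))

  res <- call_isoforms(ef$kept, canonicals, cfg)
  note("matching: %d isoform calls, %d canonical-equal tags, %d unmatched",
       nrow(res$calls), nrow(res$canonical_hits), nrow(res$unmatched))

  expr <- build_expression_table(res$calls, ef$kept, samples,
                                 n_mode = n_mode)
  canon_expr <- build_expression_table(res$canonical_hits, ef$kept,
                                       samples, n_mode = n_mode)

  annotation <- NULL
  if (!is.null(config$tracks) && length(config$tracks)) {
    tracks <- lapply(names(config$tracks), function(nm)
      load_bed_track(config$tracks[[nm]], nm))
    names(tracks) <- names(config$tracks)
    annotation <- annotate_loci(canonicals, tracks)
    note("annotation: %d/%d loci intergenic_unannotated",
         sum(annotation$intergenic_unannotated), nrow(annotation))
  } else {
    note("no annotation tracks supplied; annotation stage skipped")
  }

  records <- build_isoform_records(expr, annotation, ef$kept, samples)
  note("built %d isoform records", nrow(records))

  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  wr(res$calls, "calls.tsv")
  wr(expr, "expression.tsv")
  wr(canon_expr, "canonical_expression.tsv")
  wr(res$unmatched, "unmatched.tsv")
  wr(ef$excluded, "excluded.tsv")
  if (!is.null(annotation)) wr(annotation, "annotation.tsv")
  wr(records, "isoform_records.tsv")
  writeLines(logs, file.path(out_dir, "pipeline.log"))

  invisible(list(calls = res$calls, canonical_hits = res$canonical_hits,
                 unmatched = res$unmatched, expression = expr,
                 canonical_expression = canon_expr,
                 annotation = annotation, records = records,
                 samples = samples, log = logs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge calls, expression, annotation and sample metadata
#'
#' Builds the per-isoform display record: expression row joined with the
#' genome annotation of its canonical locus (columns NA when no tracks
#' were supplied) and the observed sample metadata (tissues, stages,
#' genotypes, sexes of the samples in which the isoform was detected,
#' comma-joined).
#'
#' @param expr Expression table from [build_expression_table()].
#' @param annotation Annotation table from [annotate_loci()], or NULL.
#' @param tags Long tag data.frame used for detection.
#' @param samples Sample sheet.
#' @return One data.frame, one row per isoform call.
#' @export
build_isoform_records <- function(expr, annotation, tags, samples) {
  out <- expr
  if (!is.null(annotation)) {
    idx <- match(out$canonical_id, annotation$canonical_id)
    out$genome_categories <- annotation$categories[idx]
  } else {
    out$genome_categories <- NA_character_
  }
  meta <- function(field) {
    vapply(out$tag_sequence, function(s) {
      sids <- unique(tags$sample_id[tags$sequence == s & tags$count > 0])
      paste(sort(unique(samples[[field]][samples$sample_id %in% sids])),
            collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  out$tissues <- meta("tissue")
  out$stages <- meta("stage")
  out$genotypes <- meta("genotype")
  out$sexes <- meta("sex")
  out
}

#' Validate pipeline inputs and print a manifest
#'
#' Loads every input named in the config, running all format and
#' invariant checks, and prints a one-line summary per input. Fails with
#' the loader's error on the first invalid file.
#'
#' @param config Config path or list, as for [run_pipeline()].
#' @return Invisibly, a character vector of manifest lines.
#' @export
load_check <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  lines <- character(0)
  say <- function(...) {
    lines <<- c(lines, sprintf(...))
  }
  genome <- load_genome(config$genome)
  say("genome\t%s\t%d contig(s), %d nt", config$genome,
      length(genome$contigs), sum(nchar(genome$contigs)))
  canon <- load_canonical_set(config$canonical, genome,
                              flank = config$params$flank %||% 15L)
  say("canonical\t%s\t%d loci", config$canonical, nrow(canon))
  for (s in names(config$reads)) {
    tg <- read_collapsed_fasta(config$reads[[s]], s)
    say("reads\t%s\tsample %s: %d tags, %d reads", config$reads[[s]], s,
        nrow(tg), sum(tg$count))
  }
  sheet <- load_sample_sheet(config$sample_sheet)
  say("sample_sheet\t%s\t%d sample(s)", config$sample_sheet, nrow(sheet))
  for (nm in names(config$tracks)) {
    tr <- load_bed_track(config$tracks[[nm]], nm)
    say("track\t%s\t%s: %d interval(s)", config$tracks[[nm]], nm, nrow(tr))
  }
  for (nm in names(config$exclude)) {
    ex <- Biostrings::readBStringSet(config$exclude[[nm]])
    say("exclude\t%s\t%s: %d sequence(s)", config$exclude[[nm]], nm,
        length(ex))
  }
  if (!is.null(config$transcripts)) {
    tx <- Biostrings::readBStringSet(config$transcripts)
    say("transcripts\t%s\t%d sequence(s)", config$transcripts, length(tx))
  }
  if (!is.null(config$term_map)) {
    tm <- read_term_map(config$term_map)
    say("term_map\t%s\t%d term(s)", config$term_map, length(tm))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
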