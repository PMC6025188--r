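# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package:
# plain R, all-offsets / all-positions enumeration.

# --- placement oracle -------------------------------------------------------
# Enumerate every ungapped placement of `tag` against a canonical body with
# its flanks, scanning a generous offset range and filtering by the overlap
# rule, with at most `max_mm` internal body mismatches.
oracle_placements <- function(tag, up, body, down,
                              min_overlap = 14L, max_mm = 1L) {
  tv <- strsplit(tag, "")[[1]]
  ctx <- strsplit(paste0(up, body, down), "")[[1]]
  L <- length(tv)
  U <- nchar(up)
  B <- nchar(body)
  C <- length(ctx)
  rows <- list()
  for (o5 in seq(-L - 20L, B + 20L)) {
    o3 <- o5 + L - B
    body_idx <- which(seq_len(L) + o5 >= 1L & seq_len(L) + o5 <= B)
    if (length(body_idx) < min_overlap) next
    mm <- integer(0)
    for (i in body_idx) {
      p <- U + o5 + i
      if (tv[i] != ctx[p] || tv[i] == "N" || ctx[p] == "N")
        mm <- c(mm, i)
    }
    if (length(mm) > max_mm) next
    if (length(mm) && any(mm %in% c(1L, L))) next
    e5 <- max(0L, -o5)
    t5 <- 0L
    for (i in rev(seq_len(e5))) {       # body edge outward to the tag 5' end
      p <- U + o5 + i
      if (p < 1L) break
      if (tv[i] == ctx[p] && tv[i] != "N" && ctx[p] != "N") t5 <- t5 + 1L
      else break
    }
    e3 <- max(0L, o3)
    t3 <- 0L
    if (e3 > 0L) for (i in (L - e3 + 1L):L) {
      p <- U + o5 + i
      if (p > C) break
      if (tv[i] == ctx[p] && tv[i] != "N" && ctx[p] != "N") t3 <- t3 + 1L
      else break
    }
    rows[[length(rows) + 1L]] <- data.frame(
      offset5 = o5, offset3 = o3,
      body_matches = length(body_idx) - length(mm),
      body_mismatch_pos = if (length(mm)) mm[1] else NA_integer_,
      templated5 = t5, templated3 = t3)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(offset5 = integer(), offset3 = integer(),
                  body_matches = integer(), body_mismatch_pos = integer(),
                  templated5 = integer(), templated3 = integer())
}

# --- target-site oracle -----------------------------------------------------
# Per-position evaluation of the two pairing rules at every anchor.
oracle_sites <- function(pirna, tx, min_run = 16L, max_wm = 3L,
                         wobble = FALSE) {
  pv <- strsplit(pirna, "")[[1]]
  tv <- strsplit(tx, "")[[1]]
  L <- length(pv)
  Tn <- length(tv)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "#")
  wmax <- min(21L, L)
  rows <- list()
  if (L < 2L) return(data.frame(site_start = integer(),
                                run_length = integer(),
                                window_mismatches = integer()))
  paired <- function(i, s) {
    t1 <- s - (i - 2L) + 1L
    if (t1 < 1L || t1 > Tn) return(FALSE)
    if (tv[t1] == comp[[pv[i]]]) return(TRUE)
    if (wobble && ((pv[i] == "G" && tv[t1] == "T") ||
                   (pv[i] == "T" && tv[t1] == "G"))) return(TRUE)
    FALSE
  }
  for (s in seq(0L, Tn - 1L)) {
    if (s < wmax - 2L) next   # mismatch window must lie within bounds
    r <- 0L
    i <- 2L
    while (i <= L && paired(i, s)) {
      r <- r + 1L
      i <- i + 1L
    }
    wm <- sum(!vapply(2L:wmax, paired, logical(1), s = s))
    if (r >= min_run && wm <= max_wm)
      rows[[length(rows) + 1L]] <- data.frame(site_start = s,
                                              run_length = r,
                                              window_mismatches = wm)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(site_start = integer(), run_length = integer(),
                  window_mismatches = integer())
}

# Build a transcript carrying exactly one duplex for `pirna` anchored so
# the whole mismatch window lies in bounds; `paired_at` gives the piRNA
# positions (within 2..min(21, L)) that pair. Returns the transcript and
# the 0-based anchor (transcript position pairing piRNA position 2).
make_duplex_tx <- function(pirna, paired_at) {
  pv <- strsplit(pirna, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  notpair <- c(A = "A", C = "C", G = "G", T = "T")  # base == pirna base never pairs, never wobbles
  wmax <- min(21L, length(pv))
  s <- wmax - 2L
  tx <- character(wmax - 1L)
  for (i in 2L:wmax) {
    t1 <- s - (i - 2L) + 1L
    tx[t1] <- if (i %in% paired_at) comp[[pv[i]]] else notpair[[pv[i]]]
  }
  list(tx = paste(tx, collapse = ""), site_start = s)
}

# --- interval-overlap oracle ------------------------------------------------
# O(n * m) pairwise scan; >= min_bp shared bases on the same contig.
oracle_overlap <- function(loci, track, min_bp = 1L) {
  vapply(seq_len(nrow(loci)), function(i) {
    any(track$contig == loci$contig[i] &
          pmin(track$end, loci$end[i]) -
            pmax(track$start, loci$start[i]) >= min_bp)
  }, logical(1))
}

# --- hypergeometric tail oracle ---------------------------------------------
# Direct summation of the upper tail.
oracle_hyper_tail <- function(k, n, K, N) {
  j <- seq(k, min(n, K))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# --- misc helpers -----------------------------------------------------------
rand_seq <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# A minimal in-memory canonical registry row for matcher tests.
toy_canonical <- function(sequence, up = "", down = "", id = "piR-t1") {
  data.frame(id = id, contig = "chrT", start = 0L,
             end = nchar(sequence), strand = "+", sequence = sequence,
             upstream_flank = up, downstream_flank = down,
             short_flank_5 = nchar(up) < 15L,
             short_flank_3 = nchar(down) < 15L,
             stringsAsFactors = FALSE)
}

# Long-format tag table from named counts for one sample.
toy_tags <- function(seqs, counts, sample_id = "s1") {
  data.frame(sequence = seqs, sample_id = sample_id,
             count = as.integer(counts), stringsAsFactors = FALSE)
}
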