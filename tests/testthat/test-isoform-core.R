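test_that("length filter keeps the 15-45 nt window with strict outer bounds", {
  tags <- toy_tags(c(rand_seq(14), rand_seq(15), rand_seq(45), rand_seq(46)),
                   rep(1, 4))
  lf <- apply_length_filter(tags)
  expect_equal(sort(nchar(lf$kept$sequence)), c(15, 45))
  expect_equal(sort(nchar(lf$rejected$sequence)), c(14, 46))
  expect_equal(nrow(lf$kept) + nrow(lf$rejected), nrow(tags))

  empty <- apply_length_filter(tags[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("exclusion filter removes substring matches on either strand, first set wins", {
  mirna <- "TAGCTTATCAGACTGATGTTGA"
  lnc <- paste0("CCC", mirna, "GGG")
  tags <- toy_tags(c(mirna,                       # exact miRNA
                     dna_revcomp(mirna),          # revcomp of an exclusion seq
                     "AAAAAAAAAAAAAAAAAAAA"),     # unrelated
                   c(5, 6, 7))
  res <- exclusion_filter(tags, list(miRNA = mirna, lncRNA = lnc))
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$sequence, "AAAAAAAAAAAAAAAAAAAA")
  expect_equal(res$excluded$reason, c("miRNA", "miRNA"))

  # no sets: identity
  id <- exclusion_filter(tags, NULL)
  expect_equal(id$kept, tags)
  expect_equal(nrow(id$excluded), 0)
})

test_that("placements match the forced examples", {
  set.seed(21)
  canon <- toy_canonical(rand_seq(28), up = rand_seq(15), down = rand_seq(15))

  # 3' templated extension of 2 nt
  tag <- paste0(canon$sequence, substr(canon$downstream_flank, 1, 2))
  pl <- enumerate_placements(tag, canon)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$offset3, 2)
  expect_equal(pl$templated3, 2)
  expect_equal(pl$body_matches, 28)

  # one internal substitution, equal ends
  tag <- canon$sequence
  substr(tag, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(tag, 10, 10))[1]
  pl <- enumerate_placements(tag, canon)
  expect_equal(pl$offset5, 0)
  expect_equal(pl$offset3, 0)
  expect_equal(pl$body_mismatch_pos, 10)

  # terminal mismatch is not an internal mismatch: no valid placement
  tag <- canon$sequence
  substr(tag, 28, 28) <- setdiff(c("A", "C", "G", "T"),
                                 substr(tag, 28, 28))[1]
  expect_equal(nrow(enumerate_placements(tag, canon)), 0)

  # N never matches: an N inside the body counts as the one mismatch
  tag <- canon$sequence
  substr(tag, 12, 12) <- "N"
  pl <- enumerate_placements(tag, canon)
  expect_equal(pl$body_mismatch_pos, 12)
  expect_equal(pl$body_matches, 27)
})

test_that("placement scanner agrees with the brute-force all-offset oracle", {
  set.seed(42)
  cfg <- detection_config()
  n_checked <- 0
  for (rep in 1:300) {
    tag_len <- sample(15:45, 1)
    body_len <- sample(26:31, 1)
    canon <- toy_canonical(rand_seq(body_len), up = rand_seq(15),
                           down = rand_seq(15))
    # half the cases: a perturbed body so valid placements actually occur
    tag <- if (rep %% 2 == 0) rand_seq(tag_len) else {
      x <- paste0(substr(canon$upstream_flank, 14, 15), canon$sequence,
                  "TT")
      substr(x, 5, 5) <- sample(c("A", "C", "G", "T"), 1)
      substr(x, 1, nchar(x))
    }
    got <- enumerate_placements(tag, canon, cfg)
    want <- oracle_placements(tag, canon$upstream_flank, canon$sequence,
                              canon$downstream_flank,
                              cfg$min_overlap, cfg$max_body_mismatch)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 100)  # the comparison exercised real placements
})

test_that("end classification implements the NE/NA/TR/SUB taxonomy", {
  set.seed(33)
  canon <- toy_canonical(rand_seq(28), up = rand_seq(15), down = rand_seq(15))

  # fully templated 3' extension
  tag <- paste0(canon$sequence, substr(canon$downstream_flank, 1, 2))
  pl <- enumerate_placements(tag, canon)
  cls <- classify_ends(pl, tag)
  expect_equal(cls$labels, "3NE")
  expect_equal(cls$variant3, substr(canon$downstream_flank, 1, 2))

  # non-templated 3' addition (each added base differs from the flank base)
  bad <- vapply(1:2, function(j)
    setdiff(c("A", "C", "G", "T"),
            substr(canon$downstream_flank, j, j))[1], character(1))
  tag <- paste0(canon$sequence, paste(bad, collapse = ""))
  pl <- enumerate_placements(tag, canon)
  cls <- classify_ends(pl, tag)
  expect_equal(cls$labels, "3NA")
  expect_equal(pl$templated3, 0)

  # mixed extension (templated then non-templated) is NA with the split kept
  tag <- paste0(canon$sequence, substr(canon$downstream_flank, 1, 2),
                setdiff(c("A", "C", "G", "T"),
                        substr(canon$downstream_flank, 3, 3))[1])
  pl <- enumerate_placements(tag, canon)
  cls <- classify_ends(pl, tag)
  expect_equal(cls$labels, "3NA")
  expect_equal(pl$templated3, 2)
  expect_equal(pl$offset3, 3)

  # variation on both ends: templated 5' extension plus 3' trim
  tag <- paste0(substr(canon$upstream_flank, 14, 15),
                substr(canon$sequence, 1, 25))
  pl <- enumerate_placements(tag, canon)
  cls <- classify_ends(pl, tag)
  expect_equal(sort(cls$labels), c("3TR", "5NE"))

  # pure trim and SUB
  tag <- substr(canon$sequence, 3, 28)
  pl <- enumerate_placements(tag, canon)
  expect_equal(classify_ends(pl, tag)$labels, "5TR")
  tag <- canon$sequence
  substr(tag, 14, 14) <- setdiff(c("A", "C", "G", "T"),
                                 substr(tag, 14, 14))[1]
  pl <- enumerate_placements(tag, canon)
  expect_equal(classify_ends(pl, tag)$labels, "SUB")

  # identical to canonical: empty labels, not an isoform
  pl <- enumerate_placements(canon$sequence, canon)
  best <- pl[which.max(pl$body_matches), ]
  expect_length(classify_ends(best, canon$sequence)$labels, 0)
})

test_that("strand symmetry: a minus-strand locus classifies the revcomp tag identically", {
  set.seed(55)
  g <- genome_ref(c(chrT = rand_seq(200)))
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrT\t60\t88\tpiR-p\t.\t+", "chrT\t60\t88\tpiR-m\t.\t-"), bed)
  cs <- load_canonical_set(bed, g)
  plus <- cs[1, ]; minus <- cs[2, ]
  for (i in 1:20) {
    e <- sample(1:3, 1)
    tag_p <- paste0(plus$sequence, substr(plus$downstream_flank, 1, e))
    tag_m <- paste0(minus$sequence, substr(minus$downstream_flank, 1, e))
    pl_p <- enumerate_placements(tag_p, plus)
    pl_m <- enumerate_placements(tag_m, minus)
    expect_equal(classify_ends(pl_p, tag_p)$labels, "3NE")
    expect_equal(classify_ends(pl_m, tag_m)$labels, "3NE")
    # the minus tag is the revcomp of the genomic continuation on the other side
    expect_equal(pl_p$offset3, e)
    expect_equal(pl_m$offset3, e)
  }
})

test_that("call_isoforms partitions tags into isoform / canonical / unmatched", {
  g <- make_genome(9, length = 4000)
  cs <- plant_canonicals(g, 20, seed = 10)
  iso_tag <- paste0(cs$sequence[3], substr(cs$downstream_flank[3], 1, 2))
  tags <- toy_tags(c(iso_tag, cs$sequence[5], rand_seq(30)), c(4, 5, 6))
  res <- call_isoforms(tags, cs)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$canonical_id, cs$id[3])
  expect_equal(res$calls$labels, "3NE")
  expect_false(res$calls$multi_mapped)
  expect_equal(res$canonical_hits$canonical_id, cs$id[5])
  expect_equal(nrow(res$unmatched), 1)
  # exhaustive and disjoint
  all_seqs <- c(res$calls$tag_sequence, res$canonical_hits$tag_sequence,
                res$unmatched$tag_sequence)
  expect_setequal(all_seqs, unique(tags$sequence))
  expect_equal(anyDuplicated(all_seqs), 0)
})

test_that("ties across identical canonicals set multi_mapped with the smaller id first", {
  set.seed(77)
  body <- rand_seq(28)
  up <- rand_seq(15); down <- rand_seq(15)
  cs <- rbind(toy_canonical(body, up, down, id = "piR-b"),
              toy_canonical(body, up, down, id = "piR-a"))
  class(cs) <- c("canonical_set", "data.frame")
  tag <- paste0(body, substr(down, 1, 2))
  res <- call_isoforms(toy_tags(tag, 3), cs)
  expect_true(res$calls$multi_mapped)
  expect_equal(res$calls$canonical_id, "piR-a")
  expect_equal(res$calls$all_canonical_ids, "piR-a,piR-b")
})

test_that("planted fixture classes are recovered exactly", {
  g <- make_genome(101, length = 5000)
  cs <- plant_canonicals(g, 10, seed = 102)
  # one tag per class, including a both-end combination
  comp <- c(`3NE` = 0.2, `3NA` = 0.2, `3TR` = 0.2, `5NE` = 0.1,
            `5NA` = 0.1, `5TR` = 0.1, SUB = 0.05, `5NE+3TR` = 0.05)
  reads <- synth_reads(cs, comp, depth = 2000, n_samples = 1, seed = 103)
  res <- call_isoforms(reads$tags, cs)
  truth <- reads$truth[reads$truth$sequence %in% reads$tags$sequence, ]
  idx <- match(truth$sequence, res$calls$tag_sequence)
  expect_false(anyNA(idx))
  expect_equal(res$calls$labels[idx], truth$labels)
  expect_equal(res$calls$offset5[idx], truth$offset5)
  expect_equal(res$calls$offset3[idx], truth$offset3)
  expect_equal(res$calls$canonical_id[idx], truth$canonical_id)
})
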