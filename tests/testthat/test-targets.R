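test_that("1U/10A eligibility respects mode semantics", {
  expect_true(is_target_eligible("TAAAAAAAAA"))                 # 1U
  expect_true(is_target_eligible("TAAAAAAAAA", mode = "both"))  # 1U and 10A
  expect_true(is_target_eligible("GAAAAAAAAA"))                 # 10A only
  expect_false(is_target_eligible("GAAAAAAAAA", mode = "both"))
  expect_false(is_target_eligible("GAAAAAAAAC"))
  expect_false(is_target_eligible("GAAAAAAAAC", mode = "both"))
  expect_warning(e <- is_target_eligible("TAAAA"), "shorter than 10")
  expect_false(e)
  # RNA alphabet accepted
  expect_true(is_target_eligible("UAAAAAAAAA"))
})

test_that("perfect and boundary duplexes are called per the two rules", {
  set.seed(91)
  pir <- paste0("T", rand_seq(25))  # 26 nt, eligible at position 1

  # perfect complement of positions 2..21 embedded in a transcript
  w <- 21
  insert <- dna_revcomp(substr(pir, 2, w))
  tx <- paste0(rand_seq(50), insert, rand_seq(50))
  sites <- find_sites(pir, tx)
  s_expect <- 50 + nchar(insert) - 1
  hit <- sites[sites$site_start == s_expect, ]
  expect_equal(nrow(hit), 1)
  expect_gte(hit$run_length, 20)
  expect_equal(hit$window_mismatches, 0)

  # run of exactly 16 with one window mismatch qualifies (18 nt piRNA:
  # window truncates at the piRNA 3' end)
  pir18 <- paste0("T", rand_seq(17))
  d <- make_duplex_tx(pir18, paired_at = 2:17)
  sites <- find_sites(pir18, d$tx)
  expect_equal(sites$site_start, d$site_start)
  expect_equal(sites$run_length, 16)
  expect_equal(sites$window_mismatches, 1)

  # run of 15 fails rule (i) even with a clean window
  d15 <- make_duplex_tx(pir18, paired_at = 2:16)
  expect_equal(nrow(find_sites(pir18, d15$tx)), 0)

  # 3 window mismatches accepted, 4 rejected (run kept >= 16 in both)
  pir26 <- paste0("T", rand_seq(25))
  d3 <- make_duplex_tx(pir26, paired_at = c(2:18))     # 19,20,21 mismatch
  s3 <- find_sites(pir26, d3$tx)
  expect_equal(s3$window_mismatches, 3)
  expect_equal(s3$run_length, 17)
  d4 <- make_duplex_tx(pir26, paired_at = c(2:17))     # 18..21 mismatch
  expect_equal(nrow(find_sites(pir26, d4$tx)), 0)
  expect_equal(oracle_sites(pir26, d4$tx)$run_length, integer(0))

  # a mismatch early in the run kills rule (i) even if rule (ii) passes
  dmid <- make_duplex_tx(pir26, paired_at = setdiff(2:21, 5))
  expect_equal(nrow(find_sites(pir26, dmid$tx)), 0)

  # piRNAs shorter than 17 nt can never have sites
  pir16 <- paste0("T", rand_seq(15))
  d16 <- make_duplex_tx(pir16, paired_at = 2:16)
  expect_equal(nrow(find_sites(pir16, d16$tx)), 0)
})

test_that("G:U wobble counts as mismatch by default, as pair when enabled", {
  pir <- paste0("T", paste(rep("G", 25), collapse = ""))  # G-rich piRNA
  # transcript base T opposite piRNA G: wobble pair
  tx_wob <- paste(rep("T", 20), collapse = "")            # covers pos 2..21
  s_def <- find_sites(pir, tx_wob)
  expect_equal(nrow(s_def), 0)
  s_wob <- find_sites(pir, tx_wob, wobble_pairs = TRUE)
  expect_gt(nrow(s_wob), 0)
  expect_gte(max(s_wob$run_length), 16)
})

test_that("site finding equals brute-force per-position evaluation on random pairs", {
  set.seed(92)
  for (rep in 1:120) {
    pir <- rand_seq(24)
    tx <- rand_seq(300)
    # plant a (possibly imperfect) duplex in half the cases so qualifying
    # sites occur; random pairs alone almost never qualify
    if (rep %% 2 == 0) {
      ins <- dna_revcomp(substr(pir, 2, min(21, nchar(pir))))
      if (rep %% 4 == 0) substr(ins, 3, 3) <- "A"
      at <- sample(1:(300 - nchar(ins)), 1)
      tx <- paste0(substr(tx, 1, at - 1), ins,
                   substr(tx, at + nchar(ins), 300))
    }
    got <- find_sites(pir, tx)
    want <- oracle_sites(pir, tx)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("raising the mismatch cap never loses sites; trimming never lengthens runs", {
  set.seed(93)
  for (rep in 1:25) {
    pir <- rand_seq(26)
    ins <- dna_revcomp(substr(pir, 2, 21))
    substr(ins, sample(1:20, 1), sample(1:20, 1)) <- "A"
    tx <- paste0(rand_seq(30), ins, rand_seq(30))
    n3 <- nrow(find_sites(pir, tx, max_window_mismatches = 3))
    n4 <- nrow(find_sites(pir, tx, max_window_mismatches = 4))
    expect_gte(n4, n3)
    # 3' trimming: run_length at a fixed site never increases
    s_full <- find_sites(pir, tx, min_run = 1, max_window_mismatches = 20)
    pir_trim <- substr(pir, 1, 22)
    s_trim <- find_sites(pir_trim, tx, min_run = 1, max_window_mismatches = 20)
    common <- intersect(s_full$site_start, s_trim$site_start)
    for (s in common) {
      expect_lte(s_trim$run_length[s_trim$site_start == s],
                 s_full$run_length[s_full$site_start == s])
    }
  }
})

test_that("isoform target comparison flags affected transcripts and enforces 2-6 inputs", {
  set.seed(94)
  pir <- paste0("T", rand_seq(27))
  trimmed <- substr(pir, 1, 16)     # below the 16-pair capacity: no sites
  ins <- dna_revcomp(substr(pir, 2, 21))
  txs <- c(tx1 = paste0(rand_seq(40), ins, rand_seq(40)),
           tx2 = rand_seq(100))
  cmp <- compare_isoform_targets(c(pir, trimmed), txs)
  expect_equal(cmp$transcript_id, c("tx1", "tx2"))
  expect_equal(cmp$sites_1, c(1L, 0L))
  expect_equal(cmp$sites_2, c(0L, 0L))
  expect_equal(cmp$affected, c(TRUE, FALSE))
  expect_equal(cmp$delta, c(1L, 0L))

  # identical isoforms: nothing affected
  same <- compare_isoform_targets(c(pir, pir), txs)
  expect_false(any(same$affected))

  expect_error(compare_isoform_targets(rep(pir, 7), txs), "between 2 and 6")
  expect_error(compare_isoform_targets(pir, txs), "between 2 and 6")
})

test_that("hypergeometric enrichment matches tail summation and the exact test", {
  set.seed(95)
  for (rep in 1:200) {
    N <- sample(50:400, 1)
    K <- sample(5:(N - 5), 1)
    n <- sample(5:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    k <- max(k, 1)
    tm <- list(T1 = sprintf("g%d", 1:K))
    bg <- sprintf("g%d", 1:N)
    targets <- c(sprintf("g%d", sample(1:K, k)),
                 sprintf("g%d", K + sample(1:(N - K), n - k)))
    row <- fisher_enrichment(targets, tm, background = bg)
    expect_equal(row$k, k)
    expect_equal(row$n, n)
    expect_equal(row$p, oracle_hyper_tail(k, n, K, N), tolerance = 1e-12)
    ft <- stats::fisher.test(rbind(c(k, n - k), c(K - k, N - K - n + k)),
                             alternative = "greater")
    expect_equal(row$p, ft$p.value, tolerance = 1e-10)
    expect_equal(row$fold, (k / n) / (K / N))
  }
})

test_that("enrichment edge cases: saturation, Bonferroni cap, ordering", {
  # k = n, K = N: p = 1, fold = 1
  tm <- list(T1 = sprintf("g%d", 1:30))
  row <- fisher_enrichment(sprintf("g%d", 1:10), tm,
                           background = sprintf("g%d", 1:30))
  expect_equal(row$p, 1)
  expect_equal(row$fold, 1)

  # Bonferroni = min(1, p * m) over the tested terms
  set.seed(96)
  tm50 <- lapply(1:50, function(i) sprintf("g%d", sample(1:200, 20)))
  names(tm50) <- sprintf("T%02d", 1:50)
  res <- fisher_enrichment(sprintf("g%d", sample(1:200, 15)), tm50,
                           background = sprintf("g%d", 1:200), min_k = 0)
  m <- nrow(res)
  expect_equal(res$p_bonferroni, pmin(1, res$p * m))
  expect_false(is.unsorted(res$p))

  # p decreases as k grows with n, K, N fixed
  ps <- vapply(1:10, function(k) {
    targets <- c(sprintf("g%d", 1:k), sprintf("h%d", 1:(12 - k)))
    fisher_enrichment(targets, list(T1 = sprintf("g%d", 1:40)),
                      background = c(sprintf("g%d", 1:40),
                                     sprintf("h%d", 1:160)))$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(fisher_enrichment(character(0), tm,
                                 background = sprintf("g%d", 1:30)),
               "empty target set")
})

test_that("term maps load from 2-column TSV and GMT", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("term_id\tgene_id", "T1\tg1", "T1\tg2", "T2\tg2"), tsv)
  tm <- read_term_map(tsv)
  expect_equal(tm$T1, c("g1", "g2"))
  expect_equal(tm$T2, "g2")

  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tg1\tg2\tg3", "T2\tdesc\tg9"), gmt)
  tg <- read_term_map(gmt)
  expect_equal(tg$T1, c("g1", "g2", "g3"))
  expect_equal(tg$T2, "g9")
})
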