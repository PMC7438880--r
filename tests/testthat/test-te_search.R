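test_that("a verbatim planted copy is found once at full identity", {
  set.seed(21)
  cons <- te_consensus("fam", rseq(300))
  g <- splice_in(rseq(100000), cons$sequence, 50000)
  sites <- scan_genome(cons, asm1(g))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 50001L)
  expect_equal(sites$end, 50300L)
  expect_equal(sites$identity, 1)
  expect_equal(sites$coverage, 1)
  expect_equal(sites$strand, "+")
  expect_equal(sites$length_class, "full")
  expect_equal(sites$sequence, cons$sequence)
})

test_that("a reverse-complemented copy is found on the minus strand", {
  set.seed(22)
  cons <- te_consensus("fam", rseq(300))
  g <- splice_in(rseq(20000), revcomp(cons$sequence), 9000)
  sites <- scan_genome(cons, asm1(g))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "-")
  expect_equal(sites$identity, 1)
  expect_equal(sites$sequence, cons$sequence) # stored element-oriented
})

test_that("identity thresholds separate heavily mutated copies", {
  set.seed(23)
  cons <- te_consensus("fam", rseq(300))
  copy <- mut(cons$sequence, 0.28)
  g <- splice_in(rseq(20000), copy, 10000)
  strict <- scan_genome(cons, asm1(g), scan_params(min_identity = 0.80))
  relaxed <- scan_genome(cons, asm1(g),
                         scan_params(min_identity = 0.70, min_score = 30))
  # oracle: the planted region's true local-alignment identity sits in the
  # (0.70, 0.80) band, so only the relaxed threshold reports it
  ora <- Biostrings::pairwiseAlignment(
    cons$sequence, g, type = "local", substitutionMatrix = sub_mat(),
    gapOpening = 5, gapExtension = 2)
  ora_id <- Biostrings::nmatch(ora) / Biostrings::nchar(ora)
  expect_gt(ora_id, 0.70)
  expect_lt(ora_id, 0.80)
  expect_equal(nrow(strict), 0L)
  expect_equal(nrow(relaxed), 1L)
})

test_that("multiple non-overlapping copies are all recovered", {
  set.seed(24)
  cons <- te_consensus("fam", rseq(300))
  g <- rseq(50000)
  at <- c(5000, 15000, 25000, 35000, 45000)
  for (p in rev(at)) g <- splice_in(g, cons$sequence, p)
  sites <- scan_genome(cons, asm1(g))
  expect_equal(nrow(sites), 5L)
})

test_that("scanning the reverse-complemented genome mirrors the site list", {
  set.seed(25)
  cons <- te_consensus("fam", rseq(300))
  g <- splice_in(rseq(30000), mut(cons$sequence, 0.05), 12000)
  g <- splice_in(g, revcomp(cons$sequence), 25000)
  fwd <- scan_genome(cons, asm1(g))
  rev <- scan_genome(cons, asm1(revcomp(g)))
  n <- nchar(g)
  expect_equal(nrow(fwd), nrow(rev))
  got <- rev[order(-rev$start), ]
  expect_equal(n - got$end + 1L, fwd$start)
  expect_equal(n - got$start + 1L, fwd$end)
  expect_equal(got$strand, chartr("+-", "-+", fwd$strand))
  expect_equal(got$score, fwd$score)
})

test_that("planted copies at moderate divergence are always recovered", {
  cons <- te_consensus("fam", {set.seed(26); rseq(300)})
  for (seed in 1:5) {
    set.seed(seed)
    g <- rseq(40000)
    positions <- c(6000, 16000, 26000, 36000)
    lens <- c(300, 300, 270, 300)
    for (i in rev(seq_along(positions))) {
      copy <- mut(substr(cons$sequence, 1, lens[i]), 0.08)
      g <- splice_in(g, copy, positions[i])
    }
    sites <- scan_genome(cons, asm1(g))
    expect_equal(nrow(sites), 4L, info = paste("seed", seed))
  }
})

test_that("overlap dedup keeps the best hit and is idempotent", {
  base <- data.frame(site_id = "", species = "S", chrom = "c1",
                     strand = "+", identity = 0.9, coverage = 1,
                     length_class = "full", subfamily = "f",
                     sequence = "A", stringsAsFactors = FALSE)
  two <- rbind(cbind(base, start = 100L, end = 400L, score = 50),
               cbind(base, start = 100L, end = 400L, score = 40))
  kept <- dedup_hits(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 50)

  # 10% overlap of the shorter site: both kept
  apart <- rbind(cbind(base, start = 100L, end = 400L, score = 50),
                 cbind(base, start = 371L, end = 671L, score = 40))
  expect_equal(nrow(dedup_hits(apart)), 2L)

  # chain of three mutually >25%-overlapping hits: only the best survives;
  # brute-force pairwise elimination agrees
  chain <- rbind(cbind(base, start = 100L, end = 400L, score = 30),
                 cbind(base, start = 200L, end = 500L, score = 40),
                 cbind(base, start = 300L, end = 600L, score = 50))
  kept <- dedup_hits(chain)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 50)
  brute <- chain
  repeat {
    drop <- NULL
    for (i in seq_len(nrow(brute))) for (j in seq_len(nrow(brute))) {
      if (i == j) next
      ov <- min(brute$end[i], brute$end[j]) - max(brute$start[i], brute$start[j]) + 1
      shorter <- min(brute$end[i] - brute$start[i], brute$end[j] - brute$start[j]) + 1
      if (ov > 0.25 * shorter && brute$score[i] < brute$score[j]) drop <- c(drop, i)
    }
    if (is.null(drop)) break
    brute <- brute[-unique(drop), , drop = FALSE]
  }
  expect_equal(kept$score, brute$score)
  expect_identical(dedup_hits(kept), kept)
})

test_that("length classes follow the published size bands", {
  expect_equal(classify_length(300 / 300), "full")
  expect_equal(classify_length(240 / 300), "short")
  expect_equal(classify_length(93 / 300), "short")
  expect_equal(classify_length(0.85), "full")
})

test_that("insertion names encode sub-genome, chromosome and length class", {
  asm <- genome_assembly("DW", c(`4A` = rseq(1000), `6B` = rseq(1000)))
  sites <- data.frame(site_id = "", species = "DW",
                      chrom = c("4A", "4A", "6B"),
                      start = c(500L, 100L, 50L), end = c(800L, 250L, 350L),
                      strand = "+", identity = 1, coverage = c(1, 0.5, 1),
                      length_class = c("full", "short", "full"),
                      subfamily = "f", score = 1, sequence = "A",
                      stringsAsFactors = FALSE)
  named <- name_sites(sites, asm)
  expect_equal(named$site_id, c("DW_A4-2", "DW_A4-1S", "DW_B6-1"))
})

test_that("a consensus shorter than the seed errors out", {
  expect_error(scan_genome(te_consensus("f", "ACGTACGT"), asm1(rseq(1000))),
               "shorter than seed")
})
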