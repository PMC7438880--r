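test_that("progressive alignment handles identical and near-identical input", {
  msa <- progressive_msa(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(unname(msa), c("ACGTACGT", "ACGTACGT"), ignore_attr = TRUE)

  set.seed(51)
  base <- rseq(300)
  copies <- vapply(1:10, function(i) mut(base, 0.005), character(1))
  names(copies) <- paste0("c", 1:10)
  msa10 <- progressive_msa(copies)
  expect_equal(unique(nchar(msa10)), 300L)
  expect_false(any(grepl("-", msa10)))
  # ungapping every row reproduces its input
  expect_identical(gsub("-", "", msa10[names(copies)]), copies)
})

test_that("pairwise alignment attains the exhaustive DP optimum", {
  al <- progressive_msa(c(a = "ACGT", b = "ACT"))
  expect_equal(sum(strsplit(al[["a"]], "")[[1]] == "-") +
                 sum(strsplit(al[["b"]], "")[[1]] == "-"), 1L)
  ora <- Biostrings::pairwiseAlignment(
    "ACGT", "ACT", type = "global", substitutionMatrix = sub_mat(),
    gapOpening = 5, gapExtension = 2)
  expect_equal(attr(al, "score"), Biostrings::score(ora))

  set.seed(52)
  for (i in 1:20) {
    a <- rseq(sample(40:150, 1)); b <- rseq(sample(40:150, 1))
    al <- progressive_msa(c(x = a, y = b))
    ora <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = sub_mat(),
      gapOpening = 5, gapExtension = 2)
    expect_equal(attr(al, "score"), Biostrings::score(ora), info = i)
  }
})

test_that("majority consensus follows the column rules", {
  expect_equal(consensus_from_msa(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_equal(consensus_from_msa(c("AA", "AA", "CA")), "AA")
  # column with 1/3 non-gap at majority 0.5 is dropped
  expect_equal(consensus_from_msa(c("AT", "-T", "-T")), "T")
  # alphabetical tie-break
  expect_equal(consensus_from_msa(c("T", "G")), "G")
  expect_error(consensus_from_msa(character(0)), "empty")
})

test_that("subfamily assignment separates variants and flags chimeras", {
  cons <- mariam_like_consensus()
  m1 <- cons[[1]]; m2 <- cons[[2]]
  expect_equal(as.character(classify_subfamily(m2$sequence, cons)),
               "Mariam2_like")
  expect_equal(as.character(classify_subfamily(m1$sequence, cons)),
               "Mariam1_like")
  # chimera joined near the identity balance point: identities to the two
  # variants are within the margin band by construction, call refused
  chim <- paste0(substr(m1$sequence, 1, 140),
                 substr(m2$sequence, 141, m2$length))
  got <- classify_subfamily(chim, cons)
  expect_equal(as.character(got), "unassigned")
  ids <- attr(got, "identities")
  expect_lt(abs(ids[1] - ids[2]), 0.03)
  set.seed(53)
  expect_equal(as.character(classify_subfamily(rseq(300), cons)),
               "unassigned")
})

test_that("TN93 distance matches the published closed form", {
  set.seed(54)
  a <- rseq(3000, gc = 0.46)
  expect_equal(tn93_distance(a, a), 0)
  for (rate in c(0.02, 0.08, 0.15)) {
    b <- mut(a, rate)
    expect_equal(tn93_distance(a, b), tn93_closed_form(a, b),
                 tolerance = 1e-6)
    expect_equal(tn93_distance(b, a), tn93_distance(a, b))
  }
  # uniform substitution process: TN93 within 2% of the JC69 closed form
  b <- mut(a, 0.10)
  p <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(tn93_distance(a, b), jc, tolerance = 0.02 * jc)
})

test_that("gapped and saturated pairs are handled", {
  # gap columns are excluded pairwise
  d <- tn93_distance("AC-GT", "ACAGT")
  expect_equal(d, 0)
  # saturation: a transition-saturated pair violates the log domain, is
  # flagged, and is imputed above the largest finite distance
  set.seed(57)
  a <- rseq(500)
  av <- strsplit(a, "")[[1]]
  bv <- av
  idx <- sample(500, 450)
  bv[idx] <- chartr("AGCT", "GATC", av[idx]) # pure transitions
  msa <- c(a = a, b = paste(bv, collapse = ""), c = mut(a, 0.05))
  D <- tn93_matrix(msa)
  sat <- attr(D, "saturated")
  expect_true(sat["a", "b"])
  expect_false(sat["a", "c"])
  expect_true(all(is.finite(D)))
  expect_equal(D["a", "b"], 1.10 * D["a", "c"], tolerance = 1e-9)
})

test_that("neighbor joining solves the three-point problem exactly", {
  D <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_s3_class(tr, "phylo")
  # three-point formulas: a = (dab+dac-dbc)/2 etc.
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(unname(lens[c("a", "b", "c")]), c(3, 2, 6))
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(55)
  for (i in 1:20) {
    tr <- ape::rtree(6)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
    D <- stats::cophenetic(tr)
    got <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(got)), 0,
                 info = i)
  }
  # ultrametric 8-taxon tree round trip
  tr8 <- ape::compute.brlen(ape::stree(8, "balanced"), 1)
  D8 <- stats::cophenetic(tr8)
  got8 <- nj_tree(D8)
  expect_equal(phangorn::RF.dist(ape::unroot(tr8), ape::unroot(got8)), 0)
  # negative branch lengths never survive the clamping rule
  expect_true(all(got8$edge.length >= 0))
})

test_that("bootstrap supports behave at the extremes and reproduce bitwise", {
  set.seed(56)
  blockA <- rseq(300); blockB <- rseq(300)
  seqs <- c(vapply(1:5, function(i) mut(blockA, 0.01), character(1)),
            vapply(1:5, function(i) mut(blockB, 0.01), character(1)))
  names(seqs) <- c(paste0("a", 1:5), paste0("b", 1:5))
  msa <- progressive_msa(seqs)
  tr <- bootstrap_support(msa, replicates = 50L, seed = 7L)
  # the two blocks differ at ~50% of columns: their bipartition is certain
  split_node <- which(vapply((length(tr$tip.label) + 1):(length(tr$tip.label) + tr$Nnode),
    function(n) {
      tips <- ape::extract.clade(tr, n)$tip.label
      setequal(tips, paste0("a", 1:5)) || setequal(tips, paste0("b", 1:5))
    }, logical(1)))
  expect_true(length(split_node) >= 1)
  expect_gte(min(as.numeric(tr$node.label[split_node])), 95)

  # single replicate: supports are all 0 or 100
  tr1 <- bootstrap_support(msa, replicates = 1L, seed = 7L)
  expect_true(all(as.numeric(tr1$node.label) %in% c(0, 100)))

  # fixed seed reproduces bit-identically
  tr2 <- bootstrap_support(msa, replicates = 50L, seed = 7L)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  # identical sequences: tree is star-like after the support cutoff
  same <- stats::setNames(rep(substr(blockA, 1, 100), 5), paste0("s", 1:5))
  trs <- bootstrap_support(progressive_msa(same), replicates = 20L,
                           seed = 3L, collapse = 45L)
  expect_equal(trs$Nnode, 1L)
})
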