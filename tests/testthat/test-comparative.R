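# small two/three-genome worlds built from a shared ancestor
make_world <- function(seed, n = 2, len = 30000, div = 0.02,
                       elem_len = 300, tsd = "GTTACAAAC") {
  set.seed(seed)
  anc <- rseq(len)
  elem <- rseq(elem_len)
  pos <- len %/% 2
  carrier <- paste0(substr(anc, 1, pos), tsd, elem, tsd,
                    substr(anc, pos + nchar(tsd) + 1, len))
  site <- list(site_id = "s1", chrom = "c1",
               start = pos + nchar(tsd) + 1L,
               end = pos + nchar(tsd) + elem_len, strand = "+",
               sequence = elem)
  list(anc = anc, elem = elem, pos = pos, tsd = tsd, carrier = carrier,
       site = site, div = div)
}

test_that("self-mapping reproduces the locus as a full site", {
  w <- make_world(41)
  asm <- asm1(w$carrier, "A")
  fl <- extract_flanks(w$site, asm, 1000L)
  cons <- list(te_consensus("fam", w$elem))
  m <- map_locus(fl, asm, cons)
  expect_equal(m$left_hit$identity, 1)
  expect_equal(m$right_hit$identity, 1)
  expect_true(m$consistent)
  expect_equal(m$inter_flank_gap, nchar(w$elem))
  expect_true(m$element_present_in_gap)
  expect_equal(classify_presence(m), "full_site")
})

test_that("an excised locus maps as an empty site with a TSD-sized footprint", {
  w <- make_world(42)
  # excision genome: flanks ligated around a single TSD remnant
  excised <- paste0(substr(w$anc, 1, w$pos), w$tsd,
                    substr(w$anc, w$pos + nchar(w$tsd) + 1, nchar(w$anc)))
  target <- asm1(mut(excised, w$div), "B")
  fl <- extract_flanks(w$site, asm1(w$carrier, "A"), 1000L)
  cons <- list(te_consensus("fam", w$elem))
  m <- map_locus(fl, target, cons)
  expect_true(m$consistent)
  expect_lte(m$inter_flank_gap, nchar(w$tsd) + 5L)
  expect_false(m$element_present_in_gap)
  expect_equal(classify_presence(m), "empty_site")
})

test_that("a deletion spanning the locus gives an absent locus", {
  w <- make_world(43)
  # remove the locus plus 3 kb on each side: both flank windows vanish
  del <- paste0(substr(w$anc, 1, w$pos - 3000),
                substr(w$anc, w$pos + 3000, nchar(w$anc)))
  target <- asm1(mut(del, w$div), "B")
  fl <- extract_flanks(w$site, asm1(w$carrier, "A"), 1000L)
  m <- map_locus(fl, target, list(te_consensus("fam", w$elem)))
  expect_equal(classify_presence(m), "absent_locus")
})

test_that("an inversion breakpoint between the flanks flags rearrangement", {
  w <- make_world(44)
  # inversion starting inside the locus: right flank lands inverted elsewhere
  inv <- paste0(substr(w$anc, 1, w$pos),
                revcomp(substr(w$anc, w$pos + 1, w$pos + 8000)),
                substr(w$anc, w$pos + 8001, nchar(w$anc)))
  target <- asm1(mut(inv, w$div), "B")
  fl <- extract_flanks(w$site, asm1(w$carrier, "A"), 1000L)
  m <- map_locus(fl, target, list(te_consensus("fam", w$elem)))
  expect_equal(classify_presence(m), "rearranged_candidate")
})

test_that("short flanks after clipping make the call ambiguous", {
  w <- make_world(45)
  asm <- asm1(w$carrier, "A")
  near_start <- w$site
  near_start$start <- 40L; near_start$end <- 340L
  fl <- extract_flanks(near_start, asm, 1000L)
  m <- map_locus(fl, asm, list(te_consensus("fam", w$elem)))
  expect_equal(classify_presence(m), "ambiguous")
})

test_that("an ancestral insertion clusters across all carriers", {
  set.seed(46)
  anc <- rseq(40000)
  elem <- rseq(300)
  tsd <- "GTTACAAAC"
  pos <- 20000
  carrier <- paste0(substr(anc, 1, pos), tsd, elem, tsd,
                    substr(anc, pos + 10, 40000))
  asms <- list(S1 = asm1(mut(carrier, 0.02), "S1"),
               S2 = asm1(mut(carrier, 0.02), "S2"),
               S3 = asm1(mut(carrier, 0.02), "S3"))
  cons <- list(te_consensus("fam", elem))
  sites <- lapply(asms, function(a)
    name_sites(dedup_hits(scan_genome(cons[[1]], a)), a))
  expect_true(all(vapply(sites, nrow, 1L) == 1L))
  mm <- membership_matrix(sites, asms, cons)
  expect_equal(nrow(mm$matrix), 1L)
  expect_true(all(mm$matrix[1, ] == "full_site"))
  v <- venn_counts(mm)
  expect_equal(unname(v["S1+S2+S3"]), 1L)
})

test_that("a lineage-specific insertion is empty or absent elsewhere", {
  set.seed(47)
  anc <- rseq(40000)
  elem <- rseq(300)
  pos <- 20000
  carrier <- paste0(substr(anc, 1, pos), "GTTACAAAC", elem, "GTTACAAAC",
                    substr(anc, pos + 10, 40000))
  asms <- list(S1 = asm1(mut(anc, 0.02), "S1"),
               S2 = asm1(mut(carrier, 0.02), "S2"))
  cons <- list(te_consensus("fam", elem))
  sites <- lapply(asms, function(a)
    name_sites(dedup_hits(scan_genome(cons[[1]], a)), a))
  expect_equal(nrow(sites$S1), 0L)
  expect_equal(nrow(sites$S2), 1L)
  mm <- membership_matrix(sites, asms, cons)
  expect_equal(unname(mm$matrix[1, "S2"]), "full_site")
  expect_equal(unname(mm$matrix[1, "S1"]), "empty_site")
  expect_equal(unname(venn_counts(mm)["S2"]), 1L)
})

test_that("venn region counts partition the clusters", {
  M <- rbind(c("full_site", "full_site", "empty_site"),
             c("full_site", "absent_locus", "absent_locus"),
             c("full_site", "absent_locus", "absent_locus"),
             c("empty_site", "full_site", "full_site"))
  colnames(M) <- c("A", "B", "C")
  rownames(M) <- paste0("cl", 1:4)
  v <- venn_counts(M)
  expect_equal(sum(v), nrow(M))
  expect_equal(unname(v["A+B"]), 1L)
  expect_equal(unname(v["A"]), 2L)
  expect_equal(unname(v["B+C"]), 1L)
})

test_that("gene associations respect feature priority and the window", {
  genes <- list(
    list(gene_id = "g1", chrom = "c1", start = 1000L, end = 2000L,
         strand = "+", features = data.frame(
           feature_type = c("exon", "exon", "intron"),
           start = c(1000L, 1600L, 1300L), end = c(1299L, 2000L, 1599L))),
    list(gene_id = "g2", chrom = "c1", start = 5000L, end = 6000L,
         strand = "+", features = data.frame(feature_type = "exon",
                                             start = 5000L, end = 6000L)))
  # element inside the implied intron
  a <- gene_association(list(site_id = "s", chrom = "c1", start = 1400L,
                             end = 1500L), genes, 500L)
  expect_equal(a$relation, "within_intron")
  expect_equal(a$distance, 0L)
  # gene ending 400 bp before the element: associated
  b <- gene_association(list(site_id = "s", chrom = "c1", start = 2400L,
                             end = 2700L), genes, 500L)
  expect_equal(b$gene_id, "g1")
  expect_equal(b$relation, "upstream")
  expect_equal(b$distance, 400L)
  # 600 bp away: outside the window
  d <- gene_association(list(site_id = "s", chrom = "c1", start = 2600L,
                             end = 2900L), genes, 500L)
  expect_equal(nrow(d), 0L)
  # CDS beats intron when both overlap
  genes[[1]]$features <- rbind(genes[[1]]$features,
                               data.frame(feature_type = "CDS",
                                          start = 1350L, end = 1450L))
  e <- gene_association(list(site_id = "s", chrom = "c1", start = 1400L,
                             end = 1500L), genes, 500L)
  expect_equal(e$relation, "within_CDS")
})
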