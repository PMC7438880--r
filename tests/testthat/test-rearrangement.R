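test_that("identical sequences give one full-length forward anchor", {
  set.seed(61)
  s <- rseq(5000)
  a <- anchor_matches(s, s, min_anchor_len = 500L)
  expect_equal(nrow(a), 1L)
  expect_equal(a$orientation, "forward")
  expect_equal(c(a$q_start, a$q_end), c(1L, 5000L))
  expect_equal(c(a$t_start, a$t_end), c(1L, 5000L))
  expect_equal(a$identity, 1)
})

test_that("a reverse-complemented middle block appears as a reverse anchor", {
  set.seed(62)
  s <- rseq(7000)
  t <- paste0(substr(s, 1, 2500), revcomp(substr(s, 2501, 4500)),
              substr(s, 4501, 7000))
  a <- anchor_matches(s, t, min_anchor_len = 500L)
  rev <- a[a$orientation == "reverse", ]
  expect_equal(nrow(rev), 1L)
  expect_lt(abs(rev$q_start - 2501L), 20L)
  expect_lt(abs(rev$q_end - 4500L), 20L)
  expect_equal(nrow(a[a$orientation == "forward", ]), 2L)
})

test_that("no anchors arise inside a diverged noise segment", {
  set.seed(63)
  s <- rseq(10000)
  noisy <- paste0(substr(s, 1, 4000), mut(substr(s, 4001, 6000), 0.40),
                  substr(s, 6001, 10000))
  a <- anchor_matches(s, noisy, min_anchor_len = 300L)
  # windowed identity oracle: the mutated span is far below 0.90 everywhere
  sv <- strsplit(s, "")[[1]]; nv <- strsplit(noisy, "")[[1]]
  wid <- vapply(seq(4001, 5700, by = 100), function(p)
    mean(sv[p:(p + 299)] == nv[p:(p + 299)]), numeric(1))
  expect_true(all(wid < 0.90))
  inside <- a$q_start >= 4100 & a$q_end <= 5900
  expect_false(any(inside))
})

test_that("planted events classify with near-exact boundaries", {
  run_case <- function(type, size, seed) {
    set.seed(seed)
    base_len <- max(20000L, 6L * size)
    anc <- rseq(base_len)
    query <- mut(anc, 0.01)
    target <- mut(anc, 0.01)
    pe <- plant_event(asm1(query, "Q"), type, size, chrom = "c1",
                      position = base_len %/% 2L)
    query <- pe$assembly$chromosomes[["c1"]]
    anchors <- anchor_matches(query, target, min_anchor_len = 300L)
    ev <- chain_and_classify(anchors, nchar(query), nchar(target),
                             min_event_size = 500L, query_seq = query,
                             target_seq = target)
    list(events = ev, truth = pe$truth)
  }
  # deletion planted in the query: the classifier reports the target span
  r <- run_case("deletion", 2000L, 611)
  expect_equal(nrow(r$events), 1L)
  expect_equal(r$events$event_type, "deletion")
  expect_lt(abs(r$events$size - 2000L), 50L)
  expect_lt(abs(r$events$t_start - r$truth$start), 50L)

  r <- run_case("inversion", 3000L, 612)
  expect_equal(r$events$event_type, "inversion")
  expect_lt(abs(r$events$q_start - r$truth$start), 300L)
  expect_lt(abs(r$events$q_end - r$truth$end), 300L)

  r <- run_case("insertion", 2000L, 613)
  expect_equal(r$events$event_type, "insertion")
  expect_match(r$events$note, "introgression")

  r <- run_case("duplication", 1500L, 614)
  expect_equal(r$events$event_type, "duplication")
  expect_equal(r$events$size, 1501L, tolerance = 0.05)
})

test_that("a novel segment plus a duplicated block yield both event types", {
  set.seed(64)
  anc <- rseq(30000)
  target <- mut(anc, 0.01)
  query <- mut(anc, 0.01)
  # novel 2-kb insertion at 10 kb and a 1.5-kb duplicated block at 20 kb
  pe1 <- plant_event(asm1(query, "Q"), "insertion", 2000L, chrom = "c1",
                     position = 10000L)
  pe2 <- plant_event(pe1$assembly, "duplication", 1500L, chrom = "c1",
                     position = 20000L)
  query <- pe2$assembly$chromosomes[["c1"]]
  anchors <- anchor_matches(query, target, min_anchor_len = 300L)
  ev <- chain_and_classify(anchors, nchar(query), nchar(target),
                           min_event_size = 500L, query_seq = query,
                           target_seq = target)
  expect_setequal(ev$event_type, c("insertion", "duplication"))
  ins <- ev[ev$event_type == "insertion", ]
  expect_match(ins$note, "introgression")
})

test_that("self-walk reports no events", {
  set.seed(65)
  src <- asm1(rseq(40000), "S")
  site <- list(site_id = "x", chrom = "c1", start = 20000L, end = 20300L)
  w <- chromosome_walk(site, src, src)
  expect_equal(w$state, "resolved")
  expect_equal(nrow(w$events), 0L)
  expect_lte(w$window_used, 5001L)
})

test_that("a locus inside a deleted region forces window expansion", {
  set.seed(66)
  anc <- rseq(40000)
  src <- asm1(anc, "S")
  tgt_seq <- mut(anc, 0.02)
  tgt_seq <- paste0(substr(tgt_seq, 1, 16000), substr(tgt_seq, 24001, 40000))
  tgt <- asm1(tgt_seq, "T")
  site <- list(site_id = "x", chrom = "c1", start = 20000L, end = 20300L)
  w <- chromosome_walk(site, src, tgt)
  expect_equal(w$state, "resolved")
  expect_gt(w$window_used, 5001L)  # expanded at least once
  expect_equal(nrow(w$events), 1L)
  # the event spans the locus in query-window coordinates
  qoff <- (site$start + site$end) %/% 2L - w$window_used %/% 2L
  expect_lte(w$events$q_start + qoff, site$start)
  expect_gte(w$events$q_end + qoff, site$end)
  expect_equal(w$events$size, 8000L, tolerance = 0.01)
})

test_that("a translocated context is found by the whole-genome fallback", {
  set.seed(67)
  anc <- rseq(40000)
  src <- asm1(anc, "S")
  tgt <- genome_assembly("T", c(c1 = rseq(30000), c7 = mut(anc, 0.02)))
  site <- list(site_id = "x", chrom = "c1", start = 20000L, end = 20300L)
  w <- chromosome_walk(site, src, tgt)
  expect_equal(w$target_chrom, "c7")
  expect_true(w$translocated)
  expect_equal(w$state, "resolved")
})

test_that("anchors, events and residual account for the walked window", {
  set.seed(68)
  anc <- rseq(40000)
  src <- asm1(anc, "S")
  pe <- plant_event(asm1(mut(anc, 0.02), "T"), "deletion", 3000L,
                    chrom = "c1", position = 18000L)
  # deletion in target = query span unmatched; walk still resolves
  w <- chromosome_walk(list(site_id = "x", chrom = "c1", start = 19000L,
                            end = 19300L), src, pe$assembly,
                       start_window = 15000L)
  covered <- sum(w$anchors$q_end - w$anchors$q_start + 1) +
    sum(w$events$size[!is.na(w$events$q_start)]) + w$residual_unexplained
  expect_equal(covered, w$window_used, tolerance = 0.01)
})
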