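#' Dot-plot style anchor matches between two sequences
#'
#' Finds maximal local matches on both orientations above length/identity
#' thresholds by exact k-mer anchoring on diagonals with x-drop extension;
#' overlapping same-diagonal matches are merged. Two presets mirror common
#' use: genome scale (`min_anchor_len = 1000`, 90% identity, the usual
#' dot-plot setting for megabase loci) and desk scale
#' (`min_anchor_len = 300`) for kilobase test problems.
#'
#' @param query_seq,target_seq nucleotide strings.
#' @param min_anchor_len minimum anchor length (bp).
#' @param min_anchor_identity minimum anchor identity.
#' @param k anchor seed length.
#' @return data.frame: `q_start`, `q_end`, `t_start`, `t_end` (1-based
#'   inclusive, forward target coordinates), `orientation`
#'   (`"forward"`/`"reverse"`), `length`, `identity`.
#' @export
anchor_matches <- function(query_seq, target_seq, min_anchor_len = 1000L,
                           min_anchor_identity = 0.90, k = 14L) {
  if (nchar(query_seq) < min_anchor_len || nchar(target_seq) < min_anchor_len)
    return(empty_anchors())
  fw <- cpp_anchors(query_seq, target_seq, k, min_anchor_len,
                    min_anchor_identity)
  fw$orientation <- rep("forward", nrow(fw))
  rc <- cpp_anchors(query_seq, revcomp(target_seq), k, min_anchor_len,
                    min_anchor_identity)
  tlen <- nchar(target_seq)
  if (nrow(rc)) {
    tmp <- rc$s_start
    rc$s_start <- tlen - rc$s_end + 1L
    rc$s_end <- tlen - tmp + 1L
  }
  rc$orientation <- rep("reverse", nrow(rc))
  out <- rbind(fw, rc)
  names(out)[names(out) == "s_start"] <- "t_start"
  names(out)[names(out) == "s_end"] <- "t_end"
  out <- out[order(out$q_start, out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_anchors <- function() {
  data.frame(q_start = integer(0), q_end = integer(0), t_start = integer(0),
             t_end = integer(0), length = integer(0), identity = numeric(0),
             orientation = character(0), stringsAsFactors = FALSE)
}

# weighted longest-increasing-subsequence chain over forward anchors:
# maximises summed length*identity subject to consistent query and target
# order with bounded overlap
main_chain <- function(anchors, max_overlap = 50L) {
  fw <- which(anchors$orientation == "forward")
  if (length(fw) == 0L) return(integer(0))
  a <- anchors[fw, , drop = FALSE]
  ord <- order(a$q_start, a$t_start)
  a <- a[ord, , drop = FALSE]
  n <- nrow(a)
  w <- a$length * a$identity
  best <- w
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (a$q_start[i] >= a$q_end[j] - max_overlap &&
          a$t_start[i] >= a$t_end[j] - max_overlap &&
          best[j] + w[i] > best[i]) {
        best[i] <- best[j] + w[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  chain <- integer(0)
  while (i > 0L) { chain <- c(i, chain); i <- prev[i] }
  fw[ord][chain]
}

#' Chain anchors and classify rearrangement events
#'
#' Forward anchors are chained by collinearity (weighted by
#' length x identity); gaps between consecutive chain anchors are then
#' typed: a query gap with target continuity is an insertion in the query
#' (tagged `"duplication"` if the gap sequence re-matches a target span
#' already covered by the chain, `"possible introgression"` if it matches
#' nowhere in the target); a target gap with query continuity is a deletion
#' (sequence lost from the query lineage, reported with the target span); a
#' gap on both sides covered by reverse-orientation anchors is an
#' inversion; a gap on both sides otherwise is a replacement, reported as a
#' deletion plus an insertion. Events below `min_event_size` are ignored.
#'
#' @param anchors data.frame from [anchor_matches()].
#' @param query_len,target_len sequence lengths (bp).
#' @param min_event_size smallest reported event (bp).
#' @param query_seq,target_seq optional sequences enabling the
#'   duplication/introgression re-match of gap sequence against the target.
#' @param min_anchor_len,min_anchor_identity thresholds for the re-match.
#' @return data.frame of events: `event_type`, `q_start`, `q_end`,
#'   `t_start`, `t_end` (NA when absent), `size`, `note`.
#' @export
chain_and_classify <- function(anchors, query_len, target_len,
                               min_event_size = 500L, query_seq = NULL,
                               target_seq = NULL, min_anchor_len = 300L,
                               min_anchor_identity = 0.90) {
  events <- list()
  add <- function(type, qs, qe, ts, te, size, note = "") {
    events[[length(events) + 1L]] <<- data.frame(
      event_type = type, q_start = qs, q_end = qe, t_start = ts, t_end = te,
      size = size, note = note, stringsAsFactors = FALSE)
  }
  chain_idx <- main_chain(anchors)
  chain <- anchors[chain_idx, , drop = FALSE]
  off <- anchors[setdiff(seq_len(nrow(anchors)), chain_idx), , drop = FALSE]
  if (nrow(chain) == 0L) {
    return(do.call(rbind, events) %||% empty_events())
  }
  # gaps between consecutive anchors only (ends handled by walk windows)
  for (i in seq_len(nrow(chain) - 1L)) {
    qgap_s <- chain$q_end[i] + 1L; qgap_e <- chain$q_start[i + 1L] - 1L
    tgap_s <- chain$t_end[i] + 1L; tgap_e <- chain$t_start[i + 1L] - 1L
    qgap <- qgap_e - qgap_s + 1L
    tgap <- tgap_e - tgap_s + 1L
    big_q <- qgap >= min_event_size
    big_t <- tgap >= min_event_size
    if (!big_q && !big_t) next
    # reverse anchors covering both gaps -> inversion
    rev_cov_q <- rev_cov_t <- 0L
    if (nrow(off)) {
      rv <- off[off$orientation == "reverse" &
                off$q_start <= qgap_e & off$q_end >= qgap_s, , drop = FALSE]
      if (nrow(rv)) {
        rev_cov_q <- sum(pmin(rv$q_end, qgap_e) - pmax(rv$q_start, qgap_s) + 1L)
        rev_cov_t <- sum(pmin(rv$t_end, tgap_e) - pmax(rv$t_start, tgap_s) + 1L)
      }
    }
    if (big_q && big_t && rev_cov_q > 0.5 * qgap && rev_cov_t > 0.3 * tgap) {
      add("inversion", qgap_s, qgap_e, tgap_s, tgap_e, qgap)
      next
    }
    if (big_q && !big_t) {
      cls <- classify_query_gap(qgap_s, qgap_e, chain, off, query_seq,
                                target_seq, min_anchor_len,
                                min_anchor_identity)
      add(cls$type, qgap_s, qgap_e,
          cls$ts %||% NA_integer_, cls$te %||% NA_integer_, qgap, cls$note)
      next
    }
    if (big_t && !big_q) {
      cls <- classify_target_gap(tgap_s, tgap_e, chain, off)
      add(cls$type, NA_integer_, NA_integer_, tgap_s, tgap_e, tgap, cls$note)
      next
    }
    # both sides large, not an inversion: replacement
    add("deletion", NA_integer_, NA_integer_, tgap_s, tgap_e, tgap,
        "replacement: target span absent from query")
    add("insertion", qgap_s, qgap_e, NA_integer_, NA_integer_, qgap,
        "replacement: query span absent from target")
  }
  (do.call(rbind, events) %||% empty_events())
}

# a large query gap: duplication if its sequence re-matches a chain-covered
# target span; insertion otherwise, "possible introgression" when the gap
# matches nowhere in the target
classify_query_gap <- function(qs, qe, chain, off, query_seq, target_seq,
                               min_anchor_len, min_anchor_identity) {
  cand <- off[off$q_start <= qe & off$q_end >= qs, , drop = FALSE]
  matches <- cand
  if (nrow(cand) == 0L && !is.null(query_seq) && !is.null(target_seq)) {
    gapseq <- substr(query_seq, qs, qe)
    rematch <- anchor_matches(gapseq, target_seq,
                              min_anchor_len = min(min_anchor_len,
                                                   max(50L, nchar(gapseq) %/% 2L)),
                              min_anchor_identity = min_anchor_identity)
    if (nrow(rematch)) {
      rematch$q_start <- rematch$q_start + qs - 1L
      rematch$q_end <- rematch$q_end + qs - 1L
      matches <- rematch
    }
  }
  if (nrow(matches)) {
    cov <- sum(pmin(matches$q_end, qe) - pmax(matches$q_start, qs) + 1L)
    if (cov >= 0.5 * (qe - qs + 1L)) {
      onto_chain <- any(matches$t_start <= chain$t_end &
                        matches$t_end >= chain$t_start)
      m <- matches[order(-matches$length * matches$identity), , drop = FALSE][1, ]
      if (onto_chain)
        return(list(type = "duplication", ts = m$t_start, te = m$t_end,
                    note = "query copy of a chain-covered target span"))
      return(list(type = "insertion", ts = m$t_start, te = m$t_end,
                  note = "matches unanchored target span (moved copy)"))
    }
  }
  list(type = "insertion", ts = NULL, te = NULL,
       note = "possible introgression: no homology in target")
}

# a large target gap: duplication (in target) if covered by off-chain
# anchors whose query span is chain-covered; deletion otherwise
classify_target_gap <- function(ts, te, chain, off) {
  if (nrow(off)) {
    cand <- off[off$orientation == "forward" &
                off$t_start <= te & off$t_end >= ts, , drop = FALSE]
    if (nrow(cand)) {
      cov <- sum(pmin(cand$t_end, te) - pmax(cand$t_start, ts) + 1L)
      onto_chain <- any(cand$q_start <= chain$q_end &
                        cand$q_end >= chain$q_start)
      if (cov >= 0.5 * (te - ts + 1L) && onto_chain)
        return(list(type = "duplication",
                    note = "extra target copy of a chain-covered query span"))
    }
  }
  list(type = "deletion", note = "target span absent from query")
}

empty_events <- function() {
  data.frame(event_type = character(0), q_start = integer(0),
             q_end = integer(0), t_start = integer(0), t_end = integer(0),
             size = integer(0), note = character(0), stringsAsFactors = FALSE)
}

#' Chromosome walk of a polymorphic locus against a counterpart genome
#'
#' The query window around the locus grows stepwise until anchors place
#' both of its ends in the target on a single chromosome, or the window
#' cap is reached. The same-name target chromosome is searched first; if it
#' yields no anchors the whole target genome is searched (translocated
#' context is noted). The final window is dot-plotted and classified.
#'
#' @param site site row (list-like with `chrom`, `start`, `end`).
#' @param source source `GenomeAssembly` (carries the locus).
#' @param target counterpart `GenomeAssembly`.
#' @param start_window,step,max_window walk geometry in bp; the window is
#'   the total width centred on the locus and grows by `step` per round.
#' @param min_anchor_len,min_anchor_identity,min_event_size see
#'   [anchor_matches()] / [chain_and_classify()]; defaults are the desk
#'   preset, pass `preset = "genome"` for 1000-bp anchors.
#' @param preset `"desk"` (300-bp anchors) or `"genome"` (1000-bp anchors).
#' @return a `WalkReport`: list with `locus`, `window_used`, `state`
#'   (`"resolved"`/`"unresolved"`), `target_chrom`, `translocated`,
#'   `anchors`, `events`, `residual_unexplained`.
#' @export
chromosome_walk <- function(site, source, target, start_window = 5000L,
                            step = 10000L, max_window = 100000L,
                            preset = c("desk", "genome"),
                            min_anchor_len = NULL, min_anchor_identity = 0.90,
                            min_event_size = 500L) {
  preset <- match.arg(preset)
  if (is.null(min_anchor_len))
    min_anchor_len <- if (preset == "desk") 300L else 1000L
  chrom_len <- nchar(source$chromosomes[[site$chrom]])
  mid <- (site$start + site$end) %/% 2L
  window <- start_window
  same <- intersect(site$chrom, names(target$chromosomes))
  result <- NULL
  repeat {
    qs <- max(1L, mid - window %/% 2L)
    qe <- min(chrom_len, mid + window %/% 2L)
    qseq <- substr(source$chromosomes[[site$chrom]], qs, qe)
    search_space <- if (length(same)) same else names(target$chromosomes)
    placed <- NULL
    translocated <- FALSE
    for (pass in 1:2) {
      for (tc in search_space) {
        anc <- anchor_matches(qseq, target$chromosomes[[tc]],
                              min_anchor_len, min_anchor_identity)
        if (nrow(anc) == 0L) next
        qlen <- nchar(qseq)
        left_ok <- any(anc$q_start <= 0.2 * qlen)
        right_ok <- any(anc$q_end >= 0.8 * qlen)
        if (is.null(placed) || (left_ok && right_ok)) {
          placed <- list(chrom = tc, anchors = anc, q_offset = qs - 1L,
                         both_ends = left_ok && right_ok)
        }
        if (left_ok && right_ok) break
      }
      if (!is.null(placed) || pass == 2L) break
      # whole-genome fallback
      search_space <- setdiff(names(target$chromosomes), same)
      translocated <- TRUE
      if (length(search_space) == 0L) break
    }
    if (!is.null(placed) && placed$both_ends) {
      result <- c(placed, list(window = qe - qs + 1L,
                               translocated = translocated &&
                                 !(placed$chrom %in% same)))
      break
    }
    if (window >= max_window) {
      if (!is.null(placed))
        result <- c(placed, list(window = qe - qs + 1L,
                                 translocated = translocated &&
                                   !(placed$chrom %in% same)))
      break
    }
    window <- min(max_window, window + step)
  }
  locus <- list(site_id = site$site_id %||% NA_character_,
                chrom = site$chrom, start = site$start, end = site$end)
  if (is.null(result)) {
    return(structure(list(locus = locus, window_used = window,
                          state = "unresolved", target_chrom = NA_character_,
                          translocated = FALSE, anchors = empty_anchors(),
                          events = empty_events(),
                          residual_unexplained = window),
                     class = "WalkReport"))
  }
  qs <- max(1L, mid - result$window %/% 2L)
  qe <- min(chrom_len, mid + result$window %/% 2L)
  qseq <- substr(source$chromosomes[[site$chrom]], qs, qe)
  tseq <- target$chromosomes[[result$chrom]]
  events <- chain_and_classify(result$anchors, nchar(qseq), nchar(tseq),
                               min_event_size, query_seq = qseq,
                               target_seq = tseq,
                               min_anchor_len = min_anchor_len,
                               min_anchor_identity = min_anchor_identity)
  # residual: query bases neither anchor-covered nor inside an event span
  covered <- rep(FALSE, nchar(qseq))
  for (i in seq_len(nrow(result$anchors)))
    covered[result$anchors$q_start[i]:result$anchors$q_end[i]] <- TRUE
  ev_q <- events[!is.na(events$q_start), , drop = FALSE]
  for (i in seq_len(nrow(ev_q)))
    covered[ev_q$q_start[i]:ev_q$q_end[i]] <- TRUE
  structure(list(locus = locus, window_used = qe - qs + 1L,
                 state = if (!is.null(result$both_ends) && result$both_ends)
                   "resolved" else "partial",
                 target_chrom = result$chrom,
                 translocated = isTRUE(result$translocated),
                 anchors = result$anchors, events = events,
                 residual_unexplained = sum(!covered)),
            class = "WalkReport")
}

#' Serialize a walk report to JSON
#' @param report a `WalkReport`.
#' @param path output file.
#' @export
write_walk_report <- function(report, path) {
  jsonlite::write_json(list(
    locus = report$locus, window_used = report$window_used,
    state = report$state, target_chrom = report$target_chrom,
    translocated = report$translocated, events = report$events,
    residual_unexplained = report$residual_unexplained),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
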