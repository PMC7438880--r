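#' Default parameters for consensus-driven element scanning
#'
#' The published E-value style cutoff of database search tools depends on
#' database size; this scanner instead uses explicit identity/coverage
#' thresholds anchored to the classical TE-family 80/80-style rule (at least
#' 80% identity), plus a raw score floor, which makes results deterministic
#' and independent of assembly size.
#'
#' @param k exact seed k-mer length.
#' @param match,mismatch match/mismatch scores.
#' @param gap_open,gap_ext positive gap costs; a gap of length L costs
#'   `gap_open + L * gap_ext`.
#' @param min_identity minimum fraction of identities over aligned columns
#'   (gap columns count against identity; N counts as mismatch).
#' @param min_coverage minimum fraction of the consensus covered by the
#'   alignment; the default 0.30 keeps truncated copies down to ~93 bp of a
#'   ~300 bp consensus.
#' @param min_score raw alignment score floor.
#' @param full_length_threshold consensus coverage at or above which a copy
#'   is called full-length; the short class of the family tops out around
#'   80% of consensus length, so 0.85 separates the two classes.
#' @return a named list of parameters.
#' @export
scan_params <- function(k = 12L, match = 2, mismatch = -3, gap_open = 5,
                        gap_ext = 2, min_identity = 0.80, min_coverage = 0.30,
                        min_score = 50, full_length_threshold = 0.85) {
  list(k = as.integer(k), match = match, mismatch = mismatch,
       gap_open = gap_open, gap_ext = gap_ext, min_identity = min_identity,
       min_coverage = min_coverage, min_score = min_score,
       full_length_threshold = full_length_threshold)
}

#' Read TE family consensus sequences from FASTA
#'
#' @param path FASTA with one record per family; record names become family
#'   names.
#' @return list of `TEConsensus` records (`family_name`, `sequence`, `length`).
#' @export
read_consensus <- function(path) {
  asm <- read_fasta(path)
  lapply(names(asm$chromosomes), function(n)
    te_consensus(n, asm$chromosomes[[n]]))
}

#' @rdname read_consensus
#' @param family_name family label.
#' @param sequence consensus nucleotide string.
#' @export
te_consensus <- function(family_name, sequence) {
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) == 0L) stop("consensus sequence must be non-empty")
  structure(list(family_name = family_name, sequence = sequence,
                 length = nchar(sequence)), class = "TEConsensus")
}

#' Scan an assembly for copies of a consensus sequence
#'
#' Seed-and-extend homology search: exact k-mer seeds on both strands are
#' clustered by diagonal and each candidate region is resolved by full
#' affine-gap local alignment of the consensus against it. Each reported
#' site is the maximal-scoring local extension of a chained seed set.
#'
#' @param consensus a `TEConsensus` (see [te_consensus()]).
#' @param assembly a `GenomeAssembly`.
#' @param params see [scan_params()].
#' @return data.frame of insertion sites sorted by (chromosome, start):
#'   `site_id` (empty until [name_sites()]), `species`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`, `identity`, `coverage`,
#'   `length_class`, `subfamily`, `score`, `sequence` (element-oriented).
#' @export
scan_genome <- function(consensus, assembly, params = scan_params()) {
  if (consensus$length < params$k)
    stop("consensus shorter than seed length k")
  fwd <- consensus$sequence
  rev <- revcomp(fwd)
  res <- list()
  for (chrom in names(assembly$chromosomes)) {
    subject <- assembly$chromosomes[[chrom]]
    hits <- cpp_scan(c(fwd, rev), subject, params$k, params$match,
                     params$mismatch, params$gap_open, params$gap_ext,
                     params$min_score)
    if (nrow(hits) == 0L) next
    hits$identity <- hits$matches / hits$aln_len
    hits$coverage <- (hits$q_end - hits$q_start + 1L) / consensus$length
    keep <- hits$identity >= params$min_identity &
      hits$coverage >= params$min_coverage
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits) == 0L) next
    strand <- ifelse(hits$query == 1L, "+", "-")
    seqs <- vapply(seq_len(nrow(hits)), function(i) {
      s <- substr(subject, hits$s_start[i], hits$s_end[i])
      if (strand[i] == "-") revcomp(s) else s
    }, character(1))
    res[[chrom]] <- data.frame(
      site_id = "", species = assembly$species_id, chrom = chrom,
      start = hits$s_start, end = hits$s_end, strand = strand,
      identity = hits$identity, coverage = hits$coverage,
      length_class = ifelse(hits$coverage >= params$full_length_threshold,
                            "full", "short"),
      subfamily = consensus$family_name, score = hits$score,
      sequence = seqs, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else empty_sites()
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

empty_sites <- function() {
  data.frame(site_id = character(0), species = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), identity = numeric(0),
             coverage = numeric(0), length_class = character(0),
             subfamily = character(0), score = numeric(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Remove redundant overlapping hits
#'
#' When two sites overlap by more than `overlap_fraction` of the shorter
#' site's length only the higher-scoring one is kept (ties: higher identity,
#' then leftmost start). Idempotent.
#'
#' @param sites data.frame from [scan_genome()] (one assembly).
#' @param overlap_fraction overlap threshold relative to the shorter site.
#' @return filtered data.frame, sorted by (chromosome, start).
#' @export
dedup_hits <- function(sites, overlap_fraction = 0.25) {
  if (nrow(sites) <= 1L) return(sites)
  ord <- order(-sites$score, -sites$identity, sites$start)
  keep <- logical(nrow(sites))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (sites$chrom[i] != sites$chrom[j]) next
      ov <- min(sites$end[i], sites$end[j]) - max(sites$start[i], sites$start[j]) + 1L
      if (ov <= 0L) next
      shorter <- min(sites$end[i] - sites$start[i], sites$end[j] - sites$start[j]) + 1L
      if (ov > overlap_fraction * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- sites[keep, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Length class of a site
#'
#' @param coverage consensus coverage fraction of the site.
#' @param full_length_threshold see [scan_params()].
#' @return `"full"` or `"short"`.
#' @export
classify_length <- function(coverage, full_length_threshold = 0.85) {
  ifelse(coverage >= full_length_threshold, "full", "short")
}

#' Assign field-style insertion names
#'
#' Names follow the sub-genome letter + chromosome number + positional
#' serial convention, with an `"S"` suffix for short (truncated) copies and
#' the species label as prefix, e.g. `"DW_A4-3S"`.
#'
#' @param sites site data.frame.
#' @param assembly the assembly the sites came from (for sub-genome labels).
#' @return sites with `site_id` filled in.
#' @export
name_sites <- function(sites, assembly) {
  if (nrow(sites) == 0L) return(sites)
  sg <- assembly$subgenome_of[sites$chrom]
  num <- sub("\\D*(\\d+).*", "\\1", sites$chrom)
  num[!grepl("\\d", sites$chrom)] <- ""
  key <- paste0(sg, num)
  ord <- order(key, sites$start)
  serial <- integer(nrow(sites))
  serial[ord] <- stats::ave(seq_along(ord), key[ord], FUN = seq_along)
  sites$site_id <- paste0(sites$species, "_", key, "-", serial,
                          ifelse(sites$length_class == "short", "S", ""))
  sites
}

#' Write sites to TSV (and optionally BED6)
#'
#' @param sites site data.frame.
#' @param path TSV output path.
#' @param bed optional BED6 output path.
#' @param params parameter list echoed into the header comment.
#' @export
write_sites <- function(sites, path, bed = NULL, params = list()) {
  cols <- setdiff(names(sites), "sequence")
  write_report_tsv(sites[, cols, drop = FALSE], path, params)
  if (!is.null(bed))
    write_bed(data.frame(chrom = sites$chrom, start = sites$start,
                         end = sites$end, name = sites$site_id,
                         score = sites$score, strand = sites$strand), bed)
  invisible(path)
}
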