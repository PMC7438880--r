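#' Extract the flanking sequences of an insertion site
#'
#' Flanks are junction-anchored on the genome forward strand regardless of
#' element orientation: the left flank is the `window` bases ending
#' immediately before the element start, the right flank the `window` bases
#' beginning immediately after the element end. Requests clipped at contig
#' ends are flagged per side.
#'
#' @param site one row of a site data.frame (list-like with `chrom`,
#'   `start`, `end`).
#' @param assembly the `GenomeAssembly` the site belongs to.
#' @param window flank width in bp.
#' @return a `FlankedLocus`: list with `site`, `window`, `left_flank`,
#'   `right_flank`, `clipped_left`, `clipped_right`.
#' @export
extract_flanks <- function(site, assembly, window) {
  if (!site$chrom %in% names(assembly$chromosomes))
    stop("unknown chromosome: ", site$chrom)
  left <- extract_region(assembly, site$chrom, site$start - window,
                         site$start - 1L, "+", clip = TRUE)
  right <- extract_region(assembly, site$chrom, site$end + 1L,
                          site$end + window, "+", clip = TRUE)
  structure(list(site = site, window = window,
                 left_flank = as.character(left),
                 right_flank = as.character(right),
                 clipped_left = attr(left, "clipped"),
                 clipped_right = attr(right, "clipped")),
            class = "FlankedLocus")
}

count_mismatches <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

#' Detect a target site duplication at an insertion junction
#'
#' Returns the longest length `L` in `[2, max_tsd_len]` such that the
#' length-`L` suffix of the left flank matches the length-`L` prefix of the
#' right flank with at most `max_mismatches` mismatches (`N` counts as a
#' mismatch). Single-base duplications are not reported: one base repeats by
#' chance at a quarter of all junctions. With `junction_slide > 0` the
#' element boundary is additionally slid by up to that many bases on each
#' side and the best (longest, then fewest mismatches) TSD is reported with
#' an `adjusted` flag — truncated copies with uncertain boundaries otherwise
#' never show their duplication.
#'
#' @param flanked a `FlankedLocus` (window must be at least `max_tsd_len`).
#' @param max_tsd_len longest duplication length considered.
#' @param max_mismatches allowed mismatches between the two copies.
#' @param junction_slide boundary slack in bp (0 = exact junction only).
#' @return a `TSD` (list with `motif`, `length`, `mismatches`, `adjusted`)
#'   or `NULL` if no duplication of length >= 2 qualifies.
#' @export
detect_tsd <- function(flanked, max_tsd_len = 10L, max_mismatches = 0L,
                       junction_slide = 0L) {
  if (flanked$window < max_tsd_len)
    stop("flank window smaller than max_tsd_len")
  scan_at <- function(left, right) {
    best <- NULL
    lmax <- min(max_tsd_len, nchar(left), nchar(right))
    for (L in seq_len(lmax)) {
      if (L < 2L) next
      suf <- substr(left, nchar(left) - L + 1L, nchar(left))
      pre <- substr(right, 1L, L)
      mm <- count_mismatches(suf, pre)
      if (mm <= max_mismatches) best <- list(motif = suf, length = L,
                                             mismatches = mm)
    }
    best
  }
  best <- scan_at(flanked$left_flank, flanked$right_flank)
  if (!is.null(best)) best$adjusted <- FALSE
  if (junction_slide > 0L) {
    site <- flanked$site
    elem <- if (!is.null(site$sequence) && nzchar(site$sequence)) {
      if ((site$strand %||% "+") == "-") revcomp(site$sequence) else site$sequence
    } else NULL
    for (dl in -junction_slide:junction_slide) {
      for (dr in -junction_slide:junction_slide) {
        if (dl == 0L && dr == 0L) next
        left <- shift_junction(flanked$left_flank, elem, dl, side = "left")
        right <- shift_junction(flanked$right_flank, elem, dr, side = "right")
        cand <- scan_at(left, right)
        if (!is.null(cand) &&
            (is.null(best) || cand$length > best$length ||
             (cand$length == best$length && cand$mismatches < best$mismatches))) {
          cand$adjusted <- TRUE
          best <- cand
        }
      }
    }
  }
  best
}

# move the element boundary by d bases: positive d moves the junction into
# the element (flank gains element bases), negative d trims the flank
shift_junction <- function(flank, elem, d, side) {
  if (d == 0L || is.null(elem)) {
    if (d < 0L && side == "left") return(substr(flank, 1L, nchar(flank) + d))
    if (d < 0L && side == "right") return(substr(flank, 1L - d, nchar(flank)))
    return(flank)
  }
  if (side == "left") {
    if (d > 0L) paste0(flank, substr(elem, 1L, d))
    else substr(flank, 1L, nchar(flank) + d)
  } else {
    if (d > 0L) paste0(substr(elem, nchar(elem) - d + 1L, nchar(elem)), flank)
    else substr(flank, 1L - d, nchar(flank))
  }
}

#' Position frequency matrix over a set of TSD motifs
#'
#' Motifs are right-padded to the longest length; the pad symbol is excluded
#' from the frequencies, so every column sums to 1 over its contributing
#' symbols. This is the numeric backing of a sequence logo.
#'
#' @param tsds list of `TSD` records (or character vector of motifs).
#' @return list with `matrix` (positions x A/C/G/T fractions) and `depth`
#'   (contributing motifs per position).
#' @export
tsd_logo <- function(tsds) {
  motifs <- if (is.character(tsds)) tsds
            else vapply(tsds, function(t) t$motif, character(1))
  if (length(motifs) == 0L) stop("no motifs supplied")
  width <- max(nchar(motifs))
  mat <- matrix(0, nrow = width, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  depth <- integer(width)
  for (m in motifs) {
    ch <- strsplit(m, "")[[1]]
    for (p in seq_along(ch)) {
      if (ch[p] %in% colnames(mat)) {
        mat[p, ch[p]] <- mat[p, ch[p]] + 1
        depth[p] <- depth[p] + 1L
      }
    }
  }
  contributing <- depth > 0L
  mat[contributing, ] <- mat[contributing, , drop = FALSE] / depth[contributing]
  list(matrix = mat, depth = depth)
}

#' Run TSD detection over a table of sites
#'
#' @param sites site data.frame.
#' @param assembly the assembly the sites belong to.
#' @param window flank window (bp).
#' @param max_tsd_len,max_mismatches,junction_slide see [detect_tsd()].
#' @return data.frame with one row per site: `site_id`, `length_class`,
#'   `tsd_motif`, `tsd_length`, `tsd_mismatches`, `adjusted` (NA where no
#'   TSD was found).
#' @export
tsd_table <- function(sites, assembly, window = 10L, max_tsd_len = 10L,
                      max_mismatches = 0L, junction_slide = 0L) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    fl <- extract_flanks(as.list(sites[i, ]), assembly, window)
    tsd <- detect_tsd(fl, max_tsd_len, max_mismatches, junction_slide)
    data.frame(site_id = sites$site_id[i],
               length_class = sites$length_class[i],
               tsd_motif = if (is.null(tsd)) NA_character_ else tsd$motif,
               tsd_length = if (is.null(tsd)) NA_integer_ else tsd$length,
               tsd_mismatches = if (is.null(tsd)) NA_integer_ else tsd$mismatches,
               adjusted = if (is.null(tsd)) NA else tsd$adjusted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
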