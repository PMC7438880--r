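#' Progressive multiple sequence alignment
#'
#' Classic progressive scheme: a guide tree is built from fractional common
#' k-mer distances by neighbor joining, then profiles are merged bottom-up
#' with affine-gap global profile-profile alignment (match +2, mismatch -3,
#' gap open 5, gap extend 2 by default, a gap of length L costing
#' `open + L*ext`). For two sequences this reduces exactly to standard
#' global pairwise alignment. Deterministic given input order.
#'
#' @param seqs named character vector of nucleotide sequences (>= 1).
#' @param match,mismatch,gap_open,gap_ext alignment scoring.
#' @param guide_k k-mer length for the guide-tree distance.
#' @return named character vector of equal-length gapped rows, in the input
#'   order, with attribute `score` for the pairwise case.
#' @export
progressive_msa <- function(seqs, match = 2, mismatch = -3, gap_open = 5,
                            gap_ext = 2, guide_k = 6L) {
  n <- length(seqs)
  if (n == 0L) stop("no sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 1L) return(seqs)
  if (n == 2L) {
    al <- cpp_pair_global(seqs[[1]], seqs[[2]], match, mismatch, gap_open,
                          gap_ext, strings = TRUE)
    out <- stats::setNames(c(al$a_aln, al$b_aln), names(seqs))
    attr(out, "score") <- al$score
    return(out)
  }
  D <- kmer_distance_matrix(seqs, k = guide_k)
  guide <- ape::root(ape::nj(stats::as.dist(D)), outgroup = names(seqs)[1],
                     resolve.root = TRUE)
  merge_profiles <- function(a, b) {
    ops <- cpp_profile_align(unname(a), unname(b), match, mismatch, gap_open,
                             gap_ext)
    apply_ops <- function(rows, consume) {
      opv <- strsplit(ops, "")[[1]]
      take <- opv %in% consume
      vapply(rows, function(r) {
        ch <- strsplit(r, "")[[1]]
        out <- character(length(opv))
        out[!take] <- "-"
        out[take] <- ch
        paste(out, collapse = "")
      }, character(1))
    }
    c(apply_ops(a, c("M", "A")), apply_ops(b, c("M", "B")))
  }
  # post-order traversal of the rooted guide tree, merging child profiles
  align_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    profs <- lapply(kids, function(k) {
      if (k <= length(guide$tip.label)) {
        stats::setNames(seqs[guide$tip.label[k]], guide$tip.label[k])
      } else align_node(k)
    })
    prof <- profs[[1]]
    for (p in profs[-1]) prof <- merge_profiles(prof, p)
    prof
  }
  root <- length(guide$tip.label) + 1L
  out <- align_node(root)
  out[names(seqs)]
}

# fractional common k-mer distance used only for the MSA guide tree
kmer_distance_matrix <- function(seqs, k = 6L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- counts[[i]]; b <- counts[[j]]
      shared <- sum(pmin(a[intersect(names(a), names(b))],
                         b[intersect(names(a), names(b))]))
      denom <- min(sum(a), sum(b))
      D[i, j] <- D[j, i] <- if (denom > 0) 1 - shared / denom else 1
    }
  }
  D
}

#' Majority-rule consensus from an alignment
#'
#' Per column the most frequent non-gap symbol is taken (ties broken
#' alphabetically); the column is emitted only if its non-gap fraction is at
#' least `majority`.
#'
#' @param msa named character vector of equal-length gapped rows.
#' @param majority minimum non-gap fraction for a column to be emitted.
#' @return consensus nucleotide string.
#' @export
consensus_from_msa <- function(msa, majority = 0.5) {
  if (length(msa) == 0L) stop("empty alignment")
  m <- do.call(rbind, strsplit(unname(msa), ""))
  cols <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    nongap <- col[col != "-"]
    if (length(nongap) / length(col) < majority) return("")
    tab <- sort(table(nongap), decreasing = TRUE)
    top <- tab[tab == tab[1]]
    sort(names(top))[1]
  }, character(1))
  paste(cols[cols != ""], collapse = "")
}

#' Assign a sequence to a subfamily by consensus identity
#'
#' The sequence is globally aligned to every family consensus; it is
#' assigned to the family with the highest identity if that identity is at
#' least `min_identity` and beats the runner-up by at least `margin`;
#' otherwise `"unassigned"` (a candidate intermediate between variants).
#'
#' @param seq nucleotide string.
#' @param consensus_set list of `TEConsensus` records.
#' @param min_identity assignment threshold.
#' @param margin required lead over the runner-up.
#' @return family name or `"unassigned"`, with attribute `identities`.
#' @export
classify_subfamily <- function(seq, consensus_set, min_identity = 0.80,
                               margin = 0.03) {
  ids <- vapply(consensus_set, function(cons) {
    al <- cpp_pair_global(seq, cons$sequence, 2, -3, 5, 2, strings = FALSE)
    al$matches / al$aln_len
  }, numeric(1))
  names(ids) <- vapply(consensus_set, function(cons) cons$family_name,
                       character(1))
  ord <- order(-ids)
  out <- if (ids[ord[1]] < min_identity ||
             (length(ids) > 1L && ids[ord[1]] - ids[ord[2]] < margin))
    "unassigned" else names(ids)[ord[1]]
  attr(out, "identities") <- ids
  out
}

#' Pairwise TN93 distance between two aligned rows
#'
#' Tamura-Nei (1993) distance with empirical base frequencies; columns with
#' a gap or N in either row are excluded (pairwise deletion). Computed via
#' the standard distance machinery of `ape`. A log-domain violation
#' (saturated pair) yields `NA` here; [tn93_matrix()] flags such entries and
#' substitutes the largest finite distance plus 10% for tree building.
#'
#' @param row_a,row_b equal-length gapped sequences.
#' @return numeric distance (NA if saturated).
#' @export
tn93_distance <- function(row_a, row_b) {
  tn93_matrix(c(a = row_a, b = row_b), impute_saturated = FALSE)[1, 2]
}

#' TN93 distance matrix for an alignment
#'
#' @param msa named character vector of equal-length gapped rows.
#' @param impute_saturated replace non-finite entries by the maximum finite
#'   distance + 10% (flagged in the `"saturated"` attribute).
#' @return symmetric distance matrix with zero diagonal.
#' @export
tn93_matrix <- function(msa, impute_saturated = TRUE) {
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unname(msa)), "")))
  rownames(bin) <- names(msa)
  D <- as.matrix(ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE))
  sat <- !is.finite(D)
  diag(sat) <- FALSE
  if (impute_saturated && any(sat)) {
    mx <- max(D[is.finite(D)], 0)
    D[sat] <- mx * 1.10
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ on a distance matrix; negative branch lengths are clamped to
#' zero with the deficit moved to the sister branch, so total path lengths
#' are preserved where possible.
#'
#' @param D symmetric distance matrix (>= 3 labelled rows).
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    if (length(sisters)) {
      s <- sisters[1]
      tr$edge.length[s] <- tr$edge.length[s] + deficit
    }
  }
  tr
}

#' Bootstrap support for an alignment-derived NJ tree
#'
#' Columns are resampled with replacement `replicates` times; for each
#' replicate a tree is rebuilt (TN93 + NJ by default) and the support of an
#' internal branch is the percentage of replicate trees containing its
#' bipartition. Branches below `collapse` percent support can be collapsed
#' into multifurcations. Bit-reproducible for a fixed seed.
#'
#' @param msa named character vector of equal-length gapped rows.
#' @param builder function(msa) -> phylo; default TN93 + NJ.
#' @param replicates number of bootstrap replicates.
#' @param seed RNG seed.
#' @param collapse optional support cutoff (percent); `NULL` keeps all
#'   branches.
#' @return the main tree with `node.label` holding percent support.
#' @export
bootstrap_support <- function(msa, builder = NULL, replicates = 100L,
                              seed = 42L, collapse = NULL) {
  if (is.null(builder))
    builder <- function(m) nj_tree(tn93_matrix(m))
  cols <- nchar(msa[[1]])
  if (cols < 1L) stop("alignment has no columns")
  main <- builder(msa)
  rows <- do.call(rbind, strsplit(unname(msa), ""))
  rownames(rows) <- names(msa)
  set.seed(seed)
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    idx <- sample.int(cols, cols, replace = TRUE)
    m2 <- apply(rows[, idx, drop = FALSE], 1, paste, collapse = "")
    reps[[b]] <- tryCatch(builder(m2), error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(reps))
  main$node.label <- as.character(support)
  if (!is.null(collapse)) {
    internal <- which(main$edge[, 2] > length(main$tip.label))
    low <- internal[support[main$edge[internal, 2] -
                              length(main$tip.label)] < collapse]
    main$edge.length[low] <- 0
    main <- ape::di2multi(main, tol = 1e-12)
  }
  main
}

#' Write a tree to newick (supports as internal node labels)
#' @param tree `ape::phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
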