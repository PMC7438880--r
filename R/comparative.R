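#' Parameters for cross-genome locus mapping
#'
#' Flank placement is stricter than family-level homology search because
#' flanks are (near-)unique sequence: default minimum identity 0.90 over at
#' least 0.80 of the flank length, reciprocal-best.
#'
#' @param min_identity minimum identity of a flank placement.
#' @param min_flank_coverage minimum fraction of the flank aligned.
#' @param max_gap maximum distance (bp) between the two placed flanks for a
#'   locus to count as a single placement.
#' @param empty_gap_tolerance maximum inter-flank gap (bp) still called an
#'   empty site; absorbs TSD remnants and small excision footprints.
#' @param element_min_identity,element_min_coverage thresholds for calling
#'   the element present in the inter-flank gap.
#' @param min_flank_len flanks shorter than this after clipping make a
#'   mapping ambiguous.
#' @return named list of parameters.
#' @export
mapping_params <- function(min_identity = 0.90, min_flank_coverage = 0.80,
                           max_gap = 50000L, empty_gap_tolerance = 100L,
                           element_min_identity = 0.80,
                           element_min_coverage = 0.80,
                           min_flank_len = 200L) {
  list(min_identity = min_identity, min_flank_coverage = min_flank_coverage,
       max_gap = max_gap, empty_gap_tolerance = empty_gap_tolerance,
       element_min_identity = element_min_identity,
       element_min_coverage = element_min_coverage,
       min_flank_len = min_flank_len)
}

# best placement of one flank sequence in a target assembly; NULL if nothing
# passes thresholds
place_flank <- function(flank, target, mp, sp = scan_params()) {
  if (nchar(flank) < mp$min_flank_len) return(NULL)
  best <- NULL
  for (chrom in names(target$chromosomes)) {
    hits <- cpp_scan(c(flank, revcomp(flank)), target$chromosomes[[chrom]],
                     sp$k, sp$match, sp$mismatch, sp$gap_open, sp$gap_ext,
                     min_score = 0.5 * nchar(flank))
    if (nrow(hits) == 0L) next
    hits$identity <- hits$matches / hits$aln_len
    hits$coverage <- (hits$q_end - hits$q_start + 1L) / nchar(flank)
    hits <- hits[hits$identity >= mp$min_identity &
                 hits$coverage >= mp$min_flank_coverage, , drop = FALSE]
    if (nrow(hits) == 0L) next
    i <- order(-hits$score)[1]
    cand <- list(chrom = chrom, start = hits$s_start[i], end = hits$s_end[i],
                 orientation = if (hits$query[i] == 1L) "+" else "-",
                 identity = hits$identity[i], coverage = hits$coverage[i],
                 score = hits$score[i])
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

#' Map an insertion locus into a target assembly via its flanks
#'
#' Both 1000-bp flanks of the locus are placed in the target
#' (seed-and-extend, best placement per flank). When both land on one
#' chromosome in consistent orientation within `max_gap`, the inter-flank
#' gap is extracted and compared against the element consensus to decide
#' whether the element is present at the orthologous site.
#'
#' @param flanked a `FlankedLocus` (window 1000 recommended).
#' @param target target `GenomeAssembly`.
#' @param consensus_set list of `TEConsensus` used to test the gap.
#' @param mp see [mapping_params()].
#' @return a `LocusMapping`: list with `left_hit`, `right_hit` (or NULL),
#'   `consistent`, `gap_chrom`, `gap_start`, `gap_end`, `inter_flank_gap`,
#'   `element_present_in_gap`, `gap_identity`, `gap_coverage`, `ambiguous`.
#' @export
map_locus <- function(flanked, target, consensus_set, mp = mapping_params()) {
  out <- list(left_hit = NULL, right_hit = NULL, consistent = FALSE,
              gap_chrom = NA_character_, gap_start = NA_integer_,
              gap_end = NA_integer_, inter_flank_gap = NA_integer_,
              element_present_in_gap = FALSE, gap_identity = NA_real_,
              gap_coverage = NA_real_, ambiguous = FALSE)
  if (nchar(flanked$left_flank) < mp$min_flank_len ||
      nchar(flanked$right_flank) < mp$min_flank_len) {
    out$ambiguous <- TRUE
    return(structure(out, class = "LocusMapping"))
  }
  out$left_hit <- place_flank(flanked$left_flank, target, mp)
  out$right_hit <- place_flank(flanked$right_flank, target, mp)
  lh <- out$left_hit; rh <- out$right_hit
  if (!is.null(lh) && !is.null(rh) && lh$chrom == rh$chrom &&
      lh$orientation == rh$orientation) {
    if (lh$orientation == "+") {
      gap_start <- lh$end + 1L; gap_end <- rh$start - 1L
    } else {
      gap_start <- rh$end + 1L; gap_end <- lh$start - 1L
    }
    gap <- gap_end - gap_start + 1L
    if (gap >= -50L && gap <= mp$max_gap) {
      out$consistent <- TRUE
      out$gap_chrom <- lh$chrom
      out$gap_start <- gap_start; out$gap_end <- gap_end
      out$inter_flank_gap <- max(0L, gap)
      if (gap > 0L) {
        gapseq <- substr(target$chromosomes[[lh$chrom]], gap_start, gap_end)
        if (lh$orientation == "-") gapseq <- revcomp(gapseq)
        # test the gap against the source site's own element copy first:
        # an orthologous copy inherits the same truncation, so coverage is
        # measured on what was actually at the source locus, not only on
        # the full-length family consensus
        cand_set <- consensus_set
        src_seq <- flanked$site$sequence %||% ""
        if (nzchar(src_seq))
          cand_set <- c(list(te_consensus("source_element", src_seq)),
                        cand_set)
        for (cons in cand_set) {
          al <- cpp_pair_local(gapseq, cons$sequence, 2, -3, 5, 2)
          if (al$aln_len > 0) {
            ident <- al$matches / al$aln_len
            cov <- (al$b_end - al$b_start + 1L) / cons$length
            if (ident >= mp$element_min_identity &&
                cov >= mp$element_min_coverage) {
              out$element_present_in_gap <- TRUE
              out$gap_identity <- ident; out$gap_coverage <- cov
              break
            }
          }
        }
      }
    }
  }
  structure(out, class = "LocusMapping")
}

#' Classify presence state of a locus in a target genome
#'
#' Pure function of the mapping, applying rules in order: (1) both flanks
#' placed and the gap aligns to a consensus at >= 0.80 identity / 0.80
#' coverage -> `full_site`; (2) both flanks placed, gap <= tolerance, no
#' consensus match -> `empty_site`; (3) exactly one flank placed, or flanks
#' placed inconsistently (different chromosomes, opposite orientations, or
#' too far apart) -> `rearranged_candidate`; (4) neither flank placed ->
#' `absent_locus`; (5) otherwise `ambiguous`.
#'
#' @param mapping a `LocusMapping` from [map_locus()].
#' @param mp see [mapping_params()].
#' @return one of `"full_site"`, `"empty_site"`, `"absent_locus"`,
#'   `"rearranged_candidate"`, `"ambiguous"`.
#' @export
classify_presence <- function(mapping, mp = mapping_params()) {
  if (isTRUE(mapping$ambiguous)) return("ambiguous")
  lh <- mapping$left_hit; rh <- mapping$right_hit
  n_placed <- sum(!is.null(lh), !is.null(rh))
  if (n_placed == 2L) {
    if (mapping$consistent && mapping$element_present_in_gap)
      return("full_site")
    if (mapping$consistent &&
        mapping$inter_flank_gap <= mp$empty_gap_tolerance)
      return("empty_site")
    if (!mapping$consistent) return("rearranged_candidate")
    return("ambiguous")
  }
  if (n_placed == 1L) return("rearranged_candidate")
  "absent_locus"
}

#' Cross-species membership matrix of orthologous insertion loci
#'
#' Every detected site's 1000-bp flanked locus is mapped into every other
#' assembly. Sites from different species are clustered into one
#' orthologous locus when one maps into the other's species as a
#' `full_site` whose inter-flank interval overlaps the other site
#' (reciprocity follows from symmetric evidence; non-transitive triples are
#' merged with a warning and flagged). The matrix cell for a species
#' without a member site is that cluster's presence call there.
#'
#' @param sites_by_species named list (species -> site data.frame).
#' @param assemblies named list (species -> `GenomeAssembly`).
#' @param consensus_set list of `TEConsensus`.
#' @param window flank window (bp).
#' @param mp see [mapping_params()].
#' @return list with `matrix` (cluster x species character matrix of
#'   states), `clusters` (data.frame site_id/species/cluster), `flagged`
#'   (clusters merged despite non-transitive evidence).
#' @export
membership_matrix <- function(sites_by_species, assemblies, consensus_set,
                              window = 1000L, mp = mapping_params()) {
  species <- names(assemblies)
  all_sites <- do.call(rbind, lapply(species, function(sp) {
    s <- sites_by_species[[sp]]
    if (is.null(s) || nrow(s) == 0L) return(NULL)
    s$species <- sp
    s
  }))
  if (is.null(all_sites) || nrow(all_sites) == 0L)
    return(list(matrix = matrix(character(0), 0, length(species),
                                dimnames = list(NULL, species)),
                clusters = data.frame(), flagged = character(0)))
  n <- nrow(all_sites)
  # mapping of every site into every other species
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- all_sites$species[i]
    fl <- extract_flanks(as.list(all_sites[i, ]), assemblies[[sp]], window)
    maps[[i]] <- lapply(species, function(tsp) {
      if (tsp == sp) return(NULL)
      m <- map_locus(fl, assemblies[[tsp]], consensus_set, mp)
      list(mapping = m, state = classify_presence(m, mp))
    })
    names(maps[[i]]) <- species
  }
  # orthology edges: site i's locus maps as full_site onto site j's interval
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    for (tsp in species) {
      mi <- maps[[i]][[tsp]]
      if (is.null(mi) || mi$state != "full_site") next
      cand <- which(all_sites$species == tsp &
                    all_sites$chrom == mi$mapping$gap_chrom &
                    all_sites$start <= mi$mapping$gap_end &
                    all_sites$end >= mi$mapping$gap_start)
      if (length(cand))
        edges <- rbind(edges, cbind(i, cand))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # flag clusters whose pairwise evidence was not fully symmetric/transitive
  flagged <- character(0)
  if (nrow(edges)) {
    und <- unique(rbind(edges, edges[, 2:1, drop = FALSE]))
    for (cl in unique(comp)) {
      members <- which(comp == cl)
      if (length(members) < 2L) next
      pairs_by_species <- expand.grid(members, members)
      pairs_by_species <- pairs_by_species[
        all_sites$species[pairs_by_species[, 1]] !=
          all_sites$species[pairs_by_species[, 2]] &
          pairs_by_species[, 1] < pairs_by_species[, 2], , drop = FALSE]
      have <- apply(pairs_by_species, 1, function(p)
        any(und[, 1] == p[1] & und[, 2] == p[2]))
      if (length(have) && !all(have)) flagged <- c(flagged, as.character(cl))
    }
    if (length(flagged))
      warning("non-transitive orthology evidence in cluster(s) ",
              paste(flagged, collapse = ", "), "; merged and flagged")
  }
  clusters <- sort(unique(comp))
  M <- matrix("absent_locus", length(clusters), length(species),
              dimnames = list(paste0("cluster", clusters), species))
  cluster_names <- character(length(clusters))
  for (ci in seq_along(clusters)) {
    members <- which(comp == clusters[ci])
    rep_site <- members[order(all_sites$species[members],
                              all_sites$start[members])][1]
    cluster_names[ci] <- all_sites$site_id[rep_site]
    for (sp in species) {
      in_sp <- members[all_sites$species[members] == sp]
      if (length(in_sp)) {
        M[ci, sp] <- "full_site"
      } else {
        # presence call from member mappings into this species, by priority
        states <- vapply(members, function(i) {
          m <- maps[[i]][[sp]]
          if (is.null(m)) NA_character_ else m$state
        }, character(1))
        states <- states[!is.na(states)]
        pri <- c("full_site", "empty_site", "rearranged_candidate",
                 "ambiguous", "absent_locus")
        hit <- pri[pri %in% states]
        M[ci, sp] <- if (length(hit)) hit[1] else "absent_locus"
      }
    }
  }
  rownames(M) <- make.unique(cluster_names)
  list(matrix = M,
       clusters = data.frame(site_id = all_sites$site_id,
                             species = all_sites$species,
                             cluster = rownames(M)[match(comp, clusters)],
                             stringsAsFactors = FALSE),
       flagged = flagged)
}

#' Venn region counts from a membership matrix
#'
#' A cluster counts toward the species subset in which its state is exactly
#' `full_site` (an `empty_site` is a conserved locus without the element and
#' is reported separately, not as presence). Counts over all non-empty
#' subsets sum to the number of clusters.
#'
#' @param membership result of [membership_matrix()] (or its `matrix`).
#' @return named integer vector; names are `"+"`-joined sorted species
#'   subsets.
#' @export
venn_counts <- function(membership) {
  M <- if (is.list(membership)) membership$matrix else membership
  if (nrow(M) == 0L) return(stats::setNames(integer(0), character(0)))
  subsets <- apply(M, 1, function(row)
    paste(sort(colnames(M)[row == "full_site"]), collapse = "+"))
  tab <- table(subsets)
  stats::setNames(as.integer(tab), names(tab))
}

#' Gene associations of an insertion site
#'
#' Genes overlapping the element are reported as `within_CDS`,
#' `within_exon_UTR` or `within_intron` (priority CDS > exon > intron);
#' otherwise genes within `window` bp are reported as `upstream` /
#' `downstream` of the element (on the genome forward strand) with their
#' distance.
#'
#' @param site one site row (list-like).
#' @param annotations list of `GeneAnnotation` from [read_gff()].
#' @param window association window (bp).
#' @return data.frame with `site_id`, `gene_id`, `relation`, `distance`.
#' @export
gene_association <- function(site, annotations, window = 500L) {
  rows <- list()
  for (g in annotations) {
    if (g$chrom != site$chrom) next
    if (site$start <= g$end && site$end >= g$start) {
      feats <- g$features
      ov <- feats[feats$start <= site$end & feats$end >= site$start, ,
                  drop = FALSE]
      relation <- if ("CDS" %in% ov$feature_type) "within_CDS"
        else if ("exon" %in% ov$feature_type) "within_exon_UTR"
        else if ("intron" %in% ov$feature_type) "within_intron"
        else "within_intron"
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = site$site_id, gene_id = g$gene_id, relation = relation,
        distance = 0L, stringsAsFactors = FALSE)
    } else {
      dist <- if (g$end < site$start) site$start - g$end
              else g$start - site$end
      if (dist <= window) {
        relation <- if (g$end < site$start) "upstream" else "downstream"
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = site$site_id, gene_id = g$gene_id, relation = relation,
          distance = dist, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(site_id = character(0), gene_id = character(0),
                  relation = character(0), distance = integer(0),
                  stringsAsFactors = FALSE)
}
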