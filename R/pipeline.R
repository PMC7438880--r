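#' Run the full comparative pipeline
#'
#' Orchestrates scan -> dedup -> naming -> TSD -> cross-species membership
#' -> Venn -> phylogeny -> chromosome walks for rearranged-candidate loci,
#' writing per-stage TSV/newick/JSON artifacts plus a human-readable
#' `summary.md` into `outdir`. Every stage is logged with its parameters
#' and record counts; stages are deterministic given `seed`.
#'
#' @param assemblies named list of `GenomeAssembly` (or a directory of
#'   FASTA files, one per species).
#' @param consensus_set list of `TEConsensus` (or a consensus FASTA path).
#' @param outdir output directory.
#' @param annotations optional list of `GeneAnnotation` (or GFF3 path) for
#'   gene associations.
#' @param sp scan parameters ([scan_params()]).
#' @param mp mapping parameters ([mapping_params()]).
#' @param flank_window flank width for cross-species comparison.
#' @param tsd_window,tsd_max_mismatches TSD stage settings.
#' @param gene_window gene-association window (bp).
#' @param bootstrap_replicates bootstrap replicates for the tree (0 skips
#'   the phylogeny stage).
#' @param collapse bootstrap support cutoff (percent) for collapsing weak
#'   branches.
#' @param walk walk rearranged-candidate loci against the discordant
#'   species (can be slow on large inputs).
#' @param seed seed for the stochastic stages (bootstrap).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `sites`, `tsd`, `membership`, `venn`,
#'   `tree`, `walks`, `gene_assoc`, `outdir`.
#' @export
run_all <- function(assemblies, consensus_set, outdir, annotations = NULL,
                    sp = scan_params(), mp = mapping_params(),
                    flank_window = 1000L, tsd_window = 10L,
                    tsd_max_mismatches = 1L, gene_window = 500L,
                    bootstrap_replicates = 100L, collapse = 45L,
                    walk = TRUE, seed = 42L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.character(assemblies)) {
    files <- list.files(assemblies, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA files in ", assemblies)
    assemblies <- lapply(files, read_fasta)
    names(assemblies) <- vapply(assemblies, `[[`, character(1), "species_id")
  }
  if (is.character(consensus_set)) consensus_set <- read_consensus(consensus_set)
  if (is.character(annotations)) annotations <- read_gff(annotations)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: scan every assembly with every consensus, dedup, classify, name
  sites_by_species <- lapply(names(assemblies), function(spc) {
    asm <- assemblies[[spc]]
    hits <- do.call(rbind, lapply(consensus_set, scan_genome, assembly = asm,
                                  params = sp))
    hits <- dedup_hits(hits)
    if (nrow(hits)) {
      hits$subfamily <- vapply(hits$sequence, function(s)
        as.character(classify_subfamily(s, consensus_set)), character(1))
    }
    hits <- name_sites(hits, asm)
    say("scan: %s -> %d site(s)", spc, nrow(hits))
    hits
  })
  names(sites_by_species) <- names(assemblies)
  all_sites <- do.call(rbind, sites_by_species)
  rownames(all_sites) <- NULL
  write_sites(all_sites, file.path(outdir, "sites.tsv"),
              bed = file.path(outdir, "sites.bed"),
              params = list(min_identity = sp$min_identity,
                            min_coverage = sp$min_coverage))

  # stage 2: TSD detection + logo
  tsd <- do.call(rbind, lapply(names(assemblies), function(spc)
    tsd_table(sites_by_species[[spc]], assemblies[[spc]],
              window = tsd_window, max_tsd_len = tsd_window,
              max_mismatches = tsd_max_mismatches, junction_slide = 3L)))
  write_report_tsv(tsd, file.path(outdir, "tsd.tsv"),
                   params = list(window = tsd_window,
                                 max_mismatches = tsd_max_mismatches))
  motifs <- tsd$tsd_motif[!is.na(tsd$tsd_motif)]
  if (length(motifs)) {
    pfm <- tsd_logo(motifs)
    write_report_tsv(data.frame(position = seq_len(nrow(pfm$matrix)),
                                pfm$matrix, depth = pfm$depth),
                     file.path(outdir, "pfm.tsv"))
  }
  say("tsd: %d/%d site(s) with a TSD", length(motifs), nrow(tsd))

  # stage 3: cross-species membership + Venn
  membership <- membership_matrix(sites_by_species, assemblies,
                                  consensus_set, window = flank_window,
                                  mp = mp)
  write_report_tsv(data.frame(cluster = rownames(membership$matrix),
                              membership$matrix),
                   file.path(outdir, "matrix.tsv"),
                   params = list(flank = flank_window))
  venn <- venn_counts(membership)
  write_report_tsv(data.frame(subset = names(venn), count = as.integer(venn)),
                   file.path(outdir, "venn.tsv"))
  say("compare: %d cluster(s), %d Venn region(s)",
      nrow(membership$matrix), length(venn))

  # stage 4: gene associations (optional)
  gene_assoc <- NULL
  if (!is.null(annotations) && nrow(all_sites)) {
    gene_assoc <- do.call(rbind, lapply(seq_len(nrow(all_sites)), function(i)
      gene_association(as.list(all_sites[i, ]), annotations,
                       window = gene_window)))
    write_report_tsv(gene_assoc, file.path(outdir, "genes.tsv"),
                     params = list(window = gene_window))
    say("genes: %d association(s)", nrow(gene_assoc))
  }

  # stage 5: phylogeny of the retrieved element copies
  tree <- NULL
  if (bootstrap_replicates > 0L && nrow(all_sites) >= 4L) {
    seqs <- stats::setNames(all_sites$sequence, all_sites$site_id)
    msa <- progressive_msa(seqs)
    tree <- bootstrap_support(msa, replicates = bootstrap_replicates,
                              seed = seed, collapse = collapse)
    write_newick(tree, file.path(outdir, "tree.nwk"))
    say("phylo: %d-leaf tree, %d bootstrap replicate(s)",
        length(tree$tip.label), bootstrap_replicates)
  }

  # stage 6: chromosome walks for rearranged-candidate cells
  walks <- list()
  if (walk && nrow(membership$matrix)) {
    M <- membership$matrix
    wdir <- file.path(outdir, "walk-reports")
    dir.create(wdir, showWarnings = FALSE)
    for (ci in seq_len(nrow(M))) {
      targets <- colnames(M)[M[ci, ] == "rearranged_candidate"]
      if (length(targets) == 0L) next
      members <- membership$clusters[
        membership$clusters$cluster == rownames(M)[ci], , drop = FALSE]
      src_sp <- members$species[1]
      site <- sites_by_species[[src_sp]]
      site <- as.list(site[site$site_id == members$site_id[1], ])
      for (tsp in targets) {
        rep <- chromosome_walk(site, assemblies[[src_sp]],
                               assemblies[[tsp]], preset = "desk")
        key <- paste0(site$site_id, "_vs_", tsp)
        walks[[key]] <- rep
        write_walk_report(rep, file.path(wdir, paste0(key, ".json")))
      }
    }
    say("walk: %d report(s)", length(walks))
  }

  write_pipeline_summary(file.path(outdir, "summary.md"), assemblies,
                         all_sites, tsd, membership, venn, tree, walks)
  invisible(list(sites = all_sites, sites_by_species = sites_by_species,
                 tsd = tsd, membership = membership, venn = venn,
                 tree = tree, walks = walks, gene_assoc = gene_assoc,
                 outdir = outdir))
}

write_pipeline_summary <- function(path, assemblies, sites, tsd, membership,
                                   venn, tree, walks) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# mitedyn pipeline summary")
  w("")
  w("## Inputs")
  for (spc in names(assemblies))
    w("- %s: %d chromosome(s), %s bp", spc,
      length(assemblies[[spc]]$chromosomes),
      format(sum(nchar(assemblies[[spc]]$chromosomes)), big.mark = ","))
  w("")
  w("## Insertion sites")
  tab <- table(sites$species)
  for (spc in names(tab)) w("- %s: %d site(s)", spc, tab[[spc]])
  w("- total: %d (%d full-length, %d short)", nrow(sites),
    sum(sites$length_class == "full"), sum(sites$length_class == "short"))
  w("")
  w("## TSD")
  w("- sites with a detected TSD: %d / %d",
    sum(!is.na(tsd$tsd_length)), nrow(tsd))
  if (any(!is.na(tsd$tsd_length))) {
    lens <- table(tsd$tsd_length)
    top <- names(sort(lens, decreasing = TRUE))[1]
    w("- modal TSD length: %s bp", top)
  }
  w("")
  w("## Cross-species sharing (full sites)")
  w("")
  w("| species subset | clusters |")
  w("|---|---|")
  for (n in names(venn)) w("| %s | %d |", n, venn[[n]])
  w("")
  if (!is.null(tree))
    w("## Phylogeny\n- %d leaves, newick written to tree.nwk",
      length(tree$tip.label))
  if (length(walks)) {
    w("")
    w("## Chromosome walks")
    for (k in names(walks))
      w("- %s: %s, %d event(s)", k, walks[[k]]$state,
        nrow(walks[[k]]$events))
  }
  invisible(path)
}
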