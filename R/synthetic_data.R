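#' Scenario configuration for the allopolyploid simulator
#'
#' The simulated species set mirrors the wheat system: an ancestral
#' sequence gives rise to the A, B and D sub-genome ancestors (deeper
#' divergence, so homeologous regions are distinguishable but not trivially
#' so), two diploids (TU carrying A, AT carrying D), two AB tetraploids (WE,
#' DW), and the ABD hexaploid (TA) whose D component splits from the AT
#' lineage late. Background evolution is substitutions only — no indel
#' process — so planted-feature coordinates stay exact; length changes enter
#' only through planted elements and rearrangement events.
#'
#' @param subgenome_length total bp per sub-genome.
#' @param n_chrom chromosomes per sub-genome.
#' @param gc GC content of the ancestral sequence.
#' @param divergence substitution rate applied on each lineage-split edge.
#' @param subgenome_divergence substitution rate from the ancestral
#'   sequence to each sub-genome ancestor (applied once per sub-genome).
#' @param insertion_plan data.frame with columns `lineage` (one of `"A"`,
#'   `"B"`, `"D"` = sub-genome ancestor branches, `"AB"` = tetraploid
#'   branch, or a species code), `count`, `length_class` (`"full"`,
#'   `"short"` or `"mixed"`), `tsd_len`, `subfamily` (consensus name or
#'   `"mixed"`).
#' @param rearrangement_plan data.frame with columns `species`,
#'   `event_type`, `size` (applied to the emitted assemblies, logged in the
#'   truth table).
#' @param min_spacing minimum distance between planted insertions on one
#'   chromosome.
#' @param seed mandatory RNG seed.
#' @return a `ScenarioConfig` list.
#' @export
scenario_config <- function(subgenome_length = 500000L, n_chrom = 2L,
                            gc = 0.46, divergence = 0.02,
                            subgenome_divergence = 0.05,
                            insertion_plan = NULL, rearrangement_plan = NULL,
                            min_spacing = 2500L, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(divergence >= 0, divergence <= 0.25,
            subgenome_divergence >= 0, subgenome_divergence <= 0.25)
  structure(list(subgenome_length = as.integer(subgenome_length),
                 n_chrom = as.integer(n_chrom), gc = gc,
                 divergence = divergence,
                 subgenome_divergence = subgenome_divergence,
                 insertion_plan = insertion_plan,
                 rearrangement_plan = rearrangement_plan,
                 min_spacing = as.integer(min_spacing),
                 seed = as.integer(seed)),
            class = "ScenarioConfig")
}

random_sequence <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rawToChar(as.raw(sample(utf8ToInt("ACGT"), n, replace = TRUE, prob = p)))
}

# substitution-only mutation: each chosen position is replaced by one of the
# three other bases
mutate_sequence <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  r <- charToRaw(seq)
  bases <- charToRaw("ACGT")
  cur <- r[pos]
  repl <- bases[sample.int(4L, k, replace = TRUE)]
  redraw <- which(repl == cur)
  while (length(redraw)) {
    repl[redraw] <- bases[sample.int(4L, length(redraw), replace = TRUE)]
    redraw <- redraw[repl[redraw] == cur[redraw]]
  }
  r[pos] <- repl
  rawToChar(r)
}

mutate_state <- function(state, rate) {
  state$chroms <- vapply(state$chroms, mutate_sequence, character(1),
                         rate = rate)
  state
}

# plant the insertions assigned to one branch into a lineage state; the
# TSD is a duplication of the tsd_len target bases as they stand on this
# lineage at planting time
plant_on_branch <- function(state, plantings) {
  if (is.null(plantings) || nrow(plantings) == 0L) return(state)
  plantings <- plantings[order(plantings$chrom, plantings$ur_pos), ,
                         drop = FALSE]
  for (i in seq_len(nrow(plantings))) {
    p <- plantings[i, ]
    hist <- state$history
    shift <- if (nrow(hist)) sum(hist$added[hist$chrom == p$chrom &
                                            hist$ur_pos < p$ur_pos]) else 0L
    at <- p$ur_pos + shift
    seq <- state$chroms[[p$chrom]]
    t <- p$tsd_len
    motif <- substr(seq, at + 1L, at + t)
    state$chroms[[p$chrom]] <- paste0(substr(seq, 1L, at + t),
                                      p$element_seq, motif,
                                      substr(seq, at + t + 1L, nchar(seq)))
    state$history <- rbind(state$history, data.frame(
      insertion_id = p$insertion_id, chrom = p$chrom, ur_pos = p$ur_pos,
      tsd_len = t, added = nchar(p$element_seq) + t,
      element_len = nchar(p$element_seq), tsd_motif = motif,
      subfamily = p$subfamily, length_class = p$length_class,
      pattern = p$pattern, stringsAsFactors = FALSE))
  }
  state
}

combine_states <- function(a, b) {
  list(chroms = c(a$chroms, b$chroms),
       history = rbind(a$history, b$history))
}

empty_history <- function() {
  data.frame(insertion_id = character(0), chrom = character(0),
             ur_pos = integer(0), tsd_len = integer(0), added = integer(0),
             element_len = integer(0), tsd_motif = character(0),
             subfamily = character(0), length_class = character(0),
             pattern = character(0), stringsAsFactors = FALSE)
}

# final 1-based inclusive element coordinates of every planting carried by a
# leaf state
leaf_truth <- function(state, species) {
  hist <- state$history
  if (nrow(hist) == 0L) return(NULL)
  hist <- hist[order(hist$chrom, hist$ur_pos), , drop = FALSE]
  rows <- lapply(seq_len(nrow(hist)), function(i) {
    h <- hist[i, ]
    before <- hist[hist$chrom == h$chrom & hist$ur_pos < h$ur_pos, ,
                   drop = FALSE]
    shift <- sum(before$added)
    start <- h$ur_pos + shift + h$tsd_len + 1L
    data.frame(species = species, insertion_id = h$insertion_id,
               chrom = h$chrom, start = start,
               end = start + h$element_len - 1L, strand = "+",
               tsd_motif = h$tsd_motif, tsd_len = h$tsd_len,
               subfamily = h$subfamily, length_class = h$length_class,
               pattern = h$pattern, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# which species inherit a planting on each branch of the wheat preset tree
branch_species <- list(
  A = c("TU", "WE", "DW", "TA"), B = c("WE", "DW", "TA"),
  D = c("AT", "TA"), AB = c("WE", "DW", "TA"),
  TU = "TU", AT = "AT", WE = "WE", DW = "DW", TA = "TA")

# sub-genomes available to each planting branch
branch_subgenomes <- list(A = "A", B = "B", D = "D", AB = c("A", "B"),
                          TU = "A", AT = "D", WE = c("A", "B"),
                          DW = c("A", "B"), TA = c("A", "B", "D"))

#' Simulate the wheat-like species set with planted elements
#'
#' Builds the five assemblies (TU, AT, WE, DW, TA) from one ancestral
#' sequence, planting element copies on the branches stated in the
#' insertion plan (inherited by all descendant species, then subject to
#' ordinary substitution divergence) and duplicating `tsd_len` target bases
#' around every planted copy. Deterministic given the config seed.
#'
#' @param config a [scenario_config()].
#' @param consensus_set named list of `TEConsensus` supplying element
#'   sequences for the plan's subfamilies.
#' @return list with `assemblies` (named list of `GenomeAssembly`) and
#'   `truth` (data.frame: one row per planted copy per carrying species,
#'   with final coordinates, TSD motif, subfamily, length class and
#'   sharing-pattern id) plus `events` (planted rearrangements, if any).
#' @export
simulate_species_set <- function(config, consensus_set) {
  set.seed(config$seed)
  nchr <- config$n_chrom
  chrom_len <- config$subgenome_length %/% nchr
  ur <- stats::setNames(
    vapply(seq_len(nchr), function(i) random_sequence(chrom_len, config$gc),
           character(1)),
    paste0(seq_len(nchr)))

  cons_by_name <- stats::setNames(consensus_set,
                                  vapply(consensus_set, `[[`, character(1),
                                         "family_name"))

  # expand the plan into individual plantings with drawn positions
  plan <- config$insertion_plan
  plantings <- NULL
  if (!is.null(plan) && nrow(plan)) {
    rows <- list()
    serial <- 0L
    for (i in seq_len(nrow(plan))) {
      for (j in seq_len(plan$count[i])) {
        serial <- serial + 1L
        lineage <- plan$lineage[i]
        sg <- branch_subgenomes[[lineage]]
        sg <- if (length(sg) > 1L) sample(sg, 1L) else sg
        fam <- plan$subfamily[i]
        if (fam == "mixed")
          fam <- names(cons_by_name)[sample.int(length(cons_by_name), 1L)]
        lc <- plan$length_class[i]
        if (lc == "mixed") lc <- if (stats::runif(1) < 0.7) "full" else "short"
        cons <- cons_by_name[[fam]]
        elem <- if (lc == "full") cons$sequence else {
          len <- sample(93:min(240L, cons$length - 10L), 1L)
          substr(cons$sequence, cons$length - len + 1L, cons$length)
        }
        rows[[serial]] <- data.frame(
          insertion_id = sprintf("ins%03d", serial), lineage = lineage,
          subgenome = sg, chrom_num = sample.int(nchr, 1L),
          tsd_len = plan$tsd_len[i], subfamily = fam, length_class = lc,
          element_seq = elem,
          pattern = paste(branch_species[[lineage]], collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
    plantings <- do.call(rbind, rows)
    plantings$chrom <- paste0(plantings$chrom_num, plantings$subgenome)
    # draw positions with minimum spacing per chromosome (in ancestral
    # coordinates; substitutions never shift them)
    plantings$ur_pos <- NA_integer_
    for (chrom in unique(plantings$chrom)) {
      idx <- which(plantings$chrom == chrom)
      margin <- 6000L
      lo <- margin; hi <- chrom_len - margin
      repeat {
        pos <- sort(sample(lo:hi, length(idx)))
        if (length(pos) < 2L || all(diff(pos) >= config$min_spacing)) break
      }
      plantings$ur_pos[idx] <- pos[sample.int(length(pos))] # shuffle onto rows
    }
  }
  take <- function(lineage) {
    if (is.null(plantings)) return(NULL)
    plantings[plantings$lineage == lineage, , drop = FALSE]
  }

  name_chroms <- function(seqs, sg) stats::setNames(seqs, paste0(names(seqs), sg))
  div <- config$divergence
  A0 <- list(chroms = name_chroms(vapply(ur, mutate_sequence, character(1),
                                         rate = config$subgenome_divergence), "A"),
             history = empty_history())
  B0 <- list(chroms = name_chroms(vapply(ur, mutate_sequence, character(1),
                                         rate = config$subgenome_divergence), "B"),
             history = empty_history())
  D0 <- list(chroms = name_chroms(vapply(ur, mutate_sequence, character(1),
                                         rate = config$subgenome_divergence), "D"),
             history = empty_history())
  A1 <- plant_on_branch(A0, take("A"))
  TU <- plant_on_branch(mutate_state(A1, div), take("TU"))
  AB <- combine_states(mutate_state(A1, div), mutate_state(plant_on_branch(B0, take("B")), div))
  AB1 <- plant_on_branch(AB, take("AB"))
  WE <- plant_on_branch(mutate_state(AB1, div), take("WE"))
  DW <- plant_on_branch(mutate_state(AB1, div), take("DW"))
  TAAB <- mutate_state(AB1, div)
  Dpre <- plant_on_branch(mutate_state(D0, div), take("D"))
  AT <- plant_on_branch(mutate_state(Dpre, div), take("AT"))
  TAD <- mutate_state(Dpre, div)
  TA <- plant_on_branch(combine_states(TAAB, TAD), take("TA"))

  leaves <- list(TU = TU, AT = AT, WE = WE, DW = DW, TA = TA)
  assemblies <- lapply(names(leaves), function(sp)
    genome_assembly(sp, leaves[[sp]]$chroms))
  names(assemblies) <- names(leaves)
  truth <- do.call(rbind, lapply(names(leaves), function(sp)
    leaf_truth(leaves[[sp]], sp)))

  # planted large-scale rearrangements, applied to the emitted assemblies
  events <- NULL
  rp <- config$rearrangement_plan
  if (!is.null(rp) && nrow(rp)) {
    ev_rows <- list()
    for (i in seq_len(nrow(rp))) {
      res <- plant_event(assemblies[[rp$species[i]]], rp$event_type[i],
                         rp$size[i], seed = NULL)
      assemblies[[rp$species[i]]] <- res$assembly
      ev_rows[[i]] <- res$truth
    }
    events <- do.call(rbind, ev_rows)
  }
  list(assemblies = assemblies, truth = truth, events = events,
       config = config)
}

#' Plant one large rearrangement event into an assembly
#'
#' `deletion` removes a span, `insertion` splices a random foreign
#' sequence, `inversion` reverse-complements a span in place, `duplication`
#' copies a span to a distant position on the same chromosome.
#'
#' @param assembly a `GenomeAssembly`.
#' @param event_type one of `"deletion"`, `"insertion"`, `"inversion"`,
#'   `"duplication"`.
#' @param size event size in bp (must be under a quarter of the chromosome).
#' @param seed optional seed (NULL continues the current RNG stream).
#' @param chrom chromosome to modify (default: drawn).
#' @param position 1-based position of the event span start (default:
#'   drawn away from chromosome ends).
#' @return list with `assembly` (modified) and `truth` (one-row data.frame
#'   with the event coordinates; for duplication, `extra` holds the copy
#'   position).
#' @export
plant_event <- function(assembly, event_type, size, seed = NULL,
                        chrom = NULL, position = NULL) {
  if (!is.null(seed)) set.seed(seed)
  size <- as.integer(size)
  if (is.null(chrom))
    chrom <- sample(names(assembly$chromosomes), 1L)
  seq <- assembly$chromosomes[[chrom]]
  n <- nchar(seq)
  if (size >= n / 4) stop("event size must be below a quarter of the chromosome")
  margin <- max(2000L, size %/% 2L)
  if (is.null(position))
    position <- sample((margin):(n - size - margin), 1L)
  s <- position; e <- position + size - 1L
  extra <- NA_integer_
  new <- switch(event_type,
    deletion = paste0(substr(seq, 1L, s - 1L), substr(seq, e + 1L, n)),
    insertion = paste0(substr(seq, 1L, s - 1L),
                       random_sequence(size, 0.46), substr(seq, s, n)),
    inversion = paste0(substr(seq, 1L, s - 1L), revcomp(substr(seq, s, e)),
                       substr(seq, e + 1L, n)),
    duplication = {
      span <- substr(seq, s, e)
      # copy lands at least one event-size away from the source
      repeat {
        extra <- sample((margin):(n - margin), 1L)
        if (extra < s - size || extra > e + size) break
      }
      paste0(substr(seq, 1L, extra), span, substr(seq, extra + 1L, n))
    },
    stop("unknown event type: ", event_type))
  assembly$chromosomes[[chrom]] <- new
  truth <- data.frame(species = assembly$species_id, event_type = event_type,
                      chrom = chrom, start = s, end = e, size = size,
                      extra = extra, stringsAsFactors = FALSE)
  list(assembly = assembly, truth = truth)
}

#' Load the packaged synthetic element-family fixtures
#'
#' Two ~300-bp consensus sequences emulating a two-variant MITE family:
#' they share their first 39 bp and last 50 bp but have divergent interiors
#' (the second variant is 291 bp). These are synthetic stand-ins generated
#' with a recorded seed, not sequences from any genome; a user with real
#' family consensus FASTA can pass it anywhere a consensus set is accepted.
#'
#' @return list of two `TEConsensus` (`Mariam1_like`, `Mariam2_like`).
#' @export
mariam_like_consensus <- function() {
  c(read_consensus(system.file("extdata", "mariam1_like_synthetic.fasta",
                               package = "mitedyn")),
    read_consensus(system.file("extdata", "mariam2_like_synthetic.fasta",
                               package = "mitedyn")))
}

#' The five-genome sharing-structure scenario
#'
#' Desk-scale (500-kb sub-genomes) preset implementing the published Venn
#' sharing structure across the five species: 2 ancient A-sub-genome
#' insertions shared by TU, WE, DW and TA; 6 D-lineage insertions shared by
#' AT and TA; 10 tetraploid-branch insertions shared by WE, DW and TA; 15
#' unique to WE; 6 unique to DW; 6 unique to TA; 1 unique to AT; 2 unique
#' to TU. All plantings carry 9-bp TSDs; element sequences come from the
#' packaged two-variant fixture pair.
#'
#' @param seed RNG seed (default 42).
#' @param subgenome_length bp per sub-genome.
#' @return as [simulate_species_set()].
#' @export
paper_scenario <- function(seed = 42L, subgenome_length = 500000L) {
  plan <- data.frame(
    lineage = c("A", "D", "AB", "WE", "DW", "TA", "AT", "TU"),
    count = c(2L, 6L, 10L, 15L, 6L, 6L, 1L, 2L),
    length_class = "mixed", tsd_len = 9L, subfamily = "mixed",
    stringsAsFactors = FALSE)
  cfg <- scenario_config(subgenome_length = subgenome_length,
                         insertion_plan = plan, seed = seed)
  simulate_species_set(cfg, mariam_like_consensus())
}

#' Write simulator output: per-species FASTA, truth BED + JSON, config echo
#'
#' @param sim result of [simulate_species_set()] / [paper_scenario()].
#' @param outdir output directory (created if needed).
#' @export
write_scenario <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$assemblies))
    write_fasta(sim$assemblies[[sp]], file.path(outdir, paste0(sp, ".fasta")))
  if (!is.null(sim$truth)) {
    write_bed(data.frame(chrom = paste0(sim$truth$species, ":",
                                        sim$truth$chrom),
                         start = sim$truth$start, end = sim$truth$end,
                         name = sim$truth$insertion_id, score = 0,
                         strand = sim$truth$strand),
              file.path(outdir, "truth.bed"))
    jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                         digits = NA)
  }
  cfg <- sim$config
  lines <- vapply(setdiff(names(cfg), c("insertion_plan", "rearrangement_plan")),
                  function(n) paste0(n, ": ", cfg[[n]]), character(1))
  writeLines(lines, file.path(outdir, "config.txt"))
  invisible(outdir)
}
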