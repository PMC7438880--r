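#' @useDynLib mitedyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a genome assembly
#'
#' A `GenomeAssembly` bundles the chromosome sequences of one species (or
#' accession) with a short species label and, for polyploids, a map from
#' chromosome name to sub-genome letter. Sequences are stored uppercase over
#' the alphabet `{A,C,G,T,N}`; any IUPAC ambiguity code is collapsed to `N`.
#' All coordinates handled by the package are 1-based inclusive.
#'
#' @param species_id short species label, e.g. `"TU"`, `"AT"`, `"WE"`,
#'   `"DW"`, `"TA"`.
#' @param chromosomes named character vector of nucleotide sequences.
#' @param subgenome_of optional named character vector mapping chromosome
#'   name to sub-genome letter (`"A"`, `"B"`, `"D"`); chromosomes without an
#'   entry are assigned `"U"` (unplaced).
#' @return an object of class `GenomeAssembly`.
#' @export
genome_assembly <- function(species_id, chromosomes, subgenome_of = NULL) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosome names must be present and unique")
  chromosomes <- vapply(chromosomes, normalize_sequence, character(1))
  if (any(nchar(chromosomes) == 0L)) stop("chromosome sequences must be non-empty")
  sg <- infer_subgenomes(names(chromosomes))
  if (!is.null(subgenome_of)) sg[names(subgenome_of)] <- subgenome_of
  structure(list(species_id = species_id, chromosomes = chromosomes,
                 subgenome_of = sg),
            class = "GenomeAssembly")
}

# sub-genome letter from chromosome names like "1A", "chr3B", "2D"; "U" when
# no A/B/D letter is recognisable
infer_subgenomes <- function(chrom_names) {
  letter <- sub(".*([ABD])$", "\\1", chrom_names)
  letter[!letter %in% c("A", "B", "D")] <- "U"
  stats::setNames(letter, chrom_names)
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat(sprintf("GenomeAssembly '%s': %d chromosome(s), %s bp total\n",
              x$species_id, length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  invisible(x)
}

#' @export
chromosome_lengths <- function(assembly) nchar(assembly$chromosomes)

normalize_sequence <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    n_bad <- nchar(gsub("[ACGTN]", "", seq))
    warning(sprintf("%d non-ACGTN character(s) collapsed to N", n_bad),
            call. = FALSE)
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string (A/C/G/T/N).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read a FASTA file into a genome assembly
#'
#' Records are uppercased and ambiguity codes collapse to `N` (with a
#' warning). Record names are taken up to the first whitespace.
#'
#' @param path FASTA file.
#' @param species_id species label attached to the assembly; defaults to the
#'   file name without extension.
#' @return a [genome_assembly()].
#' @export
read_fasta <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  sid <- species_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path))
  genome_assembly(sid, seqs)
}

#' Write a genome assembly (or named sequences) to FASTA
#'
#' @param x a `GenomeAssembly` or named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "GenomeAssembly")) x$chromosomes else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Extract a genomic region
#'
#' Coordinates are 1-based inclusive. For `strand = "-"` the reverse
#' complement is returned. When `clip = TRUE`, requests running over a
#' chromosome end are truncated to the available sequence and flagged via the
#' `"clipped"` attribute instead of raising an error; this is routine for
#' kilobase flank windows near contig ends.
#'
#' @param assembly a `GenomeAssembly`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param clip clip out-of-bounds requests instead of erroring.
#' @return nucleotide string with attribute `clipped` (logical).
#' @export
extract_region <- function(assembly, chrom, start, end, strand = "+",
                           clip = FALSE) {
  if (!chrom %in% names(assembly$chromosomes))
    stop("unknown chromosome: ", chrom)
  len <- nchar(assembly$chromosomes[[chrom]])
  clipped <- FALSE
  if (start < 1L || end > len) {
    if (!clip) stop(sprintf("interval [%d,%d] outside 1..%d on %s",
                            start, end, len, chrom))
    start <- max(1L, start); end <- min(len, end)
    clipped <- TRUE
  }
  if (start > end) {
    out <- ""
  } else {
    out <- substr(assembly$chromosomes[[chrom]], start, end)
    if (strand == "-") out <- revcomp(out)
  }
  attr(out, "clipped") <- clipped
  out
}

#' Read gene annotations from GFF3
#'
#' Imports `gene` features and their `exon`/`CDS` children; introns are
#' implied as the within-gene gaps between exons. Children that cannot be
#' traced to a gene are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return a list of `GeneAnnotation` records, each a list with `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, and a data.frame `features` holding
#'   exon/CDS/intron intervals (1-based inclusive).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 50L, warn = FALSE)) == 0L) return(list())
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(list())
  type <- as.character(gr$type)
  ids <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  parents <- vapply(as.list(gr$Parent %||% vector("list", length(gr))),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  genes <- which(type == "gene")
  gene_ids <- ids[genes]
  # map transcript id -> gene id so exon/CDS rows nested under mRNA resolve
  tx <- which(type %in% c("mRNA", "transcript"))
  tx2gene <- stats::setNames(parents[tx], ids[tx])
  resolve_gene <- function(parent) {
    if (is.na(parent)) return(NA_character_)
    if (parent %in% gene_ids) return(parent)
    if (parent %in% names(tx2gene)) return(tx2gene[[parent]])
    NA_character_
  }
  out <- list()
  for (gi in seq_along(genes)) {
    i <- genes[gi]
    out[[gene_ids[gi]]] <- list(
      gene_id = gene_ids[gi],
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      start = GenomicRanges::start(gr)[i], end = GenomicRanges::end(gr)[i],
      strand = as.character(GenomicRanges::strand(gr)[i]),
      features = data.frame(feature_type = character(0),
                            start = integer(0), end = integer(0)))
  }
  children <- which(type %in% c("exon", "CDS"))
  n_orphans <- 0L
  for (i in children) {
    g <- resolve_gene(parents[i])
    if (is.na(g) || !g %in% names(out)) { n_orphans <- n_orphans + 1L; next }
    out[[g]]$features <- rbind(out[[g]]$features, data.frame(
      feature_type = ifelse(type[i] == "CDS", "CDS", "exon"),
      start = GenomicRanges::start(gr)[i], end = GenomicRanges::end(gr)[i]))
  }
  if (n_orphans > 0L)
    warning(n_orphans, " exon/CDS row(s) without a resolvable gene skipped")
  # implied introns: gaps between exons inside the gene interval
  for (g in names(out)) {
    ex <- out[[g]]$features
    ex <- ex[ex$feature_type == "exon", , drop = FALSE]
    if (nrow(ex) >= 2L) {
      red <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
      gaps <- IRanges::gaps(red, start = out[[g]]$start, end = out[[g]]$end)
      if (length(gaps))
        out[[g]]$features <- rbind(out[[g]]$features, data.frame(
          feature_type = "intron", start = IRanges::start(gaps),
          end = IRanges::end(gaps)))
    }
  }
  unname(out)
}

#' Write gene annotations to GFF3
#'
#' Inverse of [read_gff()] for gene/exon/CDS rows (implied introns are not
#' emitted; they are recomputed on read).
#'
#' @param genes list of `GeneAnnotation` records.
#' @param path output file.
#' @export
write_gff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    writeLines(sprintf("%s\tmitedyn\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id), con)
    feats <- g$features
    feats <- feats[feats$feature_type %in% c("exon", "CDS"), , drop = FALSE]
    if (nrow(feats))
      writeLines(sprintf("%s\tmitedyn\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$chrom, feats$feature_type, feats$start, feats$end,
                         g$strand, g$gene_id), con)
  }
  invisible(path)
}

# header comment recording provenance, prepended to all TSV reports
tsv_header_comment <- function(params = list()) {
  p <- paste(vapply(names(params), function(n) paste0(n, "=", params[[n]]),
                    character(1)), collapse = " ")
  sprintf("# mitedyn %s %s",
          as.character(utils::packageVersion("mitedyn")), p)
}

#' Write a report table as TSV with a provenance comment line
#'
#' @param df data.frame.
#' @param path output file.
#' @param params named list echoed into the leading comment line.
#' @export
write_report_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header_comment(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report table written by [write_report_tsv()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Parse coordinates in the start>end minus-strand convention
#'
#' Some published tables encode strand by printing coordinates with
#' `start > end` (e.g. `"4A: 619336977-619336798"`). This helper normalises
#' such a pair to `start <= end` plus an explicit strand, the only
#' convention this package emits.
#'
#' @param chrom chromosome name.
#' @param a,b the two printed coordinates.
#' @return list with `chrom`, `start`, `end`, `strand`.
#' @export
parse_printed_interval <- function(chrom, a, b) {
  list(chrom = chrom, start = min(a, b), end = max(a, b),
       strand = if (a <= b) "+" else "-")
}

#' Export intervals as BED6
#'
#' BED is 0-based half-open on disk; the 1-based inclusive intervals used
#' throughout the package are converted on write.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (1-based inclusive coordinates).
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(df$chrom, df$start - 1L, df$end, df$name,
                    round(df$score %||% 0), df$strand %||% "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
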