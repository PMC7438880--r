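# shared fixture builders: everything is generated in code, nothing on disk

rseq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# substitution-only mutation at the given per-site rate
mut <- function(seq, rate) mitedyn:::mutate_sequence(seq, rate)

# Biostrings substitution matrix matching the package's default scoring
sub_mat <- function(match = 2, mismatch = -3) {
  Biostrings::nucleotideSubstitutionMatrix(match = match,
                                           mismatch = mismatch,
                                           baseOnly = TRUE)
}

# plant a sequence inside a background at a 1-based position (after pos)
splice_in <- function(background, insert, pos) {
  paste0(substr(background, 1, pos), insert,
         substr(background, pos + 1, nchar(background)))
}

# one-chromosome assembly
asm1 <- function(seq, species = "SP", chrom = "c1") {
  genome_assembly(species, stats::setNames(seq, chrom))
}

# independent closed-form TN93 distance (Tamura & Nei 1993), used as the
# oracle against the package's distance wrapper
tn93_closed_form <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[keep]; bv <- bv[keep]; n <- length(av)
  f <- (table(factor(av, c("A", "C", "G", "T"))) +
        table(factor(bv, c("A", "C", "G", "T")))) / (2 * n)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- mean((av == "A" & bv == "G") | (av == "G" & bv == "A"))
  P2 <- mean((av == "C" & bv == "T") | (av == "T" & bv == "C"))
  Q <- mean((av %in% c("A", "G")) != (bv %in% c("A", "G")))
  k1 <- 2 * gA * gG / gR; k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    k3 * log(1 - Q / (2 * gR * gY))
}

# evolve a sequence along every edge of a random topology, returning aligned
# tip sequences (substitutions only, so already aligned)
evolve_tips <- function(tree, root_seq, rate_scale = 1) {
  n_tip <- length(tree$tip.label)
  seqs <- character(n_tip + tree$Nnode)
  seqs[n_tip + 1] <- root_seq
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqs[child] <- mut(seqs[par], min(0.7, tree$edge.length[e] * rate_scale))
  }
  stats::setNames(seqs[seq_len(n_tip)], tree$tip.label)
}
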