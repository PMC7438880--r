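---
title: "Methods: comparative MITE dynamics across polyploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative MITE dynamics across polyploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Miniature transposable elements (MITEs) are short (~100–600 bp)
non-autonomous class II elements. Because a transposition event duplicates a
few bases of host sequence on either side of the new copy (the target site
duplication, TSD), and because an insertion is either present or absent at
an orthologous locus, MITE insertions are near-ideal markers for comparing
related genomes: shared insertions are inherited from a common ancestor,
lineage-specific insertions date element activity, and loci whose flanks no
longer co-locate in a relative point to larger structural change.

`mitedyn` implements this comparative programme for a wheat-like species
set: two diploid donors (an A-genome and a D-genome species), two AB
tetraploids, and the ABD hexaploid. Every step — element retrieval, TSD
detection, cross-genome presence/absence, phylogenetics of element copies,
and rearrangement classification — runs on plain FASTA assemblies, and a
built-in simulator generates the whole species set with planted ground
truth so that every pipeline claim is testable end to end.

# Element retrieval

`scan_genome()` is a seed-and-extend homology search: exact k-mers (default
k = 12) of the family consensus are matched against both strands of the
assembly, seeds are clustered by diagonal (band 32), and each candidate
region is resolved by full affine-gap local alignment of the consensus
against it (match +2, mismatch −3, gap of length L costing 5 + 2L).
Isolated single seeds are ignored (the classical two-hit heuristic): on
desk-scale genomes they are almost surely random 12-mer collisions.

Hits are filtered by identity (default ≥ 0.80 over aligned columns,
counting gap columns against identity and N as mismatch), consensus
coverage (default ≥ 0.30, so truncated copies down to ~93 bp of a ~300-bp
consensus are kept) and a raw score floor. We deliberately do not use an
E-value cutoff: E-values depend on database size, which makes results
incomparable between assemblies; fixed identity/coverage thresholds
anchored to the family-definition convention (≥ 80% identity) are
deterministic and testable. A copy is called full-length at ≥ 0.85
consensus coverage — the short class of the emulated family tops out around
80% of the consensus length, so 0.85 separates the two printed classes;
the threshold is configurable.

`dedup_hits()` removes redundant overlapping hits (two consensus variants
often match the same copy): when two hits overlap by more than 25% of the
shorter one, only the better-scoring hit survives. The operation is
idempotent and order-independent, which the tests check by brute-force
pairwise elimination.

# TSD detection

`detect_tsd()` is junction-anchored: the left flank is taken on the genome
forward strand immediately before the element, the right flank immediately
after, regardless of element orientation, so detection is invariant to
element strand. It reports the longest L in [2, 10] such that the length-L
suffix of the left flank matches the length-L prefix of the right flank
with at most the allowed number of mismatches. One-base "duplications" are
never reported — a single base repeats at a quarter of all junctions by
chance. Exact matching is the default; the study preset allows one
mismatch, since observed 9-bp duplications of this family vary slightly.
For truncated copies with uncertain boundaries, an optional ±3 bp junction
slide rescues duplications that the nominal boundary misses; such calls are
flagged `adjusted`.

`tsd_logo()` reduces a motif set to a position frequency matrix (the
numeric backing of a sequence logo); rendering is left to the user.

# Cross-genome presence/absence

For each detected site, `map_locus()` places the two 1000-bp flanks in a
target assembly with the same seed-and-extend machinery, at stricter
thresholds (identity ≥ 0.90 over ≥ 0.80 of the flank): flanks are
near-unique sequence, so they can be held to a higher standard than the
repeated element itself. In the simulated polyploids the closest confound
is the homeologous locus, whose flanks sit at ~12–16% divergence — safely
below the 0.90 rule — while true orthologous flanks at ≤ ~6% divergence
pass comfortably.

When both flanks land on one chromosome in consistent orientation within
50 kb, the inter-flank gap is extracted and aligned against the element.
The gap is tested against the source site's own copy first and the family
consensus second: an orthologous copy inherits the source's truncation, so
coverage must be measured on what was actually at the source locus, not
only on the full-length consensus. `classify_presence()` then applies
fixed rules in order: full site (gap carries the element at ≥ 0.80/0.80),
empty site (gap ≤ 100 bp, absorbing TSD remnants and excision footprints),
rearranged candidate (one flank only, or inconsistent placements), absent
locus (no flank placed), otherwise ambiguous.

`membership_matrix()` clusters sites across species into orthologous loci:
site A joins site B's cluster when A's locus maps into B's species as a
full site whose inter-flank interval overlaps B. Components of this graph
are the clusters; non-transitive evidence is merged with a warning and
flagged. `venn_counts()` counts clusters by the exact species subset in
which they are full sites — empty sites mean "locus conserved, element
absent" and are reported separately, matching the presence/absence framing
of insertion-polymorphism studies.

# Phylogenetics of element copies

`progressive_msa()` is a classical progressive aligner (k-mer distance
guide tree via neighbor joining, then profile–profile global alignment
with the same scoring as the scanner). The profile scorer is constructed
so that the two-sequence case reduces *exactly* to standard global
alignment — the tests hold it to the dynamic-programming optimum computed
independently by `Biostrings::pairwiseAlignment`. No installed MSA tool
exposes this contract at this scoring, which is why the aligner is part of
the package rather than delegated.

Distances are Tamura–Nei (TN93) with empirical base frequencies and
pairwise column deletion, computed through `ape::dist.dna` behind the
package's wrappers; a closed-form implementation written independently in
the test suite serves as the oracle. Saturated pairs (log-domain
violations) are flagged and imputed as the largest finite distance plus
10% so tree building can proceed. Trees are neighbor joining (`ape::nj`)
with negative branch lengths clamped to zero and the deficit moved to the
sister branch. Bootstrap support resamples alignment columns with an
explicit seed (bit-reproducible), counts bipartitions with
`ape::prop.clades`, and can collapse branches below a support cutoff
(default 45%) into multifurcations. Full maximum-likelihood tree search is
intentionally out of scope: the comparative claims the pipeline makes are
cluster-membership claims, which distance methods reproduce on data of
this kind, and NJ is deterministic and oracle-testable.

`classify_subfamily()` assigns a copy to the consensus variant with the
highest global-alignment identity, requiring ≥ 0.80 and a ≥ 0.03 lead over
the runner-up; otherwise "unassigned" — the natural label for
head-of-one/tail-of-the-other intermediates, which the packaged two-variant
fixture pair (shared 39-bp head, 50-bp tail, divergent interiors, 300 and
291 bp) makes easy to construct in tests.

# Rearrangement classification

`anchor_matches()` computes dot-plot style local matches: exact k-mer hits
(k = 14) grouped by diagonal, merged into runs, extended by an x-drop rule
and filtered by length and identity. Two presets mirror the two scales the
package works at: 1000-bp anchors at 90% identity for genome-scale loci
(the conventional dot-plot setting) and 300-bp anchors for desk-scale
simulations. Because the simulator's background process is
substitution-only, collinear blocks stay on exact diagonals; the x-drop
extension reaches breakpoints to within a few bases.

`chain_and_classify()` formalizes what a practitioner reads off a dot
plot. Forward anchors are chained by weighted collinearity
(length × identity, bounded overlap); each gap between consecutive chain
anchors is typed:

* query gap, target continuous → **insertion** in the query. If the gap
  sequence re-matches a target span already covered by the chain, it is a
  **duplication**; if it matches nowhere in the target it is noted
  *possible introgression*.
* target gap, query continuous → **deletion** (sequence present in the
  target but lost from the query lineage), reported with the target span.
  If the gap is an extra copy of chain-covered query sequence, it is a
  **duplication** in the target.
* gaps on both sides covered by reverse-orientation anchors →
  **inversion**.
* gaps on both sides otherwise → a replacement, reported as deletion plus
  insertion.

Events are reported from the query's perspective with both spans listed.
Whether a query-only span is "an insertion in the query lineage" or "a
deletion in the target lineage" is a phylogenetic interpretation requiring
outgroup information; the tool reports the mechanical finding and leaves
the interpretation to the user, flagging both readings in the note.

`chromosome_walk()` grows a window around a polymorphic locus (5 kb start,
+10 kb per round, 100 kb cap) until anchors place both window ends on one
target chromosome; the same-name chromosome is searched first and the
whole genome as fallback (translocated context is noted). The final window
is dot-plotted and classified. A window that never places is reported
`unresolved` with its full length as residual.

# The simulator

`simulate_species_set()` generates the species set from one ancestral
sequence: the A, B and D sub-genome ancestors are drawn at 5% substitution
divergence from the ancestor (so homeologous loci are distinguishable from
orthologous ones but not trivially — cross-sub-genome flank identity lands
near 0.87, just below the 0.90 mapping rule, making homeolog confusion a
measurable failure mode rather than an impossible one), and every
lineage-split edge applies 2% substitutions. The background process is
substitutions only: no indels, so planted-feature coordinates remain exact
and every truth row can be verified against the emitted FASTA
byte-for-byte. Length changes enter only through planted element copies
(which duplicate `tsd_len` target bases, default 9) and planted
rearrangement events. Planted insertions keep ≥ 2.5 kb spacing so that
1000-bp flank windows never overlap a neighbouring element.

The five-genome preset plants the published sharing structure at desk
scale (500-kb sub-genomes): 2 ancient A-sub-genome insertions on the
A-ancestor branch (hence shared by the A-carrying species: the A diploid,
both tetraploids and the hexaploid), 6 D-lineage insertions shared by the
D diploid and the hexaploid, 10 tetraploid-branch insertions shared by
both tetraploids and the hexaploid, and 15/6/6/1/2 species-unique
insertions for the wild-emmer-like, durum-like, bread-wheat-like, D-diploid
and A-diploid genomes respectively. The ancient insertions are planted on
the A-ancestor branch rather than before the sub-genome split: no single
sub-genome is carried by all five species, so a pre-sub-genome planting
produces three *homeologous* loci rather than one orthologous cluster, and
its flanks (≥ 10% diverged) could not be clustered by any mapping rule the
package would otherwise trust. Divergence values are round numbers chosen
for separability and echoed in the config output; they are not calibrated
to any particular genome release.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: nested or fragmented repeat landscapes (a real
wheat genome is ~85% repeats; flank uniqueness is far harder there),
background indels and assembly gaps, within-species polymorphism, and
sequencing/assembly error. The pipeline's thresholds are honest defaults
for clean assemblies, not tuned constants for any particular dataset.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere in R structures and in all
  serialized output, with strand as a separate column; printed
  start>end minus-strand coordinates are normalised on input
  (`parse_printed_interval()`). This matches the convention of every
  substrate the package builds on (IRanges/GRanges, `substr`).
* Flank requests overrunning a contig end are clipped and flagged, not
  errors: kilobase windows overrun desk-scale contigs routinely.
* IUPAC ambiguity codes collapse to N with a warning; N counts as a
  mismatch in all identity computations.
* Alignment tie-breaks prefer the substitution state, making traceback
  deterministic; consensus ties break alphabetically; dedup ties prefer
  higher identity, then leftmost start.
* All stochastic steps (simulation, bootstrap) take explicit seeds;
  identical seeds give byte-identical outputs, which the tests hash.
* Problem sizes in the tests (500-kb sub-genomes for the five-genome
  scenario, ≤ 50-kb single-locus worlds, 20 replicates per rearrangement
  type × size cell, 100 six-taxon trees) were chosen as the smallest
  scales at which every claim is still distinguishable from noise.

# Known limitations

* Whole-genome alignment, synteny-block inference and general structural
  variant calling are out of scope; comparison is locus-anchored by
  design.
* Duplication calls pair one query span with at most two target spans;
  higher copy numbers are reported without pairing.
* The membership matrix takes the best flank placement per target; deep
  segmental duplications of a locus could in principle capture the wrong
  paralog (reciprocal-best and the element-in-gap check mitigate this).
* TN93 distances use `ape`'s empirical-frequency convention (frequencies
  over the whole alignment for matrices, over the pair for single pairs);
  on strongly compositionally heterogeneous data the two differ.
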