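---
title: "Methods: orthology, synteny and SNP population summaries in syntsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthology, synteny and SNP population summaries in syntsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntsnp)
```

## Scope and data model

`syntsnp` is a scriptable engine for comparative bacterial genomics built
around a simple data model: *n* genomes (or resequenced strains) are
compared against *one reference* genome. Two families of analyses are
supported and share that model:

* **Synteny**: protein-level orthology between the reference and each
  related genome (bi-directional best hits), chained into blocks of
  conserved gene order, and rendered as dot-plot, line-plot and
  phylogenetic-profile data.
* **Polymorphism**: SNPs called externally against the reference (one
  table, *n* strains), located relative to annotation, classified by coding
  effect, and summarised as density maps, frequency spectra,
  metadata-grouped counts, artificial alignments, distance matrices and
  neighbor-joining trees.

Everything is produced as plain data (data frames and tab-delimited files),
so results are diffable and scriptable. All coordinates are 1-based
inclusive, the native convention of the GenBank ptt annotation format; the
only 0-based formats, bedGraph and BED, are converted at the file boundary
and the conversion is unit-tested.

## Orthology: bi-directional best hits

Orthologs are called as bi-directional best hits (BDBH) from
all-against-all protein similarity reports: the pair (a, b) is kept iff b
is a's highest-scoring hit in the target genome and a is b's
highest-scoring hit in the reference. Two decisions deserve justification:

* **Deterministic tie-breaking.** Best-hit selection orders by bit score,
  then e-value, then percent identity, then lexicographic subject
  identifier. Similarity reports frequently contain exact score ties
  (truncated bit scores); without a documented chain the ortholog set would
  depend on input row order.
* **The BDBH call is threshold-free.** No e-value or coverage cut-off is
  applied before reciprocity. Thresholds exist, but as an explicit,
  separate filtering step on the profile matrix (`filter_profile()`),
  mirroring how an analyst interactively tightens identity/coverage
  filters. This keeps the orthology call itself reproducible and makes
  every threshold visible in the run manifest.

Self-hits are discarded before best-hit selection so that self-comparisons
behave sensibly.

## Synteny blocks: greedy gap-bounded chaining

Conserved gene order is detected by chaining ortholog pairs sorted by
reference gene index. A pair extends the open chain when its reference
index advances by at most `max_gap + 1`, its target index moves by at most
`max_gap + 1` *in the chain's direction*, and the direction (ascending or
descending target index) is consistent within the chain. A chain of one
pair has no direction yet; the second member fixes it. Chains shorter than
`min_pairs` are discarded and reported as unchained.

Defaults are `max_gap = 3` (tolerate up to three skipped genes on either
genome, absorbing small insertions and annotation noise) and
`min_pairs = 2` (a single isolated pair is not evidence of conserved
order). This is deliberately the simplest rule that reproduces the
behaviours a synteny browser displays — local alignment of homologous
regions, rupture detection at rearrangement breakpoints, inversions drawn
as anti-diagonals — and it is fully checkable against a brute-force
maximal-run scanner at `max_gap = 0`, which the test suite does on planted
rearrangements.

Chaining does not wrap across the replicon origin by default, because a
wrapped block has no unambiguous linear coordinates; `wrap = TRUE` merges a
prefix and a suffix chain when both genomes are circular and the chaining
rule would join them across the origin.

The local-view alignment offset is anchored on a single gene: clicking gene
g translates a target genome by `midpoint(g) - midpoint(ortholog(g))`. An
orphan anchor yields no offset.

## SNP location and coding effect

A SNP is genic when at least one gene satisfies
`start <= position <= end`; overlapping genes each receive an annotation
row (no primary-gene heuristic — downstream consumers can re-bin, and
nothing is lost). Interval stabbing uses `IRanges::findOverlaps`.

Effect classification anchors the reading frame at the annotated start
codon. For a forward-strand gene with 0-based offset `o = position - start`:
`codon_index = o %/% 3 + 1`, `codon_position = o %% 3 + 1`. For
reverse-strand genes offsets are counted from the gene end and both codons
are reverse-complemented before translation. Translation uses the
bacterial/archaeal genetic code (table 11), with no special handling of
initiation codons — internal codon semantics apply everywhere, which keeps
the classification strand- and position-symmetric.

The classes are `synonymous` (amino acids equal), `stop_gained` (alternate
amino acid is a stop, reference is not), `nonsynonymous` (everything else,
including stop loss), and `intergenic`. Stop loss is folded into
`nonsynonymous` as the minimal extension of a three-way
synonymous/nonsynonymous/stop scheme; the full codon bookkeeping
(`ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`) is emitted so users can
re-bin. Degenerate inputs degrade explicitly rather than silently: a gene
whose length is not a multiple of three triggers a warning and positions
past the last complete codon are classified `unknown`; a codon containing
an ambiguous base (N) is classified `unknown`.

The implementation is codon arithmetic plus a genetic-code lookup. Its
oracle — used by the tests and by the simulator's ground truth — is an
independent route: extract the whole gene before and after the
substitution, translate both with Biostrings, and compare the proteins.
The two routes agree on 100% of unambiguous sites in a 10,000-SNP
verification run.

## Population summaries

* **Frequency spectrum**: for each polymorphic position, the number and
  fraction of analysed strains carrying a non-reference allele.
* **Density maps**: per-gene mode counts genic SNP records per gene (a SNP
  under two overlapping genes counts once per gene); per-kb mode tiles
  `[1, genome length]` with fixed windows anchored at position 1, the last
  window possibly short — the simplest deterministic tiling, chosen so
  window counts always sum to the total SNP count.
* **Grouped densities**: strains are split by a metadata attribute; strains
  lacking the attribute go to an explicit `"unassigned"` category, so group
  maps always sum to the global map — an invariant the tests exercise on
  random partitions.
* **Artificial alignment**: the strains-by-positions allele matrix over the
  union of polymorphic positions (optionally restricted to a gene basket).
  The reference is included as the first row; a strain absent from the SNP
  table at a column carries the reference allele there. This treats
  "no SNP recorded" as reference-identical rather than missing data — the
  input format has no missing-data symbol, and resequencing pipelines
  report only variant positions.
* **Distances and trees**: `p_distance` is the fraction of mismatching
  columns; `jukes_cantor` applies `-(3/4) log(1 - 4p/3)` and refuses
  `p >= 3/4`. Trees are built by neighbor joining (via `ape::nj`), which is
  consistent on additive matrices; the 3-taxon and additive 4-taxon cases
  are verified exactly in the tests.
* **Strain ordering**: by tree leaf order, or by "autoscore" —
  implemented here as ascending p-distance to the reference row of the
  artificial alignment, ties broken lexicographically. The autoscore is an
  interpretation (strains most similar to the reference sort first, so
  related strains cluster near the reference track); it is deterministic
  and documented rather than reverse-engineered.
* **Coverage anomalies**: maximal intervals whose depth stays below a
  threshold over at least a minimum span, with uncovered positions counted
  as depth 0 — the signature used to flag candidate absent genomic islands
  in resequencing data.

### A caution on Jukes–Cantor distances from SNP-only alignments

The artificial alignment contains only segregating sites, so its p values
are mismatch fractions over polymorphic columns — much larger than per-site
divergence. The Jukes–Cantor correction assumes per-site p; applied to
SNP-only columns it is mis-specified: the convex transform stretches long
distances disproportionately and degrades additivity, which can cost
neighbor joining short internal branches. In the package's own recovery
experiments (20-leaf trees, ~1,900 segregating sites), NJ on p-distances
recovered the generating topology in 100% of replicates, while NJ on
JC-corrected distances recovered it in 85–95%. Both models are provided;
for SNP-only alignments the p-distance is the safer default, and the
acceptance script reports both rates.

## The simulator and what it does (not) emulate

Every analysis above is testable against planted ground truth without any
external download:

* `sim_genome()` builds annotated replicons whose genes are valid ORFs
  (ATG start, sense internal codons, one terminal stop, length divisible by
  three) on random strands, separated by random spacers. Defaults
  (900 bp mean gene length, 150 bp spacers) approximate typical bacterial
  gene density.
* `sim_rearrangement()` cuts the gene order into contiguous segments,
  permutes and optionally inverts them, and returns the true ortholog map
  and segment structure. Draws are rejected until the rearrangement is
  "clean": every segment has at least two genes and no two segments land
  adjacent in a re-joining order/orientation — otherwise the planted
  segment count would be unrecoverable *by construction*, and block
  detection could not be graded against it.
* `sim_snps()` drops substitutions along each branch of a strain tree
  under a Jukes–Cantor process (Poisson event counts with mean
  `rate x branch length x genome length`, uniform positions, uniform
  alternative base). Events apply root-to-tip, so sister strains share
  stem mutations; two hits at one site on one lineage are collisions,
  resolved last-event-wins and counted. Leaf SNP tables are exact diffs of
  the leaf haplotype against the reference, and per-SNP true effects are
  computed by the whole-gene translation oracle.
* `sim_tree()` draws random topologies with branch lengths uniform on
  `[0.1, 1]`: the lower bound keeps every internal branch long enough
  (about ten expected substitutions at the default rates and genome sizes)
  that topology recovery is informative about the method rather than about
  vanishing branches.

The simulator deliberately does **not** emulate horizontal transfer,
recombination, codon usage bias, indels, back-mutation pressure at high
rates, gene gain/loss, or sequencing error. Passing tests therefore
demonstrate algorithmic correctness on clean planted structure, not
robustness to the full messiness of real bacterial populations — with real
data, ortholog misassignment and recombination will blur blocks and trees
in ways these tests do not measure.

## Verification scale and seeds

Every stochastic routine takes an explicit seed (default 1) and is fully
deterministic given it. The bundled verification (tests and
`scripts/acceptance.R`) runs at desk scale, chosen to finish in minutes on
one CPU while leaving no statistical ambiguity: 1,000-gene genomes
rearranged into 1–8 segments (10 seeds each) for synteny recovery; 100
random similarity instances (up to 200 genes a side) against a brute-force
reciprocity oracle; 10,000 simulated genic SNPs against the
translation oracle; 20 replicates of 20-strain SNP simulations
(~1,900 segregating sites each) for tree recovery; and a complete
12-subcommand demo pipeline (120 genes, 20 strains) with checksum-validated
manifests.

## Known limitations

* ptt is the only annotation format (no GenBank flat file or GFF), matching
  the engine's input contract; wrap-around (origin-spanning) genes cannot
  be represented in ptt and are rejected at parse time.
* Only single-nucleotide substitutions are handled — no indels,
  multi-nucleotide variants, or multiploid genotypes.
* BDBH yields one-to-one pairs only; paralog families and synteny-aware
  orthology clustering are out of scope.
* The "autoscore" ordering is this package's own deterministic definition,
  not a reconstruction of any particular browser's internal score.
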