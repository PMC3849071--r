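# Seeded synthetic-data generator: genomes with planted gene orders,
# rearranged derivatives with known ortholog maps and segment structure,
# and strain collections with SNPs dropped down a known tree with known
# haplotypes and effects. Everything the engine reads can be generated
# here, with full ground truth, so every analysis is testable end to end.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Simulate an annotated bacterial genome
#'
#' Genes are valid open reading frames: an ATG start codon, internal codons
#' drawn from the 61 sense codons (no internal stops), and a stop codon;
#' gene length is always a multiple of three. Genes are separated by random
#' intergenic spacers and placed on randomly chosen strands (a
#' reverse-strand gene is stored as the reverse complement of its ORF).
#' Fully deterministic per seed.
#'
#' @param n_genes Number of genes.
#' @param mean_gene_len Mean gene length in bp (Poisson-distributed codon
#'   count, minimum 10 codons).
#' @param intergenic_len Mean intergenic spacer length in bp.
#' @param genome_id Genome label.
#' @param circular Mark the replicon circular.
#' @param with_sequence Generate the nucleotide sequence (disable for
#'   gene-order-only work where only coordinates matter).
#' @param seed Integer seed.
#' @return A [genome_record()] with annotation (gene ids `g0001`, ...) and,
#'   unless disabled, sequence.
#' @export
sim_genome <- function(n_genes = 100L, mean_gene_len = 900L,
                       intergenic_len = 150L, genome_id = "ref",
                       circular = FALSE, with_sequence = TRUE, seed = 1L) {
  stopifnot(n_genes >= 1L, mean_gene_len > 0, intergenic_len > 0)
  set.seed(seed)
  n_codons <- pmax(10L, stats::rpois(n_genes, mean_gene_len / 3))
  spacer <- pmax(10L, stats::rpois(n_genes + 1L, intergenic_len))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- 3L * n_codons
  start <- cumsum(c(spacer[1L] + 1L,
                    if (n_genes > 1L) glen[-n_genes] + spacer[2:n_genes]))
  end <- start + glen - 1L
  genome_length <- end[n_genes] + spacer[n_genes + 1L]
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    name = sprintf("sg%04d", seq_len(n_genes)),
    start = start, end = end, strand = strand,
    length_aa = n_codons - 1L,
    pid = sprintf("%d", 90000000L + seq_len(n_genes)),
    product = sprintf("simulated protein %d", seq_len(n_genes)),
    stringsAsFactors = FALSE)
  sequence <- NULL
  if (with_sequence) {
    sense <- setdiff(all_codons(), STOP_CODONS)
    bases <- c("A", "C", "G", "T")
    orf <- vapply(seq_len(n_genes), function(i) {
      paste0("ATG",
             paste(sample(sense, n_codons[i] - 2L, replace = TRUE),
                   collapse = ""),
             sample(STOP_CODONS, 1L))
    }, "")
    orf[strand == "-"] <- revcomp(orf[strand == "-"])
    spacer_seq <- vapply(spacer, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    parts <- character(2L * n_genes + 1L)
    parts[seq(1L, 2L * n_genes + 1L, by = 2L)] <- spacer_seq
    parts[seq(2L, 2L * n_genes, by = 2L)] <- orf
    sequence <- paste(parts, collapse = "")
  }
  genome_record(genome_id, genes, length = genome_length,
                sequence = sequence, circular = circular,
                description = paste("simulated genome", genome_id))
}

#' Rearrange a genome into planted oriented segments
#'
#' Cuts the gene order into `n_segments` contiguous runs, permutes the
#' runs, and independently inverts each with probability `invert_prob`
#' (inversion reverses gene order, flips strands and reverse-complements
#' the sequence). Gene content is preserved; target genes are renamed
#' (`t0001`, ...) and the true ortholog map and segment structure are
#' returned as ground truth.
#'
#' By default the rearrangement is required to be "clean": every segment
#' holds at least `min_segment_genes` genes and no two segments end up
#' adjacent in an order/orientation that re-joins them into one collinear
#' or inverted run (which would make the planted segment count
#' unrecoverable by construction rather than by algorithm); draws are
#' rejected and resampled until clean.
#'
#' @param genome A [genome_record()] from [sim_genome()].
#' @param n_segments Number of planted segments (1 = identity candidate).
#' @param invert_prob Per-segment inversion probability.
#' @param target_id Label for the derived genome.
#' @param min_segment_genes Minimum genes per segment (default 2, so every
#'   planted segment is reportable as a block).
#' @param seed Integer seed.
#' @param max_tries Resampling budget for the cleanliness requirement.
#' @return List with `target` (a [genome_record()]), and `truth`: a list
#'   holding `ortholog_map` (data frame `ref_gene_id`, `target_gene_id`),
#'   `pairs` (a perfect-score ortholog pair table usable directly by the
#'   synteny module), and `segments` (data frame, one row per planted
#'   segment in target order: `ref_first`, `ref_last` reference gene
#'   indices, `inverted`).
#' @export
sim_rearrangement <- function(genome, n_segments, invert_prob = 0.3,
                              target_id = "target", min_segment_genes = 2L,
                              seed = 1L, max_tries = 1000L) {
  n <- nrow(genome$genes)
  if (n_segments > n) stop_syntsnp("n_segments exceeds the gene count")
  if (n_segments * min_segment_genes > n)
    stop_syntsnp("cannot cut ", n, " genes into ", n_segments,
                 " segments of >= ", min_segment_genes, " genes")
  set.seed(seed)

  draw <- function() {
    cuts <- if (n_segments > 1L)
      sort(sample(which(seq_len(n - 1L) >= 1L), n_segments - 1L))
    else integer()
    first <- c(1L, cuts + 1L)
    last <- c(cuts, n)
    perm <- sample(n_segments)
    inv <- stats::runif(n_segments) < invert_prob
    list(first = first, last = last, perm = perm, inv = inv)
  }
  clean <- function(d) {
    sizes <- d$last - d$first + 1L
    if (any(sizes < min_segment_genes)) return(FALSE)
    if (n_segments == 1L) return(TRUE)
    # placed order: segment d$perm[k] at position k
    for (k in seq_len(n_segments - 1L)) {
      a <- d$perm[k]; b <- d$perm[k + 1L]
      ia <- d$inv[a]; ib <- d$inv[b]
      # boundary ref indices in target orientation
      a_last <- if (ia) d$first[a] else d$last[a]
      b_first <- if (ib) d$last[b] else d$first[b]
      joins <- (!ia && !ib && b_first == a_last + 1L) ||
               (ia && ib && b_first == a_last - 1L)
      if (joins) return(FALSE)
    }
    TRUE
  }
  d <- NULL
  for (t in seq_len(max_tries)) {
    cand <- draw()
    if (clean(cand)) { d <- cand; break }
  }
  if (is.null(d))
    stop_syntsnp("could not draw a clean rearrangement in ", max_tries,
                 " tries")

  g <- genome$genes
  has_seq <- !is.null(genome$sequence)
  # bp cut points: halfway through the intergenic gap before each segment's
  # first gene (and after the last gene), so each chunk carries its genes.
  seg_bp <- function(i) {
    from_gene <- d$first[i]; to_gene <- d$last[i]
    from_bp <- if (from_gene == 1L) 1L
               else (g$end[from_gene - 1L] + g$start[from_gene]) %/% 2L + 1L
    to_bp <- if (to_gene == n) genome$length
             else (g$end[to_gene] + g$start[to_gene + 1L]) %/% 2L
    c(from_bp, to_bp)
  }
  new_genes <- list()
  new_seq <- character(n_segments)
  offset <- 0L
  ref_order_of_target <- integer(0)
  for (k in seq_len(n_segments)) {
    s <- d$perm[k]
    bp <- seg_bp(s)
    idx <- seq.int(d$first[s], d$last[s])
    gg <- g[idx, , drop = FALSE]
    seg_len <- bp[2L] - bp[1L] + 1L
    if (d$inv[s]) {
      new_start <- offset + (bp[2L] - gg$end) + 1L
      new_end <- offset + (bp[2L] - gg$start) + 1L
      gg$start <- new_start; gg$end <- new_end
      gg$strand <- ifelse(gg$strand == "+", "-", "+")
      gg <- gg[rev(seq_len(nrow(gg))), , drop = FALSE]
      idx <- rev(idx)
      if (has_seq)
        new_seq[k] <- revcomp(substring(genome$sequence, bp[1L], bp[2L]))
    } else {
      shift <- offset - bp[1L] + 1L
      gg$start <- gg$start + shift; gg$end <- gg$end + shift
      if (has_seq)
        new_seq[k] <- substring(genome$sequence, bp[1L], bp[2L])
    }
    new_genes[[k]] <- gg
    ref_order_of_target <- c(ref_order_of_target, idx)
    offset <- offset + seg_len
  }
  tg <- do.call(rbind, new_genes)
  ref_ids <- tg$gene_id
  tg$gene_id <- sprintf("t%04d", seq_len(n))
  tg$name <- sprintf("st%04d", seq_len(n))
  tg$pid <- sprintf("%d", 91000000L + seq_len(n))
  map <- data.frame(ref_gene_id = ref_ids, target_gene_id = tg$gene_id,
                    stringsAsFactors = FALSE)
  target <- genome_record(target_id, tg, length = offset,
                          sequence = if (has_seq)
                            paste(new_seq, collapse = "") else NULL,
                          circular = genome$circular,
                          description = paste("rearranged derivative of",
                                              genome$genome_id))
  pairs <- data.frame(ref_gene_id = map$ref_gene_id,
                      target_genome_id = target_id,
                      target_gene_id = map$target_gene_id,
                      pct_identity = 100, query_cov = 1,
                      bit_score = 2 * (g$end[match(map$ref_gene_id,
                                                   g$gene_id)] -
                                       g$start[match(map$ref_gene_id,
                                                     g$gene_id)] + 1) / 3,
                      e_value = 0, stringsAsFactors = FALSE)
  pairs <- pairs[order(match(pairs$ref_gene_id, g$gene_id)), , drop = FALSE]
  rownames(pairs) <- NULL
  segments <- data.frame(
    segment_id = seq_len(n_segments),
    ref_first = d$first[d$perm], ref_last = d$last[d$perm],
    inverted = d$inv[d$perm])
  list(target = target,
       truth = list(ortholog_map = map, pairs = pairs, segments = segments))
}

#' Simulate reciprocal similarity reports for a known ortholog map
#'
#' Emits 12-column tabular hits in both directions: one strong hit per true
#' ortholog pair (high identity and bit score, full coverage) plus optional
#' weaker decoy hits against random non-orthologous genes, so best-hit
#' selection is actually exercised.
#'
#' @param ref,target [genome_record()]s.
#' @param map Data frame `ref_gene_id`, `target_gene_id` (true pairs).
#' @param decoy_rate Expected number of decoy hits per gene.
#' @param seed Integer seed.
#' @return List with data frames `ab` (ref query) and `ba` (target query)
#'   in [read_blast_tabular()] layout, plus named vectors `ref_lengths`
#'   and `target_lengths` (protein lengths in aa).
#' @export
sim_similarity <- function(ref, target, map, decoy_rate = 0.5, seed = 1L) {
  set.seed(seed)
  aa_len <- function(g) {
    stats::setNames((g$genes$end - g$genes$start + 1L) %/% 3L - 1L,
                    g$genes$gene_id)
  }
  rlen <- aa_len(ref); tlen <- aa_len(target)
  mk_true <- function(q, s, qlen) {
    n <- length(q)
    pid <- stats::runif(n, 80, 100)
    data.frame(query_id = q, subject_id = s, pct_identity = round(pid, 2),
               aln_length = qlen, mismatch = round(qlen * (100 - pid) / 100),
               gapopen = 0L, qstart = 1L, qend = qlen, sstart = 1L,
               send = qlen, e_value = 10^-stats::runif(n, 50, 180),
               bit_score = round(2 * qlen * pid / 100, 1),
               stringsAsFactors = FALSE)
  }
  mk_decoys <- function(qids, sids, qlen) {
    n_dec <- stats::rpois(1L, decoy_rate * length(qids))
    if (!n_dec) return(NULL)
    q <- sample(qids, n_dec, replace = TRUE)
    s <- sample(sids, n_dec, replace = TRUE)
    len <- pmax(20L, round(unname(qlen[q]) * stats::runif(n_dec, 0.2, 0.8)))
    pid <- stats::runif(n_dec, 25, 60)
    data.frame(query_id = q, subject_id = s, pct_identity = round(pid, 2),
               aln_length = len, mismatch = round(len * (100 - pid) / 100),
               gapopen = 1L, qstart = 1L, qend = len, sstart = 1L,
               send = len, e_value = 10^-stats::runif(n_dec, 2, 20),
               bit_score = round(2 * len * pid / 100, 1),
               stringsAsFactors = FALSE)
  }
  ab <- mk_true(map$ref_gene_id, map$target_gene_id,
                unname(rlen[map$ref_gene_id]))
  ba <- mk_true(map$target_gene_id, map$ref_gene_id,
                unname(tlen[map$target_gene_id]))
  ba$bit_score <- ab$bit_score  # reciprocal hits score alike
  ab <- rbind(ab, mk_decoys(ref$genes$gene_id, target$genes$gene_id, rlen))
  ba <- rbind(ba, mk_decoys(target$genes$gene_id, ref$genes$gene_id, tlen))
  add_cov <- function(h, qlen) {
    h$query_cov <- pmin(1, (h$qend - h$qstart + 1) / unname(qlen[h$query_id]))
    h
  }
  list(ab = add_cov(ab, rlen), ba = add_cov(ba, tlen),
       ref_lengths = rlen, target_lengths = tlen)
}

#' Simulate SNPs down a known phylogeny
#'
#' Drops substitutions along every branch of a tree under a Jukes-Cantor
#' process: the number of events on a branch is Poisson with mean
#' `subs_per_site * branch length * genome length` (branch lengths default
#' to 1 when the tree has none), positions are uniform, and the new base is
#' uniform over the three alternatives. Events are applied root-to-tip, so
#' sister leaves share the mutations on their common stem. Two events at
#' one site on one root-to-leaf path are a collision: the last event wins
#' and the count is reported. Each leaf's SNP set is the exact difference
#' between its haplotype and the reference.
#'
#' @param genome Reference [genome_record()] with sequence.
#' @param tree ape `phylo`; leaves are the strain ids.
#' @param subs_per_site Expected substitutions per site per unit branch
#'   length.
#' @param seed Integer seed.
#' @param record_effects Also classify every genic SNP by whole-gene
#'   translation (see [effects_by_translation()]) into the ground truth.
#' @return List with `snps` (data frame over all strains), `haplotypes`
#'   (named character vector of leaf sequences), `effects` (data frame from
#'   [effects_by_translation()], or `NULL`), `n_collisions`, and `tree`.
#' @export
sim_snps <- function(genome, tree, subs_per_site = 0.001, seed = 1L,
                     record_effects = TRUE) {
  if (is.null(genome$sequence)) stop_syntsnp("genome sequence required")
  stopifnot(subs_per_site > 0)
  set.seed(seed)
  L <- genome$length
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  bl <- tree$edge.length %||% rep(1, nrow(tree$edge))
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  n_collisions <- 0L
  # preorder: reverse postorder guarantees parents before children
  edge_order <- rev(ape::postorder(tree))
  mutated <- vector("list", ntip + tree$Nnode)  # positions hit on the path
  mutated[[root]] <- integer()
  for (e in edge_order) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    s <- seqs[[par]]
    n_mut <- stats::rpois(1L, subs_per_site * bl[e] * L)
    hit <- integer()
    if (n_mut > 0L) {
      pos <- sample.int(L, n_mut, replace = TRUE)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
      hit <- pos
    }
    path_hits <- c(mutated[[par]], hit)
    n_collisions <- n_collisions + sum(duplicated(path_hits)) -
      sum(duplicated(mutated[[par]]))
    seqs[[child]] <- s
    mutated[[child]] <- path_hits
  }
  if (n_collisions > 0L)
    message("sim_snps: ", n_collisions,
            " site collisions (last event wins)")
  ref_chars <- seqs[[root]]
  haplotypes <- stats::setNames(
    vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), ""),
    tree$tip.label)
  snps <- do.call(rbind, lapply(seq_len(ntip), function(i) {
    pos <- which(seqs[[i]] != ref_chars)
    data.frame(strain_id = rep(tree$tip.label[i], length(pos)),
               position = pos, ref_allele = ref_chars[pos],
               alt_allele = seqs[[i]][pos], stringsAsFactors = FALSE)
  }))
  if (is.null(snps))
    snps <- data.frame(strain_id = character(), position = integer(),
                       ref_allele = character(), alt_allele = character())
  effects <- if (record_effects && nrow(snps))
    effects_by_translation(snps, genome) else NULL
  list(snps = snps, haplotypes = haplotypes, effects = effects,
       n_collisions = n_collisions, tree = tree)
}

#' Classify SNP effects by whole-gene translation
#'
#' Reference oracle for effect classification, independent of codon
#' arithmetic: for every (SNP, overlapping gene), the full gene sequence is
#' extracted before and after applying the substitution, both are
#' translated (table 11, reverse-complemented first for minus-strand
#' genes), and the proteins compared. The effect is `synonymous` when they
#' are equal, `stop_gained` when a stop newly appears at the mutated codon,
#' else `nonsynonymous`. Genes whose length is not a multiple of three and
#' codons containing N give `unknown`.
#'
#' @param snps SNP data frame.
#' @param genome Reference [genome_record()] with sequence.
#' @return Data frame `strain_id`, `position`, `gene_id`, `effect` for
#'   every genic (SNP, gene) combination.
#' @export
effects_by_translation <- function(snps, genome) {
  loc <- locate_snps(snps, genome)
  if (!nrow(loc))
    return(data.frame(strain_id = character(), position = integer(),
                      gene_id = character(), effect = character()))
  gi <- match(loc$gene_id, genome$genes$gene_id)
  g <- genome$genes[gi, ]
  pos <- snps$position[loc$snp_row]
  alt <- snps$alt_allele[loc$snp_row]
  glen <- g$end - g$start + 1L
  ref_nt <- substring(genome$sequence, g$start, g$end)
  alt_nt <- paste0(substring(ref_nt, 1L, pos - g$start),
                   alt,
                   substring(ref_nt, pos - g$start + 2L, glen))
  minus <- g$strand == "-"
  ref_nt[minus] <- revcomp(ref_nt[minus])
  alt_nt[minus] <- revcomp(alt_nt[minus])
  frame_ok <- glen %% 3L == 0L
  effect <- rep("unknown", nrow(loc))
  idx <- which(frame_ok & !grepl("N", ref_nt, fixed = TRUE) &
               !grepl("N", alt_nt, fixed = TRUE))
  if (length(idx)) {
    gc11 <- genetic_code_11()
    tr <- function(x) {
      as.character(Biostrings::translate(
        Biostrings::DNAStringSet(x), genetic.code = gc11,
        if.fuzzy.codon = "X", no.init.codon = TRUE))
    }
    p_ref <- tr(ref_nt[idx])
    p_alt <- tr(alt_nt[idx])
    same <- p_ref == p_alt
    effect[idx][same] <- "synonymous"
    # codon index of the mutated site in CDS orientation
    cds_off <- ifelse(minus[idx], g$end[idx] - pos[idx], pos[idx] - g$start[idx])
    ci <- cds_off %/% 3L + 1L
    ref_aa <- substring(p_ref, ci, ci)
    alt_aa <- substring(p_alt, ci, ci)
    effect[idx][!same & alt_aa == "*" & ref_aa != "*"] <- "stop_gained"
    effect[idx][!same & !(alt_aa == "*" & ref_aa != "*")] <- "nonsynonymous"
    # a codon with an unknown amino acid (should not happen for ACGT input)
    effect[idx][is.na(same)] <- "unknown"
  }
  data.frame(strain_id = snps$strain_id[loc$snp_row], position = pos,
             gene_id = loc$gene_id, effect = effect,
             stringsAsFactors = FALSE)
}

#' Simulate a random strain phylogeny
#'
#' Random bifurcating topology (ape::rtree) with branch lengths drawn
#' uniformly from `branch_range`; the lower bound keeps internal branches
#' long enough to accumulate signal under the simulator's substitution
#' rates.
#'
#' @param n_strains Number of leaves; labelled `s01`, `s02`, ...
#' @param branch_range Length-2 numeric range for branch lengths.
#' @param seed Integer seed.
#' @return An ape `phylo`.
#' @export
sim_tree <- function(n_strains, branch_range = c(0.1, 1), seed = 1L) {
  set.seed(seed)
  tree <- ape::rtree(n_strains, rooted = TRUE,
                     br = function(n) stats::runif(n, branch_range[1L],
                                                   branch_range[2L]))
  tree$tip.label <- sprintf("s%02d", seq_len(n_strains))
  tree
}

#' Simulate a coverage track with planted low-coverage islands
#'
#' Piecewise-constant depths around `mean_depth` with `n_islands` planted
#' near-zero segments of `island_span` bp — the signature of an absent
#' genomic island in resequencing data.
#'
#' @param genome_length Track extent in bp.
#' @param strain_id Strain label.
#' @param mean_depth Background depth.
#' @param n_islands Number of planted low segments.
#' @param island_span Length of each island in bp.
#' @param seed Integer seed.
#' @return List with `track` (a `coverage_track` data frame) and
#'   `islands` (data frame of planted `start`, `end`).
#' @export
sim_coverage <- function(genome_length, strain_id = "s01", mean_depth = 50,
                         n_islands = 1L, island_span = 5000L, seed = 1L) {
  set.seed(seed)
  step <- 1000L
  # islands are window-aligned so the planted extent is exactly recoverable
  island_span <- max(step, (island_span %/% step) * step)
  starts <- seq.int(1L, genome_length, by = step)
  ends <- pmin(starts + step - 1L, genome_length)
  depth <- pmax(1, round(stats::rnorm(length(starts), mean_depth,
                                      mean_depth / 5)))
  gap <- genome_length %/% (n_islands + 1L)
  isl_start <- (seq_len(n_islands) * gap) %/% step * step + 1L
  isl_start <- pmin(isl_start,
                    (genome_length - island_span) %/% step * step + 1L)
  islands <- data.frame(start = isl_start,
                        end = isl_start + island_span - 1L)
  for (i in seq_len(n_islands)) {
    hit <- starts >= islands$start[i] & starts <= islands$end[i]
    depth[hit] <- 0
  }
  track <- data.frame(strain_id = strain_id, start = starts, end = ends,
                      depth = depth)
  class(track) <- c("coverage_track", "data.frame")
  list(track = track, islands = islands)
}

#' Write a complete demonstration dataset with ground truth
#'
#' Generates and writes every input format the engine reads: a reference
#' genome (ptt + FASTA), two rearranged derivative genomes with reciprocal
#' similarity reports (tabular) and true correspondence files, a strain
#' tree (Newick), a SNP table simulated down that tree, strain metadata
#' grouping the strains by the tree's basal split, and a coverage track
#' (bedGraph) with one planted low-coverage island.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Reference gene count.
#' @param n_strains Number of SNP-carrying strains.
#' @param subs_per_site Substitution rate for the SNP simulation.
#' @param seed Integer seed controlling the whole dataset.
#' @return Invisibly, a list with the generated objects and ground truth
#'   (`ref`, `targets`, `similarities`, `tree`, `snp_sim`, `coverage`,
#'   `paths`).
#' @export
sim_demo_dataset <- function(dir, n_genes = 120L, n_strains = 20L,
                             subs_per_site = 5e-4, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- sim_genome(n_genes = n_genes, genome_id = "ref", seed = seed)
  r1 <- sim_rearrangement(ref, n_segments = 3L, target_id = "genomeB",
                          seed = seed + 1L)
  r2 <- sim_rearrangement(ref, n_segments = 5L, target_id = "genomeC",
                          seed = seed + 2L)
  s1 <- sim_similarity(ref, r1$target, r1$truth$ortholog_map,
                       seed = seed + 3L)
  s2 <- sim_similarity(ref, r2$target, r2$truth$ortholog_map,
                       seed = seed + 4L)
  tree <- sim_tree(n_strains, seed = seed + 5L)
  snp_sim <- sim_snps(ref, tree, subs_per_site = subs_per_site,
                      seed = seed + 6L)
  cov <- sim_coverage(ref$length, strain_id = tree$tip.label[1L],
                      n_islands = 1L,
                      island_span = max(2000L, ref$length %/% 20L),
                      seed = seed + 7L)
  # metadata: group strains by the tree's basal split
  basal <- ape::prop.part(tree)[[2L]] %||% seq_len(n_strains %/% 2L)
  grp <- ifelse(seq_len(n_strains) %in% basal, "cladeA", "cladeB")
  metadata <- data.frame(strain_id = tree$tip.label, group = grp,
                         stringsAsFactors = FALSE)

  p <- function(...) file.path(dir, ...)
  paths <- list(
    ref_ptt = p("ref.ptt"), ref_fasta = p("ref.fna"),
    b_ptt = p("genomeB.ptt"), b_fasta = p("genomeB.fna"),
    c_ptt = p("genomeC.ptt"), c_fasta = p("genomeC.fna"),
    blast_ref_b = p("ref_vs_genomeB.blast"),
    blast_b_ref = p("genomeB_vs_ref.blast"),
    blast_ref_c = p("ref_vs_genomeC.blast"),
    blast_c_ref = p("genomeC_vs_ref.blast"),
    corr_b = p("ref_genomeB.corr.tsv"), corr_c = p("ref_genomeC.corr.tsv"),
    tree = p("strains.nwk"), snps = p("snps.tsv"),
    metadata = p("metadata.tsv"), bedgraph = p("coverage.bedgraph"))
  write_ptt(ref, paths$ref_ptt)
  write_fasta(stats::setNames(ref$sequence, ref$genome_id), paths$ref_fasta)
  write_ptt(r1$target, paths$b_ptt)
  write_fasta(stats::setNames(r1$target$sequence, "genomeB"), paths$b_fasta)
  write_ptt(r2$target, paths$c_ptt)
  write_fasta(stats::setNames(r2$target$sequence, "genomeC"), paths$c_fasta)
  write_blast_tabular(s1$ab, paths$blast_ref_b)
  write_blast_tabular(s1$ba, paths$blast_b_ref)
  write_blast_tabular(s2$ab, paths$blast_ref_c)
  write_blast_tabular(s2$ba, paths$blast_c_ref)
  write_correspondence(r1$truth$pairs, paths$corr_b)
  write_correspondence(r2$truth$pairs, paths$corr_c)
  write_newick(tree, paths$tree)
  write_snp_table(snp_sim$snps, paths$snps)
  write_metadata(metadata, paths$metadata)
  con <- file(paths$bedgraph, "w")
  writeLines(sprintf("ref\t%d\t%d\t%s", cov$track$start - 1L,
                     cov$track$end, format(cov$track$depth, trim = TRUE)),
             con)
  close(con)
  invisible(list(ref = ref, targets = list(genomeB = r1, genomeC = r2),
                 similarities = list(genomeB = s1, genomeC = s2),
                 tree = tree, snp_sim = snp_sim, coverage = cov,
                 metadata = metadata, paths = paths))
}
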