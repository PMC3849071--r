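# Frequency spectra, density maps, alignments, distances, trees, exports.

demo_snps <- function() {
  data.frame(strain_id = c("s1", "s2", "s2", "s3", "s4"),
             position = c(10L, 10L, 20L, 10L, 35L),
             ref_allele = c("A", "A", "C", "A", "G"),
             alt_allele = c("G", "G", "T", "T", "A"),
             stringsAsFactors = FALSE)
}

test_that("frequency counts strains with a non-reference allele per position", {
  f <- snp_frequency(demo_snps(), c("s1", "s2", "s3", "s4"))
  expect_equal(f$position, c(10L, 20L, 35L))
  expect_equal(f$count, c(3L, 1L, 1L))
  expect_equal(f$fraction, c(0.75, 0.25, 0.25))
  # one SNP in one of four strains
  f1 <- snp_frequency(demo_snps()[1, ], c("s1", "s2", "s3", "s4"))
  expect_equal(f1$fraction, 0.25)
  # mutated in every analysed strain
  f2 <- snp_frequency(demo_snps()[c(1, 2, 4), ], c("s1", "s2", "s3"))
  expect_equal(f2$fraction, 1)
  expect_error(snp_frequency(demo_snps(), character()), "non-empty")
})

test_that("frequency equals a brute-force per-position tally", {
  set.seed(41)
  strains <- sprintf("s%02d", 1:12)
  snps <- data.frame(strain_id = sample(strains, 300, TRUE),
                     position = sample(1:80, 300, TRUE),
                     ref_allele = "A", alt_allele = "C")
  snps <- unique(snps)
  f <- snp_frequency(snps, strains)
  for (p in f$position) {
    manual <- length(unique(snps$strain_id[snps$position == p]))
    expect_equal(f$count[f$position == p], manual)
    expect_equal(f$fraction[f$position == p], manual / length(strains))
  }
})

test_that("per-kb windows tile the genome and counts sum to the SNP total", {
  genes <- data.frame(gene_id = "g1", start = 100L, end = 399L, strand = "+")
  g <- tiny_genome(NULL, genes, "r", length = 2500L)
  d <- snp_density(demo_snps(), g, mode = "per_kb", window_kb = 1)
  expect_equal(d$window_start, c(1L, 1001L, 2001L))
  expect_equal(d$window_end, c(1000L, 2000L, 2500L))
  expect_equal(sum(d$count), nrow(demo_snps()))
  d0 <- snp_density(demo_snps()[0, ], g, mode = "per_kb")
  expect_true(all(d0$count == 0))
})

test_that("per-gene density counts overlap-shared SNPs once per gene", {
  genes <- data.frame(gene_id = c("g1", "g2"), start = c(5L, 30L),
                      end = c(25L, 60L), strand = "+")
  g <- tiny_genome(NULL, genes, "r", length = 100L)
  d <- snp_density(demo_snps(), g, mode = "per_gene")
  expect_equal(d$count[d$gene_id == "g1"], 4L)  # three at pos 10, one at 20
  expect_equal(d$count[d$gene_id == "g2"], 1L)  # pos 35
  expect_error(snp_density(demo_snps(), g, strains = "ghost"), "absent")
})

test_that("density equals a brute-force recount on random inputs", {
  set.seed(43)
  genome <- sim_genome(n_genes = 20, seed = 44)
  snps <- random_genic_snps(genome, 300)
  d <- snp_density(snps, genome, mode = "per_gene")
  for (k in sample(nrow(genome$genes), 8)) {
    gg <- genome$genes[k, ]
    manual <- sum(snps$position >= gg$start & snps$position <= gg$end)
    expect_equal(d$count[d$gene_id == gg$gene_id], manual)
  }
  dk <- snp_density(snps, genome, mode = "per_kb", window_kb = 2)
  for (k in sample(nrow(dk), 5)) {
    manual <- sum(snps$position >= dk$window_start[k] &
                  snps$position <= dk$window_end[k])
    expect_equal(dk$count[k], manual)
  }
  expect_equal(sum(dk$count), nrow(snps))
})

test_that("group densities sum to the global map for any strain partition", {
  set.seed(45)
  genome <- sim_genome(n_genes = 15, seed = 46)
  snps <- random_genic_snps(genome, 200)
  strains <- unique(snps$strain_id)
  for (i in 1:4) {
    md <- data.frame(strain_id = strains,
                     grp = sample(c("x", "y", "z", NA), length(strains),
                                  TRUE))
    maps <- group_density(snps, md, "grp", genome)
    total <- Reduce(`+`, lapply(maps, `[[`, "count"))
    global <- snp_density(snps, genome, mode = "per_gene")$count
    expect_equal(total, global)
  }
  # single group is the identity
  md1 <- data.frame(strain_id = strains, grp = "only")
  expect_equal(group_density(snps, md1, "grp", genome)$only$count,
               snp_density(snps, genome)$count)
  expect_error(group_density(snps, md1, "nope", genome), "not in metadata")
})

test_that("artificial alignment fills alt alleles over a reference backbone", {
  seq <- paste(rep("A", 40), collapse = "")
  g <- genome_record("ref", data.frame(gene_id = "g1", name = "-",
                                       start = 1L, end = 30L, strand = "+",
                                       pid = "1", product = "p"),
                     sequence = seq)
  snps <- data.frame(strain_id = c("s1", "s2", "s2"),
                     position = c(10L, 10L, 20L),
                     ref_allele = "A", alt_allele = c("G", "G", "T"))
  aln <- artificial_alignment(snps, c("s1", "s2"), g)
  expect_equal(aln$positions, c(10L, 20L))
  expect_equal(aln$strains, c("ref", "s1", "s2"))
  expect_equal(unname(aln$alleles["ref", ]), c("A", "A"))
  expect_equal(unname(aln$alleles["s1", ]), c("G", "A"))
  expect_equal(unname(aln$alleles["s2", ]), c("G", "T"))
  # a strain with no SNPs still gets a (reference) row
  aln3 <- artificial_alignment(snps, c("s1", "s2", "s9"), g)
  expect_equal(unname(aln3$alleles["s9", ]), c("A", "A"))
  # no SNPs at all: zero columns, rows present
  aln0 <- artificial_alignment(snps[0, ], c("s1", "s2"), g)
  expect_length(aln0$positions, 0L)
  expect_equal(aln0$strains, c("ref", "s1", "s2"))
  # gene subset restricts the positions
  g2 <- genome_record("ref", data.frame(gene_id = c("g1", "g2"),
                                        name = "-", start = c(1L, 15L),
                                        end = c(12L, 30L), strand = "+",
                                        pid = c("1", "2"), product = "p"),
                      sequence = seq)
  alns <- artificial_alignment(snps, c("s1", "s2"), g2, gene_subset = "g2")
  expect_equal(alns$positions, 20L)
})

test_that("alignment equals simulator haplotypes at segregating sites", {
  genome <- sim_genome(n_genes = 12, seed = 47)
  tree <- sim_tree(6, seed = 48)
  sim <- sim_snps(genome, tree, subs_per_site = 1e-3, seed = 49,
                  record_effects = FALSE)
  aln <- artificial_alignment(sim$snps, tree$tip.label, genome)
  for (s in tree$tip.label) {
    hap_chars <- substring(sim$haplotypes[[s]], aln$positions,
                           aln$positions)
    expect_equal(unname(aln$alleles[s, ]), hap_chars)
  }
  # distances invariant to strain input order (up to row permutation)
  aln_r <- artificial_alignment(sim$snps, rev(tree$tip.label), genome)
  d1 <- snp_distances(aln)
  d2 <- snp_distances(aln_r)
  expect_equal(d1[rownames(d2), colnames(d2)], d2)
})

test_that("p and Jukes-Cantor distances match closed forms", {
  m <- rbind(a = c("A", "A", "A", "A"), b = c("A", "A", "A", "C"))
  expect_equal(snp_distances(m)["a", "b"], 0.25)
  expect_equal(snp_distances(m, "jukes_cantor")["a", "b"],
               -0.75 * log(1 - 1 / 3), tolerance = 1e-9)
  expect_equal(snp_distances(m, "jukes_cantor")["a", "b"], 0.30410,
               tolerance = 1e-4)
  m2 <- rbind(a = c("A", "C"), b = c("A", "C"))
  expect_equal(snp_distances(m2)["a", "b"], 0)
  m3 <- rbind(a = c("A", "C", "G", "T"), b = c("C", "A", "T", "G"))
  expect_error(snp_distances(m3, "jukes_cantor"), "3/4")
  expect_error(snp_distances(m3[, 0]), "zero columns")
  # random matrices: symmetric, zero diagonal, p in [0, 1]
  set.seed(50)
  for (i in 1:5) {
    r <- matrix(sample(c("A", "C", "G", "T"), 60, TRUE), nrow = 5,
                dimnames = list(paste0("x", 1:5), NULL))
    d <- snp_distances(r)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 5))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("neighbor joining recovers known small trees", {
  # 3 taxa: unique topology, branch lengths from the three-point formulas
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(d)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_setequal(round(tr$edge.length, 6), c(0.5, 1.5, 2.5))
  # additive 4-taxon matrix from a known tree -> exact topology
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:2.5):1);")
  dm <- ape::cophenetic.phylo(true)
  tr4 <- build_tree(dm)
  expect_equal(rf_dist(tr4, true), 0)
  expect_error(build_tree(d[1:2, 1:2]), "at least 3")
})

test_that("mutate and diff are exact inverses", {
  genome <- sim_genome(n_genes = 10, seed = 51)
  set.seed(52)
  snps <- unique(random_genic_snps(genome, 60))
  snps <- snps[!duplicated(snps$position), ]
  snps$strain_id <- "s1"
  mut <- mutate_sequence(genome$sequence, snps)
  expect_equal(nchar(mut), nchar(genome$sequence))
  back <- diff_sequences(genome$sequence, mut, "s1")
  expect_equal(back[order(back$position), c("position", "ref_allele",
                                            "alt_allele")],
               snps[order(snps$position), c("position", "ref_allele",
                                            "alt_allele")],
               ignore_attr = TRUE)
  expect_equal(mutate_sequence(genome$sequence, snps[0, ]),
               genome$sequence)
  # conflicting alternate alleles at one position are rejected
  bad <- rbind(snps[1, ], transform(snps[1, ], alt_allele = setdiff(
    c("A", "C", "G", "T"), c(snps$ref_allele[1], snps$alt_allele[1]))[1]))
  expect_error(mutate_sequence(genome$sequence, bad), "conflicting")
})

test_that("low-coverage intervals match planted islands and a per-base scan", {
  sim <- sim_coverage(60000L, n_islands = 2L, island_span = 5000L,
                      seed = 53)
  got <- coverage_anomalies(sim$track, low_threshold = 5, min_span = 1000)
  expect_equal(nrow(got), 2L)
  expect_equal(got$start, sim$islands$start)
  expect_equal(got$end, sim$islands$end)
  # uniform high coverage -> nothing
  flat <- data.frame(strain_id = "s", start = 1L, end = 10000L, depth = 50)
  expect_equal(nrow(coverage_anomalies(flat, 10, 100)), 0L)
  # brute-force per-base check on a random piecewise track
  set.seed(54)
  bounds <- sort(sample(1:2000, 20))
  tr <- data.frame(strain_id = "s",
                   start = c(1L, bounds + 1L),
                   end = c(bounds, 2100L),
                   depth = sample(0:20, 21, TRUE))
  got <- coverage_anomalies(tr, low_threshold = 8, min_span = 30)
  perbase <- rep(0, 2100)
  for (i in seq_len(nrow(tr))) perbase[tr$start[i]:tr$end[i]] <- tr$depth[i]
  low <- perbase < 8
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  manual <- data.frame(start = starts[r$values], end = ends[r$values])
  manual <- manual[manual$end - manual$start + 1 >= 30, ]
  expect_equal(got$start, manual$start)
  expect_equal(got$end, manual$end)
})

test_that("strain ordering follows the tree or the autoscore", {
  tree <- ape::read.tree(text = "((s2,s3),s1);")
  expect_equal(order_strains(c("s1", "s2", "s3"), "tree", tree = tree),
               c("s2", "s3", "s1"))
  expect_error(order_strains(c("s1", "sX"), "tree", tree = tree),
               "missing strains: sX")
  # autoscore: a strain identical to the reference sorts first
  seq <- paste(rep("A", 50), collapse = "")
  g <- genome_record("ref", data.frame(gene_id = "g1", name = "-",
                                       start = 1L, end = 30L, strand = "+",
                                       pid = "1", product = "p"),
                     sequence = seq)
  snps <- data.frame(strain_id = c("s2", "s2", "s3"),
                     position = c(5L, 9L, 5L), ref_allele = "A",
                     alt_allele = "C")
  aln <- artificial_alignment(snps, c("s1", "s2", "s3"), g)
  expect_equal(order_strains(c("s1", "s2", "s3"), "autoscore",
                             alignment = aln), c("s1", "s3", "s2"))
  # brute-force sort by (distance to reference, id)
  set.seed(56)
  genome <- sim_genome(n_genes = 10, seed = 57)
  tree2 <- sim_tree(8, seed = 58)
  sim <- sim_snps(genome, tree2, 1e-3, seed = 59, record_effects = FALSE)
  aln2 <- artificial_alignment(sim$snps, tree2$tip.label, genome)
  got <- order_strains(tree2$tip.label, "autoscore", alignment = aln2)
  score <- vapply(tree2$tip.label, function(s)
    mean(aln2$alleles[s, ] != aln2$alleles[1, ]), 0)
  expect_equal(got, tree2$tip.label[order(score, tree2$tip.label)])
})

test_that("alignment exports round-trip as FASTA and positions table", {
  genome <- sim_genome(n_genes = 8, seed = 60)
  tree <- sim_tree(4, seed = 61)
  sim <- sim_snps(genome, tree, 1e-3, seed = 62, record_effects = FALSE)
  aln <- artificial_alignment(sim$snps, tree$tip.label, genome)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, fa)
  seqs <- read_fasta(fa)
  expect_equal(names(seqs), aln$strains)
  expect_equal(unname(nchar(seqs)), rep(length(aln$positions),
                                        length(aln$strains)))
  expect_equal(strsplit(seqs[["ref"]], "")[[1]],
               unname(aln$alleles["ref", ]))
  tab <- withr::local_tempfile()
  write_alignment_table(aln, tab)
  lines <- readLines(tab)
  expect_length(lines, 1L + length(aln$positions))
  d <- withr::local_tempfile()
  write_distance_matrix(snp_distances(aln), d)
  expect_equal(as.integer(trimws(readLines(d)[1])), length(aln$strains))
})
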