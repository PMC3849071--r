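# Synteny chaining, offsets, plot data and region selection.

perfect_pairs <- function(ref, target_ids = NULL, target_genome = "t") {
  ids <- ref$genes$gene_id
  data.frame(ref_gene_id = ids, target_genome_id = target_genome,
             target_gene_id = target_ids %||% ids,
             pct_identity = 100, query_cov = 1, bit_score = 100,
             e_value = 0, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical gene order yields one collinear block over all genes", {
  g <- sim_genome(n_genes = 10, seed = 1, with_sequence = FALSE)
  b <- detect_blocks(perfect_pairs(g), g, g, max_gap = 1, min_pairs = 2)
  expect_equal(nrow(b$blocks), 1L)
  expect_equal(b$blocks$orientation, "collinear")
  expect_equal(b$blocks$n_pairs, 10L)
  expect_equal(sum(is.na(b$pairs$block_id)), 0L)
})

test_that("a planted inversion splits the chain into three oriented blocks", {
  g <- sim_genome(n_genes = 10, seed = 2, with_sequence = FALSE)
  # target order: 1 2 3 | 7 6 5 4 | 8 9 10 -> target indices of ref genes
  target_pos <- c(1, 2, 3, 7, 6, 5, 4, 8, 9, 10)
  tg <- g$genes
  tg$gene_id <- paste0("t", seq_len(10))
  target <- genome_record("t", tg)
  pairs <- perfect_pairs(g, target_ids = paste0("t", target_pos))
  b <- detect_blocks(pairs, g, target, max_gap = 0, min_pairs = 2)
  expect_equal(b$blocks$orientation, c("collinear", "inverted", "collinear"))
  expect_equal(b$blocks$ref_first_idx, c(1L, 4L, 8L))
  expect_equal(b$blocks$ref_last_idx, c(3L, 7L, 10L))
  # line plot draws the inverted segment descending
  lp <- lineplot_data(b)
  expect_true(lp$target_from[2] > lp$target_to[2])
  expect_true(all(lp$target_from[c(1, 3)] < lp$target_to[c(1, 3)]))
})

test_that("planted rearrangements are recovered exactly (oracle-checked)", {
  g <- sim_genome(n_genes = 100, seed = 31, with_sequence = FALSE)
  for (k in c(2, 4, 7)) {
    r <- sim_rearrangement(g, k, invert_prob = 0.5, seed = k * 13)
    b <- detect_blocks(r$truth$pairs, g, r$target, max_gap = 0,
                       min_pairs = 2)
    expect_equal(nrow(b$blocks), k)
    got <- b$blocks[order(b$blocks$ref_first_idx),
                    c("ref_first_idx", "ref_last_idx", "orientation")]
    want <- r$truth$segments[order(r$truth$segments$ref_first), ]
    expect_equal(got$ref_first_idx, want$ref_first)
    expect_equal(got$ref_last_idx, want$ref_last)
    expect_equal(got$orientation == "inverted", want$inverted)
    # independent maximal-run scanner agrees
    idx <- syntsnp:::pair_indices(r$truth$pairs, g, r$target)
    runs <- oracle_runs(idx$ref, idx$target)
    expect_equal(length(runs), k)
    expect_setequal(vapply(runs, `[[`, 1, "ref_first"), want$ref_first)
  }
})

test_that("increasing max_gap never increases the block count", {
  set.seed(55)
  g <- sim_genome(n_genes = 60, seed = 9, with_sequence = FALSE)
  r <- sim_rearrangement(g, 6, seed = 10)
  pairs <- r$truth$pairs[sample(nrow(r$truth$pairs), 45), ]  # drop some genes
  counts <- vapply(0:5, function(gap)
    nrow(detect_blocks(pairs, g, r$target, max_gap = gap,
                       min_pairs = 2)$blocks), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("every pair lands in at most one block; discards are the unchained", {
  g <- sim_genome(n_genes = 80, seed = 12, with_sequence = FALSE)
  r <- sim_rearrangement(g, 5, seed = 12)
  b <- detect_blocks(r$truth$pairs, g, r$target, max_gap = 0, min_pairs = 3)
  in_blocks <- sum(b$blocks$n_pairs)
  expect_equal(in_blocks + sum(is.na(b$pairs$block_id)), nrow(r$truth$pairs))
  expect_equal(anyDuplicated(na.omit(paste(b$pairs$ref_gene_id,
                                           b$pairs$block_id))), 0L)
})

test_that("self-comparison gives a single collinear block spanning the genome", {
  g <- sim_genome(n_genes = 25, seed = 13, with_sequence = FALSE)
  b <- detect_blocks(perfect_pairs(g), g, g, max_gap = 0, min_pairs = 2)
  expect_equal(nrow(b$blocks), 1L)
  expect_equal(b$blocks$n_pairs, 25L)
  expect_equal(b$blocks$ref_start, min(g$genes$start))
  expect_equal(b$blocks$ref_end, max(g$genes$end))
})

test_that("local offset translates the target onto the anchor", {
  genes_r <- data.frame(gene_id = "a", start = 1000L, end = 1999L,
                        strand = "+")
  genes_t <- data.frame(gene_id = "b", start = 5000L, end = 5999L,
                        strand = "+")
  ref <- tiny_genome(NULL, genes_r, "r")
  target <- tiny_genome(NULL, genes_t, "t")
  pairs <- data.frame(ref_gene_id = "a", target_genome_id = "t",
                      target_gene_id = "b", pct_identity = 100,
                      query_cov = 1, bit_score = 1, e_value = 0)
  # midpoints 1499.5 and 5499.5: shift the target by -4000 to align
  expect_equal(local_offset("a", pairs, ref, target), -4000)
  # self-ortholog -> zero shift
  pairs_self <- transform(pairs, target_gene_id = "a")
  expect_equal(local_offset("a", pairs_self, ref, ref), 0)
  # orphan anchor -> absent
  expect_true(is.na(local_offset("a", pairs[0, ], ref, target)))
  expect_error(local_offset("zz", pairs, ref, target), "unknown anchor")
})

test_that("dot plot puts self-comparison points on the diagonal", {
  g <- sim_genome(n_genes = 12, seed = 14, with_sequence = FALSE)
  dp <- dotplot_data(perfect_pairs(g), g, g)
  expect_equal(dp$ref_mid, dp$target_mid)
  expect_equal(nrow(dotplot_data(perfect_pairs(g)[0, ], g, g)), 0L)
  expect_false(is.unsorted(dp$ref_mid))
})

test_that("region selection equals the brute-force point-in-rectangle test", {
  set.seed(15)
  g <- sim_genome(n_genes = 50, seed = 15, with_sequence = FALSE)
  r <- sim_rearrangement(g, 4, seed = 16)
  dp <- dotplot_data(r$truth$pairs, g, r$target)
  expect_setequal(select_region(dp, c(1, g$length), c(1, r$target$length)),
                  dp$ref_gene_id)
  expect_length(select_region(dp, c(1, 2), c(1, 2)), 0L)
  for (i in 1:10) {
    rw <- sort(runif(2, 1, g$length)); tw <- sort(runif(2, 1, r$target$length))
    manual <- dp$ref_gene_id[dp$ref_mid >= rw[1] & dp$ref_mid <= rw[2] &
                             dp$target_mid >= tw[1] & dp$target_mid <= tw[2]]
    expect_setequal(select_region(dp, rw, tw), manual)
  }
  expect_error(select_region(dp, c(10, 1), c(1, 2)), "start > end")
})

test_that("origin-wrapping chains merge only when both genomes are circular", {
  g <- sim_genome(n_genes = 12, seed = 17, with_sequence = FALSE,
                  circular = TRUE)
  # target = rotation of the reference by 4 genes: linear chaining sees 2
  # blocks, circular wrapping sees 1
  rot <- c(5:12, 1:4)
  tg <- g$genes[rot, ]
  offs <- c(rep(0L, 8), rep(g$genes$end[12], 4))
  tg$start <- tg$start + offs - min(tg$start + offs) + 1L
  tg$end <- tg$start + (g$genes$end[rot] - g$genes$start[rot])
  tg$gene_id <- paste0("t", seq_len(12))
  target <- genome_record("t", tg, circular = TRUE)
  pairs <- data.frame(ref_gene_id = g$genes$gene_id[rot],
                      target_genome_id = "t",
                      target_gene_id = paste0("t", 1:12),
                      pct_identity = 100, query_cov = 1, bit_score = 1,
                      e_value = 0)
  b_lin <- detect_blocks(pairs, g, target, max_gap = 0, min_pairs = 2)
  b_wrap <- detect_blocks(pairs, g, target, max_gap = 0, min_pairs = 2,
                          wrap = TRUE)
  expect_equal(nrow(b_lin$blocks), 2L)
  expect_equal(nrow(b_wrap$blocks), 1L)
  expect_equal(b_wrap$blocks$n_pairs, 12L)
})
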