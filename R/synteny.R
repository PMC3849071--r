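# Synteny-block chaining and plot-data generation.

# Map pair gene ids to chromosomal gene indices within their genomes,
# erroring on unknown genes.
pair_indices <- function(pairs, ref, target) {
  ri <- match(pairs$ref_gene_id, ref$genes$gene_id)
  ti <- match(pairs$target_gene_id, target$genes$gene_id)
  if (anyNA(ri))
    stop_syntsnp("pairs reference unknown reference genes: ",
                 paste(pairs$ref_gene_id[is.na(ri)], collapse = ", "))
  if (anyNA(ti))
    stop_syntsnp("pairs reference unknown target genes: ",
                 paste(pairs$target_gene_id[is.na(ti)], collapse = ", "))
  list(ref = ri, target = ti)
}

#' Detect synteny blocks by greedy gap-bounded chaining
#'
#' Ortholog pairs, sorted by reference gene index, are chained left to
#' right. A pair extends the open chain when (i) its reference index exceeds
#' the previous member's by at most `max_gap + 1`, (ii) its target index
#' differs from the previous member's by at most `max_gap + 1` in the
#' chain's direction, and (iii) the direction (ascending or descending
#' target index) is consistent within the chain. A chain of a single pair
#' has no direction yet; its direction is fixed by the second member.
#' Chains shorter than `min_pairs` are discarded and reported as unchained.
#'
#' Chains do not wrap across the origin by default; with `wrap = TRUE` and
#' both genomes circular, a chain ending at the last reference gene and a
#' chain starting at the first are merged when the chaining rule would join
#' them across the origin on both genomes.
#'
#' @param pairs One-to-one ortholog pairs (see [bdbh()]).
#' @param ref,target [genome_record()]s providing chromosomal gene order.
#' @param max_gap Maximum number of skippable genes between consecutive
#'   chain members, on either genome (default 3).
#' @param min_pairs Minimum chain size to report a block (default 2).
#' @param wrap Join chains across the origin of circular genomes.
#' @return Object of class `synteny_blocks`: list with
#'   `blocks` (data frame: `block_id`, `orientation` in
#'   `{collinear, inverted}`, `n_pairs`, `ref_start`, `ref_end`,
#'   `target_start`, `target_end` in bp spanning exactly the member genes),
#'   `pairs` (the input pairs with chromosomal indices and their `block_id`,
#'   `NA` when unchained), and the two genome ids.
#' @export
detect_blocks <- function(pairs, ref, target, max_gap = 3L, min_pairs = 2L,
                          wrap = FALSE) {
  stopifnot(max_gap >= 0L, min_pairs >= 1L)
  idx <- pair_indices(pairs, ref, target)
  p <- pairs
  p$ref_idx <- idx$ref
  p$target_idx <- idx$target
  p <- p[order(p$ref_idx), , drop = FALSE]
  rownames(p) <- NULL
  n <- nrow(p)
  chain_id <- integer(n)
  chain_dir <- integer(0)  # per chain: +1 ascending, -1 descending, 0 unset
  if (n) {
    cur <- 1L
    chain_id[1L] <- 1L
    chain_dir <- 0L
    for (i in seq_len(n)[-1L]) {
      rgap <- p$ref_idx[i] - p$ref_idx[i - 1L]
      tstep <- p$target_idx[i] - p$target_idx[i - 1L]
      dir <- chain_dir[cur]
      extend <- rgap >= 1L && rgap <= max_gap + 1L &&
        ((dir == 0L && abs(tstep) >= 1L && abs(tstep) <= max_gap + 1L) ||
         (dir == 1L && tstep >= 1L && tstep <= max_gap + 1L) ||
         (dir == -1L && tstep <= -1L && tstep >= -(max_gap + 1L)))
      if (extend) {
        chain_id[i] <- cur
        if (dir == 0L) chain_dir[cur] <- sign(tstep)
      } else {
        cur <- cur + 1L
        chain_id[i] <- cur
        chain_dir[cur] <- 0L
      }
    }
  }
  sizes <- tabulate(chain_id)

  # Optional origin wrap: merge the last chain into the first when the rule
  # would chain them across the origin on both circular genomes.
  if (wrap && isTRUE(ref$circular) && isTRUE(target$circular) &&
      length(unique(chain_id[chain_id > 0L])) >= 2L) {
    first_c <- chain_id[1L]; last_c <- chain_id[n]
    if (first_c != last_c) {
      nr <- nrow(ref$genes); nt <- nrow(target$genes)
      rgap <- (p$ref_idx[1L] + nr) - p$ref_idx[n]
      tstep <- p$target_idx[1L] - p$target_idx[n]
      tstep_wrap <- if (tstep > 0L) tstep - nt else tstep + nt
      dl <- chain_dir[last_c]; df <- chain_dir[first_c]
      for (ts in c(tstep, tstep_wrap)) {
        dir_ok <- (dl == 0L || sign(ts) == dl) && (df == 0L || sign(ts) == df)
        if (rgap >= 1L && rgap <= max_gap + 1L && abs(ts) >= 1L &&
            abs(ts) <= max_gap + 1L && dir_ok) {
          chain_id[chain_id == last_c] <- first_c
          if (chain_dir[first_c] == 0L) chain_dir[first_c] <- sign(ts)
          sizes <- tabulate(chain_id)
          break
        }
      }
    }
  }

  keep_chain <- which(sizes >= min_pairs)
  block_of_chain <- rep(NA_integer_, length(sizes))
  block_of_chain[keep_chain] <- seq_along(keep_chain)
  p$block_id <- block_of_chain[chain_id]

  mk_block <- function(b) {
    m <- p[which(p$block_id == b), , drop = FALSE]
    dir <- chain_dir[keep_chain[b]]
    orientation <- if (dir == -1L) "inverted" else "collinear"
    rg <- ref$genes[m$ref_idx, ]
    tg <- target$genes[m$target_idx, ]
    data.frame(block_id = b, orientation = orientation, n_pairs = nrow(m),
               ref_start = min(rg$start), ref_end = max(rg$end),
               target_start = min(tg$start), target_end = max(tg$end),
               ref_first_idx = min(m$ref_idx), ref_last_idx = max(m$ref_idx),
               stringsAsFactors = FALSE)
  }
  blocks <- if (length(keep_chain))
    do.call(rbind, lapply(seq_along(keep_chain), mk_block))
  else data.frame(block_id = integer(), orientation = character(),
                  n_pairs = integer(), ref_start = integer(),
                  ref_end = integer(), target_start = integer(),
                  target_end = integer(), ref_first_idx = integer(),
                  ref_last_idx = integer())
  # report blocks in reference order and renumber; remap pair block ids
  ord <- order(blocks$ref_start, blocks$block_id)
  remap <- integer(nrow(blocks))
  remap[blocks$block_id[ord]] <- seq_along(ord)
  blocks <- blocks[ord, , drop = FALSE]
  blocks$block_id <- seq_len(nrow(blocks))
  rownames(blocks) <- NULL
  p$block_id <- ifelse(is.na(p$block_id), NA_integer_, remap[p$block_id])
  structure(list(blocks = blocks, pairs = p,
                 ref_genome_id = ref$genome_id,
                 target_genome_id = target$genome_id),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("<synteny_blocks> ", x$ref_genome_id, " vs ", x$target_genome_id, ": ",
      nrow(x$blocks), " blocks (",
      sum(x$blocks$orientation == "inverted"), " inverted), ",
      sum(is.na(x$pairs$block_id)), " unchained pairs\n", sep = "")
  invisible(x)
}

#' Local synteny alignment offset at an anchor gene
#'
#' The signed translation (in bp) to apply to target-genome coordinates so
#' that the anchor gene and its ortholog coincide at their midpoints:
#' `offset = ref midpoint - target midpoint`. `NA` when the anchor is an
#' orphan (no ortholog in the target genome).
#'
#' @param anchor_gene_id Reference gene identifier.
#' @param pairs Ortholog pairs for the (ref, target) genome pair.
#' @param ref,target [genome_record()]s.
#' @return Numeric offset in bp, or `NA_real_` for an orphan anchor.
#' @export
local_offset <- function(anchor_gene_id, pairs, ref, target) {
  i <- match(anchor_gene_id, ref$genes$gene_id)
  if (is.na(i)) stop_syntsnp("unknown anchor gene: ", anchor_gene_id)
  j <- match(anchor_gene_id, pairs$ref_gene_id)
  if (is.na(j)) return(NA_real_)
  k <- match(pairs$target_gene_id[j], target$genes$gene_id)
  if (is.na(k)) stop_syntsnp("pair targets unknown gene: ",
                             pairs$target_gene_id[j])
  midpoint(ref$genes$start[i], ref$genes$end[i]) -
    midpoint(target$genes$start[k], target$genes$end[k])
}

#' Dot-plot data from ortholog pairs
#'
#' One point per ortholog pair at the two genes' midpoints, carrying percent
#' identity; sorted by reference coordinate (ties by target coordinate).
#' Synteny ruptures and rearrangements appear as breaks and anti-diagonals.
#'
#' @param pairs Ortholog pairs.
#' @param ref,target [genome_record()]s.
#' @return Data frame with columns `ref_gene_id`, `target_gene_id`,
#'   `ref_mid`, `target_mid`, `pct_identity`.
#' @export
dotplot_data <- function(pairs, ref, target) {
  idx <- pair_indices(pairs, ref, target)
  out <- data.frame(
    ref_gene_id = pairs$ref_gene_id,
    target_gene_id = pairs$target_gene_id,
    ref_mid = midpoint(ref$genes$start[idx$ref], ref$genes$end[idx$ref]),
    target_mid = midpoint(target$genes$start[idx$target],
                          target$genes$end[idx$target]),
    pct_identity = pairs$pct_identity, stringsAsFactors = FALSE)
  out <- out[order(out$ref_mid, out$target_mid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Line-plot segments from synteny blocks
#'
#' One segment per block. `target_from`/`target_to` follow the block's
#' orientation: ascending for collinear blocks, descending for inverted
#' ones, so inverted blocks draw as anti-diagonal segments.
#'
#' @param blocks A `synteny_blocks` object from [detect_blocks()].
#' @return Data frame with columns `block_id`, `orientation`, `n_pairs`,
#'   `ref_from`, `ref_to`, `target_from`, `target_to`, sorted by reference
#'   coordinate.
#' @export
lineplot_data <- function(blocks) {
  b <- blocks$blocks
  inv <- b$orientation == "inverted"
  out <- data.frame(block_id = b$block_id, orientation = b$orientation,
                    n_pairs = b$n_pairs, ref_from = b$ref_start,
                    ref_to = b$ref_end,
                    target_from = ifelse(inv, b$target_end, b$target_start),
                    target_to = ifelse(inv, b$target_start, b$target_end),
                    stringsAsFactors = FALSE)
  out <- out[order(out$ref_from, out$block_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select ortholog pairs within a rectangular dot-plot region
#'
#' Returns the reference gene ids whose dot-plot point falls inside both
#' coordinate windows — a gene basket usable with [export_gene_table()] and
#' [filter_profile()].
#'
#' @param dotplot Data frame from [dotplot_data()].
#' @param ref_window,target_window Length-2 numeric `c(start, end)` bp
#'   intervals, inclusive.
#' @return Character vector of selected reference gene ids.
#' @export
select_region <- function(dotplot, ref_window, target_window) {
  chk <- function(w, nm) {
    if (length(w) != 2L || anyNA(w)) stop_syntsnp(nm, " must be c(start, end)")
    if (w[1L] > w[2L]) stop_syntsnp(nm, " has start > end")
  }
  chk(ref_window, "ref_window"); chk(target_window, "target_window")
  inside <- dotplot$ref_mid >= ref_window[1L] &
            dotplot$ref_mid <= ref_window[2L] &
            dotplot$target_mid >= target_window[1L] &
            dotplot$target_mid <= target_window[2L]
  dotplot$ref_gene_id[inside]
}

#' Write synteny blocks as a tab-delimited table
#'
#' One row per block: spans on both genomes, orientation, number of pairs
#' and the member reference gene ids (comma-separated).
#'
#' @param blocks A `synteny_blocks` object.
#' @param path Output path.
#' @export
write_blocks <- function(blocks, path) {
  b <- blocks$blocks
  members <- vapply(b$block_id, function(id) {
    m <- blocks$pairs[which(blocks$pairs$block_id == id), , drop = FALSE]
    paste(m$ref_gene_id[order(m$ref_idx)], collapse = ",")
  }, "")
  df <- data.frame(block_id = b$block_id, ref_genome = blocks$ref_genome_id,
                   target_genome = blocks$target_genome_id,
                   ref_start = b$ref_start, ref_end = b$ref_end,
                   target_start = b$target_start, target_end = b$target_end,
                   orientation = b$orientation, n_pairs = b$n_pairs,
                   ref_gene_ids = members, stringsAsFactors = FALSE)
  write_tsv_hash(df, path)
}
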