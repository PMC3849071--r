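# Bi-directional best-hit orthology and phylogenetic-profile matrices.

#' Best hit per query from a one-direction similarity report
#'
#' For each query the hit with maximal bit score is kept. Ties are broken
#' deterministically: lower e-value, then higher percent identity, then
#' lexicographically smallest subject identifier.
#'
#' @param hits Data frame of similarity hits (see [read_blast_tabular()]);
#'   all hits must belong to one (query genome, subject genome) direction.
#' @return Data frame with one row per query, ordered by `query_id`.
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, -xtfrm(hits$bit_score), hits$e_value,
               -xtfrm(hits$pct_identity), hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Bi-directional best-hit (BDBH) ortholog pairs
#'
#' A pair (a, b) is an ortholog pair iff a's best hit in the target genome
#' is b and b's best hit in the reference genome is a. The orthology call
#' itself is threshold-free; similarity/coverage cut-offs are applied later
#' at profile-filtering time. Self hits (query equal to subject, as arise in
#' a self comparison) are discarded before best-hit selection.
#'
#' @param hits_ab Reference-to-target similarity hits.
#' @param hits_ba Target-to-reference similarity hits.
#' @param target_genome_id Label recorded on each pair.
#' @param ref_gene_order Optional character vector giving the reference
#'   chromosomal gene order used to sort the output; defaults to
#'   lexicographic order of `ref_gene_id`.
#' @return Ortholog pair data frame (columns `ref_gene_id`,
#'   `target_genome_id`, `target_gene_id`, `pct_identity`, `query_cov`,
#'   `bit_score`, `e_value`), one-to-one within the genome pair, carrying
#'   the forward (A to B) hit's metrics.
#' @examples
#' ab <- data.frame(query_id = "a1", subject_id = "b1", pct_identity = 95,
#'                  aln_length = 100, mismatch = 5, gapopen = 0, qstart = 1,
#'                  qend = 100, sstart = 1, send = 100, e_value = 1e-50,
#'                  bit_score = 200, query_cov = 1)
#' ba <- transform(ab, query_id = "b1", subject_id = "a1")
#' bdbh(ab, ba, "genomeB")
#' @export
bdbh <- function(hits_ab, hits_ba, target_genome_id = "target",
                 ref_gene_order = NULL) {
  drop_self <- function(h) h[h$query_id != h$subject_id, , drop = FALSE]
  fwd <- best_hits(drop_self(hits_ab))
  rev <- best_hits(drop_self(hits_ba))
  empty <- data.frame(ref_gene_id = character(),
                      target_genome_id = character(),
                      target_gene_id = character(), pct_identity = numeric(),
                      query_cov = numeric(), bit_score = numeric(),
                      e_value = numeric())
  if (!nrow(fwd) || !nrow(rev)) return(empty)
  back <- rev$subject_id[match(fwd$subject_id, rev$query_id)]
  keep <- !is.na(back) & back == fwd$query_id
  fwd <- fwd[keep, , drop = FALSE]
  if (!nrow(fwd)) return(empty)
  pairs <- data.frame(ref_gene_id = fwd$query_id,
                      target_genome_id = target_genome_id,
                      target_gene_id = fwd$subject_id,
                      pct_identity = fwd$pct_identity,
                      query_cov = fwd$query_cov,
                      bit_score = fwd$bit_score,
                      e_value = fwd$e_value, stringsAsFactors = FALSE)
  if (!is.null(ref_gene_order)) {
    pairs <- pairs[order(match(pairs$ref_gene_id, ref_gene_order)), ,
                   drop = FALSE]
  } else {
    pairs <- pairs[order(pairs$ref_gene_id), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

#' Build a phylogenetic-profile matrix
#'
#' Rows are reference genes in chromosomal order; columns are target
#' genomes, ordered by the leaves of a phylogenetic tree when one is given
#' (else input order). Each filled cell records the ortholog's percent
#' identity and query coverage; absent cells are orphans (no ortholog).
#'
#' @param ref Reference [genome_record()].
#' @param pairs_by_genome Named list: target genome id -> ortholog pair data
#'   frame (see [bdbh()]).
#' @param tree Optional ape `phylo` whose leaf set must equal the target
#'   genome set.
#' @return Object of class `profile_matrix`: list with `ref_gene_ids`,
#'   `products`, `target_genome_ids`, and numeric matrices `identity` and
#'   `coverage` (`NA` = absent cell).
#' @export
build_profile <- function(ref, pairs_by_genome, tree = NULL) {
  genomes <- names(pairs_by_genome)
  if (is.null(genomes) || any(!nzchar(genomes)))
    stop_syntsnp("pairs_by_genome must be a named list")
  if (!is.null(tree)) {
    leaves <- tree$tip.label
    if (!setequal(leaves, genomes)) {
      stop_syntsnp("tree leaves do not match genome ids; missing from tree: ",
                   paste(setdiff(genomes, leaves), collapse = ", "),
                   "; extra in tree: ",
                   paste(setdiff(leaves, genomes), collapse = ", "))
    }
    genomes <- leaves
  }
  gene_ids <- ref$genes$gene_id
  id_mat <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(genomes),
                   dimnames = list(gene_ids, genomes))
  cov_mat <- id_mat
  for (g in genomes) {
    p <- pairs_by_genome[[g]]
    if (!nrow(p)) next
    unknown <- setdiff(p$ref_gene_id, gene_ids)
    if (length(unknown))
      stop_syntsnp("pairs for ", g, " reference unknown genes: ",
                   paste(unknown, collapse = ", "))
    id_mat[p$ref_gene_id, g] <- p$pct_identity
    cov_mat[p$ref_gene_id, g] <- p$query_cov
  }
  structure(list(ref_gene_ids = gene_ids, products = ref$genes$product,
                 target_genome_ids = genomes, identity = id_mat,
                 coverage = cov_mat),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", length(x$ref_gene_ids), " genes x ",
      length(x$target_genome_ids), " genomes; ",
      sum(!is.na(x$identity)), " filled cells\n", sep = "")
  invisible(x)
}

#' Filter a phylogenetic profile
#'
#' Mirrors the dynamic display filters of a comparative browser: cells below
#' either similarity threshold become absent (orphan), and rows can be
#' restricted by a case-insensitive keyword match on the gene product and/or
#' by membership in a gene basket. Row order is preserved.
#'
#' @param profile A `profile_matrix` from [build_profile()].
#' @param min_identity Minimum percent identity in `[0, 100]`.
#' @param min_cov Minimum query coverage in `[0, 1]`.
#' @param keyword Optional keyword; rows whose product does not contain it
#'   (case-insensitively, fixed string) are dropped.
#' @param basket Optional character vector of gene ids; rows outside it are
#'   dropped.
#' @return A filtered `profile_matrix`.
#' @export
filter_profile <- function(profile, min_identity = 0, min_cov = 0,
                           keyword = NULL, basket = NULL) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_cov >= 0, min_cov <= 1)
  id <- profile$identity
  cov <- profile$coverage
  drop <- !is.na(id) & (id < min_identity | cov < min_cov)
  id[drop] <- NA_real_
  cov[drop] <- NA_real_
  keep <- rep(TRUE, length(profile$ref_gene_ids))
  if (!is.null(keyword))
    keep <- keep & grepl(tolower(keyword), tolower(profile$products),
                         fixed = TRUE)
  if (!is.null(basket))
    keep <- keep & profile$ref_gene_ids %in% basket
  structure(list(ref_gene_ids = profile$ref_gene_ids[keep],
                 products = profile$products[keep],
                 target_genome_ids = profile$target_genome_ids,
                 identity = id[keep, , drop = FALSE],
                 coverage = cov[keep, , drop = FALSE]),
            class = "profile_matrix")
}

#' Write a profile matrix as a wide tab-delimited table
#'
#' One row per reference gene, one column per genome; filled cells are
#' `identity/coverage`, orphan cells are empty.
#'
#' @param profile A `profile_matrix`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  cells <- matrix("", nrow = length(profile$ref_gene_ids),
                  ncol = length(profile$target_genome_ids))
  filled <- !is.na(profile$identity)
  cells[filled] <- sprintf("%.2f/%.3f", profile$identity[filled],
                           profile$coverage[filled])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#gene_id", profile$target_genome_ids), collapse = "\t"),
             con)
  if (nrow(cells))
    writeLines(paste(profile$ref_gene_ids,
                     apply(cells, 1L, paste, collapse = "\t"), sep = "\t"),
               con)
  invisible(path)
}
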