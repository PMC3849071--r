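# Population-level SNP summaries: frequency spectra, density maps, grouped
# counts, artificial alignments, distances, trees, sequence export,
# coverage heterogeneity and strain ordering.

#' SNP frequency-of-occurrence spectrum
#'
#' For every polymorphic position, the number and fraction of analysed
#' strains carrying a non-reference allele there. SNP rows for strains
#' outside `strains` are ignored.
#'
#' @param snps SNP data frame.
#' @param strains Character vector of analysed strain ids (non-empty).
#' @return Data frame with columns `position`, `count`, `fraction`, sorted
#'   by position.
#' @export
snp_frequency <- function(snps, strains) {
  if (!length(strains)) stop_syntsnp("strains must be non-empty")
  s <- snps[snps$strain_id %in% strains, , drop = FALSE]
  if (!nrow(s))
    return(data.frame(position = integer(), count = integer(),
                      fraction = numeric()))
  key <- unique(s[c("strain_id", "position")])
  tab <- table(key$position)
  pos <- as.integer(names(tab))
  out <- data.frame(position = pos, count = as.integer(tab),
                    fraction = as.integer(tab) / length(strains))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNP density maps, per gene or per kilobase window
#'
#' Per-gene mode counts genic SNP records per gene (a SNP under overlapping
#' genes counts once per gene; every strain's record counts). Per-kb mode
#' tiles the genome with fixed windows of `window_kb * 1000` bp anchored at
#' position 1 (the last window may be short) and counts all SNP records per
#' window.
#'
#' @param snps SNP data frame.
#' @param genome Reference [genome_record()].
#' @param mode `"per_gene"` or `"per_kb"`.
#' @param window_kb Window size in kb for per-kb mode (>= 1).
#' @param strains Optional strain subset; unknown strains are an error.
#' @return Data frame: per-gene mode has columns `gene_id`, `count`
#'   (every gene appears, zero counts included); per-kb mode has
#'   `window_start`, `window_end`, `count` covering `[1, genome length]`.
#' @export
snp_density <- function(snps, genome, mode = c("per_gene", "per_kb"),
                        window_kb = 1, strains = NULL) {
  mode <- match.arg(mode)
  if (!is.null(strains)) {
    unknown <- setdiff(strains, unique(snps$strain_id))
    if (length(unknown))
      stop_syntsnp("strain(s) absent from the SNP table: ",
                   paste(unknown, collapse = ", "))
    snps <- snps[snps$strain_id %in% strains, , drop = FALSE]
  }
  if (mode == "per_gene") {
    loc <- locate_snps(snps, genome)
    counts <- table(factor(loc$gene_id, levels = genome$genes$gene_id))
    out <- data.frame(gene_id = genome$genes$gene_id,
                      count = as.integer(counts), stringsAsFactors = FALSE)
  } else {
    stopifnot(window_kb >= 1)
    w <- as.integer(window_kb * 1000)
    starts <- seq.int(1L, genome$length, by = w)
    ends <- pmin(starts + w - 1L, genome$length)
    bin <- findInterval(snps$position, starts)
    counts <- tabulate(bin, nbins = length(starts))
    out <- data.frame(window_start = starts, window_end = ends,
                      count = counts)
  }
  attr(out, "mode") <- mode
  out
}

#' Metadata-grouped differential SNP density
#'
#' Splits strains by the value of a metadata attribute and computes one
#' density map per category. Strains present in the SNP table but lacking
#' the attribute (or absent from the metadata) are collected under an
#' explicit `"unassigned"` category. Group maps sum to the global map for
#' any partition.
#'
#' @param snps SNP data frame.
#' @param metadata Data frame from [read_metadata()].
#' @param attribute Metadata column name to group by.
#' @param genome Reference [genome_record()].
#' @inheritParams snp_density
#' @return Named list of density data frames, one per category.
#' @export
group_density <- function(snps, metadata, attribute, genome,
                          mode = c("per_gene", "per_kb"), window_kb = 1) {
  mode <- match.arg(mode)
  if (!attribute %in% names(metadata))
    stop_syntsnp("attribute '", attribute, "' not in metadata")
  all_strains <- unique(snps$strain_id)
  value <- metadata[[attribute]][match(all_strains, metadata$strain_id)]
  value[is.na(value)] <- "unassigned"
  groups <- split(all_strains, value)
  lapply(groups, function(ss)
    snp_density(snps[snps$strain_id %in% ss, , drop = FALSE], genome,
                mode = mode, window_kb = window_kb))
}

#' Artificial alignment of alleles at polymorphic positions
#'
#' Builds the strains-by-positions allele matrix behind SNP-based
#' phylogenetics: columns are the union of polymorphic positions across the
#' chosen strains (optionally restricted to a gene subset), sorted
#' ascending; the reference genome is included as the first row and carries
#' its own allele at every column; each strain row carries its alternate
#' allele where it has a SNP and the reference allele elsewhere. Strains
#' with zero SNPs still get a row.
#'
#' @param snps SNP data frame.
#' @param strains Character vector of strain ids to include.
#' @param genome Reference [genome_record()] with sequence.
#' @param gene_subset Optional character vector of gene ids; positions are
#'   restricted to those inside the listed genes.
#' @return Object of class `artificial_alignment`: list with `positions`
#'   (sorted integer vector), `strains` (reference id first) and `alleles`
#'   (character matrix, rows named by strain).
#' @export
artificial_alignment <- function(snps, strains, genome, gene_subset = NULL) {
  if (is.null(genome$sequence))
    stop_syntsnp("reference sequence required for artificial alignment")
  s <- snps[snps$strain_id %in% strains, , drop = FALSE]
  validate_snps(s, reference = genome$sequence, what = "snps")
  dup <- duplicated(s[c("strain_id", "position")])
  if (any(dup)) {
    key <- s[duplicated(s[c("strain_id", "position")]) |
             duplicated(s[c("strain_id", "position")], fromLast = TRUE), ]
    if (nrow(unique(key[c("strain_id", "position", "alt_allele")])) >
        nrow(unique(key[c("strain_id", "position")])))
      stop_syntsnp("conflicting SNPs at one position for one strain")
    s <- s[!dup, , drop = FALSE]
  }
  positions <- sort(unique(s$position))
  if (!is.null(gene_subset)) {
    unknown <- setdiff(gene_subset, genome$genes$gene_id)
    if (length(unknown))
      stop_syntsnp("unknown genes in gene_subset: ",
                   paste(unknown, collapse = ", "))
    g <- genome$genes[genome$genes$gene_id %in% gene_subset, , drop = FALSE]
    keep <- vapply(positions, function(p) any(g$start <= p & p <= g$end),
                   NA)
    positions <- positions[keep]
    s <- s[s$position %in% positions, , drop = FALSE]
  }
  rows <- c(genome$genome_id, strains)
  ref_row <- if (length(positions))
    substring(genome$sequence, positions, positions) else character()
  alleles <- matrix(rep(ref_row, each = length(rows)),
                    nrow = length(rows), ncol = length(positions),
                    dimnames = list(rows, positions))
  if (nrow(s)) {
    ri <- match(s$strain_id, rows)
    ci <- match(s$position, positions)
    alleles[cbind(ri, ci)] <- s$alt_allele
  }
  structure(list(positions = positions, strains = rows, alleles = alleles),
            class = "artificial_alignment")
}

#' @export
print.artificial_alignment <- function(x, ...) {
  cat("<artificial_alignment> ", length(x$strains), " rows (incl. reference) x ",
      length(x$positions), " polymorphic positions\n", sep = "")
  invisible(x)
}

#' Pairwise distances from an artificial alignment
#'
#' `p_distance` is the fraction of mismatching columns between two rows;
#' `jukes_cantor` applies the divergence correction
#' `-(3/4) * log(1 - (4/3) * p)`, which is undefined (error) at
#' `p >= 3/4`. The matrix is symmetric with a zero diagonal and invariant
#' to strain input order up to row permutation.
#'
#' @param alignment An `artificial_alignment` or a character matrix of
#'   alleles with row names.
#' @param model `"p_distance"` or `"jukes_cantor"`.
#' @param include_reference Keep the reference row (first row of an
#'   `artificial_alignment`) in the matrix.
#' @return Symmetric numeric matrix of pairwise distances.
#' @export
snp_distances <- function(alignment, model = c("p_distance", "jukes_cantor"),
                          include_reference = TRUE) {
  model <- match.arg(model)
  m <- if (inherits(alignment, "artificial_alignment")) alignment$alleles
       else alignment
  if (!include_reference && inherits(alignment, "artificial_alignment"))
    m <- m[-1L, , drop = FALSE]
  if (ncol(m) == 0L)
    stop_syntsnp("distance undefined on an alignment with zero columns")
  if (nrow(m) < 2L) stop_syntsnp("need at least two rows")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      p <- mean(m[i, ] != m[j, ])
      if (model == "jukes_cantor") {
        if (p >= 0.75)
          stop_syntsnp("Jukes-Cantor distance undefined at p >= 3/4 ",
                       "(rows ", rownames(m)[i], ", ", rownames(m)[j], ")")
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape), consistent on additive matrices.
#'
#' @param d Symmetric distance matrix with at least 3 taxa.
#' @param method Only `"neighbor_joining"` is implemented.
#' @return An ape `phylo` (unrooted), leaf set equal to the matrix labels.
#' @export
build_tree <- function(d, method = "neighbor_joining") {
  method <- match.arg(method, "neighbor_joining")
  if (nrow(d) < 3L)
    stop_syntsnp("need at least 3 taxa to build a tree, got ", nrow(d))
  ape::nj(stats::as.dist(d))
}

#' Apply a strain's SNPs to the reference sequence
#'
#' Substitutes the alternate allele at every SNP position; length is
#' preserved, and diffing the result against the reference recovers exactly
#' the input SNP set. Conflicting SNPs (two different alternate alleles at
#' one position for the strain) are an error.
#'
#' @param sequence Reference nucleotide string.
#' @param strain_snps SNP data frame rows for one strain.
#' @return The mutated sequence (character scalar).
#' @export
mutate_sequence <- function(sequence, strain_snps) {
  if (!nrow(strain_snps)) return(sequence)
  validate_snps(strain_snps, reference = sequence, what = "strain_snps")
  if (length(unique(strain_snps$strain_id)) > 1L)
    stop_syntsnp("strain_snps must belong to a single strain")
  dup <- duplicated(strain_snps$position)
  if (any(dup)) {
    per_pos <- tapply(strain_snps$alt_allele, strain_snps$position,
                      function(a) length(unique(a)))
    if (any(per_pos > 1L))
      stop_syntsnp("conflicting SNPs at position(s) ",
                   paste(names(per_pos)[per_pos > 1L], collapse = ", "))
    strain_snps <- strain_snps[!dup, , drop = FALSE]
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[strain_snps$position] <- strain_snps$alt_allele
  paste(chars, collapse = "")
}

#' Diff a mutated sequence against the reference
#'
#' Inverse of [mutate_sequence()]: returns the SNP set that transforms
#' `reference` into `mutated`.
#'
#' @param reference,mutated Equal-length nucleotide strings.
#' @param strain_id Strain label for the output rows.
#' @return SNP data frame (`strain_id`, `position`, `ref_allele`,
#'   `alt_allele`).
#' @export
diff_sequences <- function(reference, mutated, strain_id = "strain") {
  if (nchar(reference) != nchar(mutated))
    stop_syntsnp("sequences differ in length")
  a <- strsplit(reference, "", fixed = TRUE)[[1]]
  b <- strsplit(mutated, "", fixed = TRUE)[[1]]
  pos <- which(a != b)
  data.frame(strain_id = rep(strain_id, length(pos)), position = pos,
             ref_allele = a[pos], alt_allele = b[pos],
             stringsAsFactors = FALSE)
}

#' Detect heterogeneously covered (candidate absent) regions
#'
#' Scans a coverage track for maximal intervals whose depth stays below
#' `low_threshold` over at least `min_span` bp — candidate deleted regions
#' or absent genomic islands in resequencing data. Positions not covered by
#' any track interval count as depth 0. Adjacent low intervals are merged.
#'
#' @param track A `coverage_track` from [read_bedgraph()] (columns `start`,
#'   `end`, `depth`, 1-based inclusive).
#' @param low_threshold Depth below which a base is "low".
#' @param min_span Minimum interval length in bp to report.
#' @param genome_length Extent of the scanned region; defaults to the last
#'   covered position.
#' @return Data frame of sorted, non-overlapping intervals (`start`, `end`,
#'   `span`, `mean_depth`).
#' @export
coverage_anomalies <- function(track, low_threshold, min_span,
                               genome_length = NULL) {
  stopifnot(low_threshold >= 0, min_span >= 0)
  genome_length <- genome_length %||% (if (nrow(track)) max(track$end) else 0L)
  if (genome_length == 0L)
    return(data.frame(start = integer(), end = integer(), span = integer(),
                      mean_depth = numeric()))
  track <- track[order(track$start), , drop = FALSE]
  # piecewise-constant depth over [1, genome_length]; gaps have depth 0
  bounds <- sort(unique(c(1L, track$start, track$end + 1L,
                          genome_length + 1L)))
  bounds <- bounds[bounds <= genome_length + 1L]
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1L] - 1L
  depth <- if (nrow(track)) {
    idx <- findInterval(seg_start, track$start)
    ifelse(idx >= 1L & seg_start <= track$end[pmax(idx, 1L)],
           track$depth[pmax(idx, 1L)], 0)
  } else rep(0, length(seg_start))
  low <- depth < low_threshold
  # merge consecutive low segments
  out <- list()
  i <- 1L
  while (i <= length(low)) {
    if (low[i]) {
      j <- i
      while (j < length(low) && low[j + 1L]) j <- j + 1L
      s <- seg_start[i]; e <- seg_end[j]
      if (e - s + 1L >= min_span) {
        spans <- seg_end[i:j] - seg_start[i:j] + 1L
        out[[length(out) + 1L]] <-
          data.frame(start = s, end = e, span = e - s + 1L,
                     mean_depth = sum(depth[i:j] * spans) / sum(spans))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), span = integer(),
                      mean_depth = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Order strains for stacked SNP displays
#'
#' Tree mode returns the strains in the leaf order of a phylogenetic tree
#' (which must contain every strain). Autoscore mode sorts strains by
#' ascending p-distance to the reference row of an artificial alignment,
#' ties broken lexicographically, so strains most similar to the reference
#' come first.
#'
#' @param strains Character vector of strain ids.
#' @param by `"tree"` or `"autoscore"`.
#' @param tree ape `phylo` (tree mode).
#' @param alignment `artificial_alignment` containing every strain
#'   (autoscore mode).
#' @return Reordered character vector of strain ids.
#' @export
order_strains <- function(strains, by = c("tree", "autoscore"), tree = NULL,
                          alignment = NULL) {
  by <- match.arg(by)
  if (by == "tree") {
    if (is.null(tree)) stop_syntsnp("tree mode requires a tree")
    missing <- setdiff(strains, tree$tip.label)
    if (length(missing))
      stop_syntsnp("tree is missing strains: ", paste(missing, collapse = ", "))
    tree$tip.label[tree$tip.label %in% strains]
  } else {
    if (is.null(alignment)) stop_syntsnp("autoscore mode requires an alignment")
    m <- alignment$alleles
    missing <- setdiff(strains, rownames(m))
    if (length(missing))
      stop_syntsnp("alignment is missing strains: ",
                   paste(missing, collapse = ", "))
    ref <- m[1L, , drop = TRUE]
    score <- vapply(strains, function(s)
      if (length(ref)) mean(m[s, ] != ref) else 0, 0)
    strains[order(score, strains)]
  }
}

#' Write an artificial alignment as FASTA and/or a positions table
#'
#' @param alignment An `artificial_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  seqs <- apply(alignment$alleles, 1L, paste, collapse = "")
  if (!length(alignment$positions))
    seqs <- stats::setNames(rep("", length(alignment$strains)),
                            alignment$strains)
  write_fasta(seqs, path)
}

#' @rdname write_alignment_fasta
#' @export
write_alignment_table <- function(alignment, path) {
  df <- data.frame(position = alignment$positions,
                   t(alignment$alleles), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("position", alignment$strains)
  write_tsv_hash(df, path)
}

#' Write a distance matrix in square PHYLIP layout
#' @param d Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  writeLines(sprintf("%-10s %s", rownames(d),
                     apply(d, 1L, function(r)
                       paste(sprintf("%.6f", r), collapse = " "))), con)
  invisible(path)
}
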