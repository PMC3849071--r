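# Readers and writers for every external format the engine touches.
#
# All coordinates are 1-based inclusive in memory. bedGraph is the single
# 0-based half-open format on disk and is converted on load/save.

#' Construct a genome record
#'
#' A genome record bundles a replicon's identifier, length, circularity,
#' ordered gene annotations and (optionally) its nucleotide sequence. It is
#' the reference container used by every other module.
#'
#' @param genome_id Short unique label.
#' @param genes Data frame with columns `gene_id`, `name`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`), `pid`, `product` and optionally `length_aa`
#'   (protein length in amino acids, as in the ptt Length column).
#' @param length Replicon length in bp. Defaults to the sequence length when
#'   a sequence is given, else to the maximum gene end.
#' @param sequence Optional nucleotide string over `{A,C,G,T,N}`.
#' @param description Free-text description.
#' @param circular Logical; whether the replicon is circular.
#' @return An object of class `genome_record`: a list with fields
#'   `genome_id`, `description`, `length`, `circular`, `genes` (sorted by
#'   `start`, ties by `gene_id`) and `sequence` (or `NULL`).
#' @examples
#' g <- data.frame(gene_id = "g1", name = "-", start = 1, end = 9,
#'                 strand = "+", pid = 1L, product = "demo")
#' genome_record("demo", g, sequence = "ATGAAATAA")
#' @export
genome_record <- function(genome_id, genes, length = NULL, sequence = NULL,
                          description = "", circular = FALSE) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  needed <- c("gene_id", "name", "start", "end", "strand", "pid", "product")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols))
    stop_syntsnp("genes is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.null(sequence)) {
    sequence <- check_sequence(sequence, paste0("sequence of ", genome_id))
  }
  if (is.null(length)) {
    length <- if (!is.null(sequence)) nchar(sequence)
              else if (nrow(genes)) max(genes$end) else 0L
  }
  if (!is.null(sequence) && nchar(sequence) != length)
    stop_syntsnp("sequence length (", nchar(sequence),
                 ") does not match declared genome length (", length, ")")
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      stop_syntsnp("duplicate gene_id in ", genome_id, ": ",
                   paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                         collapse = ", "))
    if (any(genes$start < 1L) || any(genes$end > length))
      stop_syntsnp("gene coordinates outside [1, ", length, "] in ", genome_id)
    if (any(genes$start > genes$end))
      stop_syntsnp("gene with start > end in ", genome_id,
                   " (wrap-around genes are not supported)")
    if (!all(genes$strand %in% c("+", "-")))
      stop_syntsnp("strand must be '+' or '-'")
    genes <- order_by(genes, c("start", "gene_id"))
    rownames(genes) <- NULL
  }
  structure(
    list(genome_id = genome_id, description = description,
         length = as.integer(length), circular = isTRUE(circular),
         genes = genes, sequence = sequence),
    class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ", x$length, " bp, ",
      nrow(x$genes), " genes",
      if (x$circular) ", circular" else "",
      if (!is.null(x$sequence)) ", with sequence" else "", "\n", sep = "")
  invisible(x)
}

#' Read a GenBank ptt protein table
#'
#' Parses the tab-separated GenBank protein table layout: a title line, an
#' "N proteins" line, a header row beginning with `Location`, then one row
#' per protein with Location given as `start..end`. The `Synonym` column is
#' used as the unique gene identifier and the `Length` column (protein
#' length in amino acids) is kept as `length_aa`.
#'
#' @param path Path to the ptt file.
#' @param genome_id Genome label; defaults to the file name without
#'   extension.
#' @param sequence Optional genome nucleotide sequence (string) or path to a
#'   single-record FASTA; fixes the genome length. Without it, the length is
#'   the maximum gene end.
#' @param description Optional description; defaults to the ptt title line.
#' @param circular Logical, stored on the record.
#' @return A [genome_record()] (without sequence unless supplied).
#' @export
read_ptt <- function(path, genome_id = NULL, sequence = NULL,
                     description = NULL, circular = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^Location\t", lines)
  if (!length(hdr))
    stop_syntsnp("not a ptt file (no 'Location' header row): ", path)
  hdr <- hdr[1L]
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  title <- if (hdr > 1L) lines[1L] else ""
  # the title line conventionally ends in "- 1..<length>"
  title_len <- NULL
  m <- regmatches(title, regexec("\\s*-\\s*1\\.\\.([0-9]+)\\s*$", title))[[1]]
  if (length(m) == 2L) {
    title_len <- as.integer(m[2])
    title <- sub("\\s*-\\s*1\\.\\.[0-9]+\\s*$", "", title)
  }
  description <- description %||% title
  body_idx <- seq_len(length(lines) - hdr) + hdr
  body_idx <- body_idx[nzchar(lines[body_idx])]
  parse_row <- function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop_syntsnp("ptt line ", i, ": expected 9 tab-separated fields, got ",
                   length(f))
    m <- regmatches(f[1], regexec("^([0-9]+)\\.\\.([0-9]+)$", f[1]))[[1]]
    if (length(m) != 3L)
      stop_syntsnp("ptt line ", i, ": malformed Location field '", f[1], "'")
    start <- as.integer(m[2]); end <- as.integer(m[3])
    if (start > end)
      stop_syntsnp("ptt line ", i, ": Location start > end ('", f[1],
                   "'); wrap-around genes are not supported")
    if (!f[2] %in% c("+", "-"))
      stop_syntsnp("ptt line ", i, ": strand must be '+' or '-', got '", f[2], "'")
    list(start = start, end = end, strand = f[2],
         length_aa = suppressWarnings(as.integer(f[3])),
         pid = f[4], name = f[5], gene_id = f[6], product = f[9])
  }
  rows <- lapply(body_idx, parse_row)
  genes <- if (length(rows)) {
    data.frame(
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      name = vapply(rows, `[[`, "", "name"),
      start = vapply(rows, `[[`, 1L, "start"),
      end = vapply(rows, `[[`, 1L, "end"),
      strand = vapply(rows, `[[`, "", "strand"),
      length_aa = vapply(rows, `[[`, 1L, "length_aa"),
      pid = vapply(rows, `[[`, "", "pid"),
      product = vapply(rows, `[[`, "", "product"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), name = character(), start = integer(),
               end = integer(), strand = character(), length_aa = integer(),
               pid = character(), product = character())
  }
  if (is.character(sequence) && length(sequence) == 1L && file.exists(sequence)) {
    seqs <- read_fasta(sequence)
    if (length(seqs) != 1L)
      stop_syntsnp("companion FASTA must hold exactly one record: ", sequence)
    sequence <- unname(seqs[[1L]])
  }
  genome_record(genome_id, genes,
                length = if (is.null(sequence)) title_len,
                sequence = sequence,
                description = description, circular = circular)
}

#' Write a genome's annotation as a ptt protein table
#'
#' @param genome A [genome_record()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ptt <- function(genome, path) {
  g <- genome$genes
  n <- nrow(g)
  header <- c(
    sprintf("%s - 1..%d", genome$description %||% genome$genome_id,
            genome$length),
    sprintf("%d proteins", n),
    paste(c("Location", "Strand", "Length", "PID", "Gene", "Synonym",
            "Code", "COG", "Product"), collapse = "\t"))
  length_aa <- if ("length_aa" %in% names(g)) g$length_aa
               else (g$end - g$start + 1L) %/% 3L - 1L
  body <- if (n) sprintf("%d..%d\t%s\t%s\t%s\t%s\t%s\t-\t-\t%s",
                         g$start, g$end, g$strand,
                         ifelse(is.na(length_aa), "-", length_aa),
                         g$pid, g$name, g$gene_id, g$product)
          else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#' `read_fasta` rejects duplicate identifiers; `write_fasta` then
#' `read_fasta` round-trips identifiers and sequences exactly.
#'
#' @param path File path.
#' @param records Named character vector of sequences.
#' @param width Line width for sequence wrapping on output.
#' @return `read_fasta`: named character vector (possibly empty).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop_syntsnp("duplicate FASTA identifiers in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (length(records) && is.null(names(records)))
    stop_syntsnp("records must be a named character vector")
  set <- Biostrings::BStringSet(unlist(records) %||% character())
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a 12-column tabular protein similarity report
#'
#' Accepts the standard 12-column tab-separated BLAST dialect (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bit score). Query coverage is
#' derived as `(qend - qstart + 1) / query length`, clamped to `[0, 1]`;
#' query lengths (in the same residue units as qstart/qend) are supplied as
#' a named vector, typically from a ptt `Length` column.
#'
#' @param path Path to the tabular report.
#' @param query_lengths Named numeric vector: query identifier -> query
#'   protein length. Queries missing from it get `NA` coverage.
#' @return Data frame of hits with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `e_value`, `bit_score`, `query_cov`.
#' @export
read_blast_tabular <- function(path, query_lengths = NULL) {
  lines <- readLines(path)
  lines_idx <- which(nzchar(lines) & !startsWith(lines, "#"))
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "e_value", "bit_score")
  if (!length(lines_idx)) {
    df <- as.data.frame(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)), cols))
    df$query_cov <- numeric()
    return(df)
  }
  parts <- strsplit(lines[lines_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop_syntsnp("line ", lines_idx[which(nf != 12L)[1L]],
                 ": expected 12 tab-separated fields, got ",
                 nf[which(nf != 12L)[1L]])
  m <- do.call(rbind, parts)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop_syntsnp("line ", lines_idx[which(is.na(v))[1L]],
                   ": non-numeric value '", m[which(is.na(v))[1L], j],
                   "' in column ", j)
    v
  }
  df <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                   pct_identity = num(3L), aln_length = num(4L),
                   mismatch = num(5L), gapopen = num(6L),
                   qstart = num(7L), qend = num(8L),
                   sstart = num(9L), send = num(10L),
                   e_value = num(11L), bit_score = num(12L),
                   stringsAsFactors = FALSE)
  if (any(df$pct_identity < 0 | df$pct_identity > 100))
    stop_syntsnp("pct_identity outside [0,100] in ", path)
  if (any(df$e_value < 0))
    stop_syntsnp("negative e-value in ", path)
  qlen <- if (is.null(query_lengths)) rep(NA_real_, nrow(df))
          else unname(query_lengths[df$query_id])
  df$query_cov <- pmin(1, pmax(0, (df$qend - df$qstart + 1) / qlen))
  df
}

#' Write hits in the 12-column tabular dialect
#' @param hits Data frame as returned by [read_blast_tabular()].
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  fmt <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
                 hits$query_id, hits$subject_id, hits$pct_identity,
                 as.integer(hits$aln_length), as.integer(hits$mismatch),
                 as.integer(hits$gapopen), as.integer(hits$qstart),
                 as.integer(hits$qend), as.integer(hits$sstart),
                 as.integer(hits$send), hits$e_value, hits$bit_score)
  writeLines(fmt, path)
  invisible(path)
}

corr_cols <- c("ref_gene_id", "target_genome_id", "target_gene_id",
               "pct_identity", "query_cov", "bit_score", "e_value")

#' Read and write protein correspondence (ortholog pair) tables
#'
#' Tab-delimited dialect with a `#`-prefixed header line and columns
#' `ref_gene_id`, `target_genome_id`, `target_gene_id`, `pct_identity`,
#' `query_cov`, `bit_score`, `e_value`.
#'
#' @param path File path.
#' @param pairs Ortholog pair data frame (the dialect columns above).
#' @return `read_correspondence`: data frame of ortholog pairs.
#' @export
read_correspondence <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) {
    return(as.data.frame(stats::setNames(
      c(rep(list(character()), 3L), rep(list(numeric()), 4L)), corr_cols)))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L))
    stop_syntsnp("line ", keep[which(nf != 7L)[1L]],
                 ": expected 7 tab-separated fields, got ", nf[which(nf != 7L)[1L]])
  m <- do.call(rbind, parts)
  df <- data.frame(ref_gene_id = m[, 1L], target_genome_id = m[, 2L],
                   target_gene_id = m[, 3L],
                   pct_identity = as.numeric(m[, 4L]),
                   query_cov = as.numeric(m[, 5L]),
                   bit_score = as.numeric(m[, 6L]),
                   e_value = as.numeric(m[, 7L]), stringsAsFactors = FALSE)
  if (anyNA(df[4:7]))
    stop_syntsnp("non-numeric metric field in correspondence file ", path)
  if (any(df$pct_identity < 0 | df$pct_identity > 100) ||
      any(df$query_cov < 0 | df$query_cov > 1) || any(df$e_value < 0))
    stop_syntsnp("metric out of range in correspondence file ", path)
  df
}

#' @rdname read_correspondence
#' @export
write_correspondence <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(corr_cols, collapse = "\t")), con)
  if (nrow(pairs)) {
    writeLines(sprintf("%s\t%s\t%s\t%.3f\t%.4f\t%.1f\t%.3g",
                       pairs$ref_gene_id, pairs$target_genome_id,
                       pairs$target_gene_id, pairs$pct_identity,
                       pairs$query_cov, pairs$bit_score, pairs$e_value), con)
  }
  invisible(path)
}

#' Read and write tab-delimited SNP tables
#'
#' Dialect: `#`-prefixed header, then columns `strain_id`, `position`,
#' `ref_allele`, `alt_allele` and optionally `coverage`. Alleles are single
#' bases in `{A,C,G,T}` and must differ; when the reference sequence is
#' supplied every `ref_allele` is validated against it.
#'
#' @param path File path.
#' @param reference Optional reference nucleotide sequence (string) used to
#'   validate `ref_allele` at each position.
#' @param snps SNP data frame to write.
#' @return `read_snp_table`: data frame with columns `strain_id`,
#'   `position`, `ref_allele`, `alt_allele`, `coverage` (`NA` when absent).
#' @export
read_snp_table <- function(path, reference = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) {
    return(data.frame(strain_id = character(), position = integer(),
                      ref_allele = character(), alt_allele = character(),
                      coverage = numeric()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L | nf > 5L))
    stop_syntsnp("line ", keep[which(nf < 4L | nf > 5L)[1L]],
                 ": expected 4 or 5 tab-separated fields")
  df <- data.frame(
    strain_id = vapply(parts, `[[`, "", 1L),
    position = as.integer(vapply(parts, `[[`, "", 2L)),
    ref_allele = toupper(vapply(parts, `[[`, "", 3L)),
    alt_allele = toupper(vapply(parts, `[[`, "", 4L)),
    coverage = vapply(parts, function(f)
      if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else NA_real_, 0),
    stringsAsFactors = FALSE)
  if (anyNA(df$position))
    stop_syntsnp("non-numeric position in SNP table ", path)
  validate_snps(df, reference = reference, what = path)
  df
}

# Shared SNP invariants: alleles in {A,C,G,T}, ref != alt, position in
# range, ref matches loaded reference sequence.
validate_snps <- function(snps, reference = NULL, what = "SNP table") {
  if (!nrow(snps)) return(invisible(snps))
  ok <- snps$ref_allele %in% c("A", "C", "G", "T") &
        snps$alt_allele %in% c("A", "C", "G", "T")
  if (!all(ok))
    stop_syntsnp(what, ": alleles must be single bases in {A,C,G,T}")
  same <- snps$ref_allele == snps$alt_allele
  if (any(same))
    stop_syntsnp(what, ": ref_allele equals alt_allele at position ",
                 snps$position[which(same)[1L]])
  if (any(snps$position < 1L))
    stop_syntsnp(what, ": positions must be >= 1")
  if (!is.null(reference)) {
    if (any(snps$position > nchar(reference)))
      stop_syntsnp(what, ": position beyond reference length ",
                   nchar(reference))
    base <- substring(reference, snps$position, snps$position)
    bad <- base != snps$ref_allele
    if (any(bad)) {
      i <- which(bad)[1L]
      stop_syntsnp(what, ": ref_allele mismatch at position ",
                   snps$position[i], " (table says ", snps$ref_allele[i],
                   ", reference has ", base[i], ")")
    }
  }
  invisible(snps)
}

#' @rdname read_snp_table
#' @export
write_snp_table <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#strain_id\tposition\tref_allele\talt_allele\tcoverage", con)
  if (nrow(snps)) {
    cov <- if ("coverage" %in% names(snps)) snps$coverage else NA_real_
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s", snps$strain_id,
                       as.integer(snps$position), snps$ref_allele,
                       snps$alt_allele,
                       ifelse(is.na(cov), "-", format(cov, trim = TRUE))), con)
  }
  invisible(path)
}

#' Read a strain metadata table
#'
#' Tab-delimited with a header line (optionally `#`-prefixed): `strain_id`
#' followed by named categorical attribute columns. Strain identifiers must
#' be unique; empty cells become `NA` ("unassigned" in grouped analyses).
#'
#' @param path File path.
#' @return Data frame, one row per strain, first column `strain_id`.
#' @export
read_metadata <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_syntsnp("empty metadata file: ", path)
  header <- sub("^#", "", lines[1L])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (cols[1L] != "strain_id")
    stop_syntsnp("metadata header must start with 'strain_id': ", path)
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  df <- as.data.frame(stats::setNames(lapply(seq_along(cols), function(j)
    vapply(parts, function(f) if (length(f) >= j) f[j] else "", "")), cols),
    stringsAsFactors = FALSE)
  df[df == ""] <- NA
  if (anyDuplicated(df$strain_id))
    stop_syntsnp("duplicate strain_id in metadata: ",
                 paste(unique(df$strain_id[duplicated(df$strain_id)]),
                       collapse = ", "))
  df
}

#' Write a strain metadata table
#' @param metadata Data frame, first column `strain_id`.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  m <- metadata
  m[] <- lapply(m, function(v) ifelse(is.na(v), "", as.character(v)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(m), collapse = "\t"), con)
  if (nrow(m)) writeLines(do.call(paste, c(m, sep = "\t")), con)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' bedGraph intervals are 0-based half-open on disk; they are converted to
#' 1-based inclusive in memory (`start + 1`, `end` unchanged). Intervals are
#' sorted and must not overlap.
#'
#' @param path File path.
#' @param strain_id Strain label attached to the track.
#' @return Object of class `coverage_track`: data frame with columns
#'   `strain_id`, `start`, `end`, `depth` plus attribute `strain_id`.
#' @export
read_bedgraph <- function(path, strain_id = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                !startsWith(lines, "track"))
  strain_id <- strain_id %||% sub("\\.[^.]*$", "", basename(path))
  if (!length(keep)) {
    tr <- data.frame(strain_id = character(), start = integer(),
                     end = integer(), depth = numeric())
    class(tr) <- c("coverage_track", "data.frame")
    return(tr)
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    stop_syntsnp("line ", keep[which(lengths(parts) < 4L)[1L]],
                 ": bedGraph needs 4 fields")
  start0 <- as.integer(vapply(parts, `[[`, "", 2L))
  end0 <- as.integer(vapply(parts, `[[`, "", 3L))
  depth <- as.numeric(vapply(parts, `[[`, "", 4L))
  if (anyNA(start0) || anyNA(end0) || anyNA(depth))
    stop_syntsnp("non-numeric bedGraph field in ", path)
  if (any(depth < 0)) stop_syntsnp("negative depth in ", path)
  tr <- data.frame(strain_id = strain_id, start = start0 + 1L, end = end0,
                   depth = depth)
  tr <- tr[order(tr$start), , drop = FALSE]
  if (nrow(tr) > 1L && any(tr$start[-1L] <= tr$end[-nrow(tr)]))
    stop_syntsnp("overlapping bedGraph intervals in ", path)
  rownames(tr) <- NULL
  class(tr) <- c("coverage_track", "data.frame")
  tr
}

#' Write intervals as BED
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open
#' convention (`start - 1`, `end` unchanged).
#'
#' @param intervals Data frame with columns `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @param chrom Chromosome label for column 1.
#' @export
write_bed <- function(intervals, path, chrom = "ref") {
  name <- if ("name" %in% names(intervals)) intervals$name
          else sprintf("region_%d", seq_len(nrow(intervals)))
  lines <- if (nrow(intervals))
    sprintf("%s\t%d\t%d\t%s", chrom, as.integer(intervals$start) - 1L,
            as.integer(intervals$end), name)
  else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Wrappers over ape preserving leaf names, topology and branch lengths to
#' printed precision.
#'
#' @param path File path.
#' @param tree An ape `phylo` object.
#' @param digits Printed branch-length precision.
#' @return `read_newick`: an ape `phylo`.
#' @export
read_newick <- function(path) {
  fail <- function(c) stop_syntsnp("Newick parse error in ", path, ": ",
                                   conditionMessage(c))
  tree <- tryCatch(ape::read.tree(path), error = fail, warning = fail)
  if (is.null(tree)) stop_syntsnp("Newick parse error in ", path)
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path, digits = 10L) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Export a gene table for a selection of genes
#'
#' Writes a tab-delimited table (header + one row per selected gene) with
#' identifier, name, coordinates, strand and product, stably sorted by the
#' requested column with ties broken by `gene_id`. Output is
#' byte-deterministic for a given selection.
#'
#' @param genome A [genome_record()].
#' @param selection Character vector of gene identifiers (a gene basket).
#' @param path Output path.
#' @param sort_by Column to sort on: one of `"start"`, `"end"`,
#'   `"gene_id"`, `"name"`.
#' @return Invisibly, the exported data frame.
#' @export
export_gene_table <- function(genome, selection, path,
                              sort_by = c("start", "end", "gene_id", "name")) {
  sort_by <- match.arg(sort_by)
  g <- genome$genes
  unknown <- setdiff(selection, g$gene_id)
  if (length(unknown))
    stop_syntsnp("unknown gene_id in selection: ",
                 paste(unknown, collapse = ", "))
  out <- g[g$gene_id %in% selection,
           c("gene_id", "name", "start", "end", "strand", "product"),
           drop = FALSE]
  out <- order_by(out, c(sort_by, "gene_id"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s\t%s", out$gene_id, out$name,
                       out$start, out$end, out$strand, out$product), con)
  invisible(out)
}

#' Write a generic tab-delimited table with a # header
#' @param df Data frame.
#' @param path Output path.
#' @keywords internal
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    cells <- lapply(df, function(v) {
      if (is.double(v)) format(v, trim = TRUE, scientific = FALSE, digits = 10)
      else as.character(v)
    })
    writeLines(do.call(paste, c(cells, sep = "\t")), con)
  }
  invisible(path)
}
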