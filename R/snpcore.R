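# SNP location relative to annotation and coding-effect classification.
#
# Effects are classified under the bacterial/archaeal genetic code
# (translation table 11) into {synonymous, nonsynonymous, stop_gained,
# intergenic}; stop-loss substitutions are folded into nonsynonymous and a
# SNP falling in an overlapping gene is classified once per gene. Codons
# containing ambiguous bases (N), and positions past the last full codon of
# a gene whose length is not a multiple of three, get effect "unknown".

#' Locate SNPs relative to gene annotation
#'
#' Interval stabbing of SNP positions against gene extents: a SNP is genic
#' when at least one gene satisfies `start <= position <= end`, else
#' intergenic. Overlapping genes each contribute a hit.
#'
#' @param snps SNP data frame (`strain_id`, `position`, `ref_allele`,
#'   `alt_allele`).
#' @param genome Reference [genome_record()].
#' @return Data frame with one row per (SNP, overlapping gene): columns
#'   `snp_row` (row index into `snps`), `gene_id`. SNPs absent from it are
#'   intergenic.
#' @export
locate_snps <- function(snps, genome) {
  if (any(snps$position < 1L | snps$position > genome$length))
    stop_syntsnp("SNP position outside [1, ", genome$length, "]")
  if (!nrow(snps) || !nrow(genome$genes))
    return(data.frame(snp_row = integer(), gene_id = character()))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(snps$position, snps$position),
    IRanges::IRanges(genome$genes$start, genome$genes$end))
  data.frame(snp_row = S4Vectors::queryHits(hits),
             gene_id = genome$genes$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

# Vectorised effect classification for genic SNPs.
# position/alt: vectors; gi: row indices into genome$genes. Returns a data
# frame of codon bookkeeping and the effect call.
classify_core <- function(position, alt, gi, genome) {
  g <- genome$genes
  seqc <- genome$sequence
  if (is.null(seqc)) stop_syntsnp("genome sequence required for classification")
  start <- g$start[gi]; end <- g$end[gi]; strand <- g$strand[gi]
  len <- end - start + 1L
  fwd <- strand == "+"
  off <- ifelse(fwd, position - start, end - position)  # 0-based CDS offset
  codon_index <- off %/% 3L + 1L
  codon_position <- off %% 3L + 1L
  # genome coordinates of the codon (left end on the genome)
  codon_left <- ifelse(fwd, start + (codon_index - 1L) * 3L,
                       end - codon_index * 3L + 1L)
  in_frame <- codon_index * 3L <= len  # full codon inside the gene
  ref_codon <- rep(NA_character_, length(position))
  alt_codon <- rep(NA_character_, length(position))
  raw <- substring(seqc, codon_left, codon_left + 2L)
  raw[!in_frame] <- NA_character_
  # CDS-orientation codons
  ref_codon[fwd & in_frame] <- raw[fwd & in_frame]
  if (any(!fwd & in_frame))
    ref_codon[!fwd & in_frame] <- revcomp(raw[!fwd & in_frame])
  cds_alt <- ifelse(fwd, alt, comp_base(alt))
  ok <- in_frame
  alt_codon[ok] <- paste0(
    substring(ref_codon[ok], 1L, codon_position[ok] - 1L),
    cds_alt[ok],
    substring(ref_codon[ok], codon_position[ok] + 1L, 3L))
  ref_aa <- translate_codons(ref_codon)
  alt_aa <- translate_codons(alt_codon)
  effect <- rep("unknown", length(position))
  known <- ok & !is.na(ref_aa) & !is.na(alt_aa)
  effect[known & ref_aa == alt_aa] <- "synonymous"
  effect[known & ref_aa != alt_aa] <- "nonsynonymous"
  effect[known & alt_aa == "*" & ref_aa != "*"] <- "stop_gained"
  data.frame(codon_index = codon_index, codon_position = codon_position,
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
             frame_ok = in_frame, stringsAsFactors = FALSE)
}

#' Classify the coding effect of one SNP within one gene
#'
#' Codon bookkeeping is anchored at the start codon: for a forward-strand
#' gene at the SNP's 0-based offset `o` from the gene start,
#' `codon_index = o %/% 3 + 1` and `codon_position = o %% 3 + 1`; for a
#' reverse-strand gene offsets are counted from the gene end and both codons
#' are reverse-complemented before translation with the bacterial code
#' (table 11). The effect is `stop_gained` when the alternate amino acid is
#' a stop and the reference is not, `synonymous` when the amino acids are
#' equal, else `nonsynonymous` (including stop loss). Codons containing N,
#' or positions past the last complete codon of a gene whose length is not a
#' multiple of three, yield `unknown`.
#'
#' @param position 1-based SNP position on the reference.
#' @param alt_allele Alternate base.
#' @param gene_id Identifier of the gene containing the SNP.
#' @param genome Reference [genome_record()] with sequence.
#' @return One-row data frame: `codon_index`, `codon_position`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect`.
#' @examples
#' g <- data.frame(gene_id = "g1", name = "-", start = 1, end = 9,
#'                 strand = "+", pid = 1L, product = "demo")
#' gen <- genome_record("demo", g, sequence = "ATGAAATAA")
#' classify_snp(6, "G", "g1", gen)  # AAA -> AAG, synonymous
#' @export
classify_snp <- function(position, alt_allele, gene_id, genome) {
  gi <- match(gene_id, genome$genes$gene_id)
  if (is.na(gi)) stop_syntsnp("unknown gene: ", gene_id)
  g <- genome$genes[gi, ]
  if (position < g$start || position > g$end)
    stop_syntsnp("SNP position ", position, " not inside gene ", gene_id)
  if ((g$end - g$start + 1L) %% 3L != 0L)
    warning("gene ", gene_id, " length is not a multiple of 3; ",
            "reading frame anchored at the start codon", call. = FALSE)
  out <- classify_core(position, toupper(alt_allele), gi, genome)
  out$frame_ok <- NULL
  out
}

#' Annotate a SNP set against a reference genome
#'
#' Produces one annotation row per (SNP, overlapping gene) plus one
#' intergenic row for each SNP overlapped by no gene, in deterministic
#' (position, strain, gene) order. Reference alleles are validated against
#' the genome sequence.
#'
#' @param snps SNP data frame.
#' @param genome Reference [genome_record()] with sequence.
#' @return Data frame with columns `strain_id`, `position`, `ref_allele`,
#'   `alt_allele`, `location` (`genic`/`intergenic`), `gene_id` (`NA` when
#'   intergenic), `codon_index`, `codon_position`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `effect`.
#' @export
annotate_snps <- function(snps, genome) {
  empty <- data.frame(strain_id = character(), position = integer(),
                      ref_allele = character(), alt_allele = character(),
                      location = character(), gene_id = character(),
                      codon_index = integer(), codon_position = integer(),
                      ref_codon = character(), alt_codon = character(),
                      ref_aa = character(), alt_aa = character(),
                      effect = character())
  if (!nrow(snps)) return(empty)
  validate_snps(snps, reference = genome$sequence, what = "snps")
  loc <- locate_snps(snps, genome)
  gi <- match(loc$gene_id, genome$genes$gene_id)

  # warn once per out-of-frame gene touched by a SNP
  if (length(gi)) {
    glen <- genome$genes$end[gi] - genome$genes$start[gi] + 1L
    bad <- unique(loc$gene_id[glen %% 3L != 0L])
    if (length(bad))
      warning("gene(s) with length not a multiple of 3: ",
              paste(bad, collapse = ", "),
              "; frames anchored at start codons", call. = FALSE)
  }
  genic <- if (nrow(loc)) {
    cls <- classify_core(snps$position[loc$snp_row],
                         snps$alt_allele[loc$snp_row], gi, genome)
    data.frame(strain_id = snps$strain_id[loc$snp_row],
               position = snps$position[loc$snp_row],
               ref_allele = snps$ref_allele[loc$snp_row],
               alt_allele = snps$alt_allele[loc$snp_row],
               location = "genic", gene_id = loc$gene_id,
               codon_index = cls$codon_index,
               codon_position = cls$codon_position,
               ref_codon = cls$ref_codon, alt_codon = cls$alt_codon,
               ref_aa = cls$ref_aa, alt_aa = cls$alt_aa,
               effect = cls$effect, stringsAsFactors = FALSE)
  } else empty
  inter_rows <- setdiff(seq_len(nrow(snps)), unique(loc$snp_row))
  inter <- if (length(inter_rows)) {
    data.frame(strain_id = snps$strain_id[inter_rows],
               position = snps$position[inter_rows],
               ref_allele = snps$ref_allele[inter_rows],
               alt_allele = snps$alt_allele[inter_rows],
               location = "intergenic", gene_id = NA_character_,
               codon_index = NA_integer_, codon_position = NA_integer_,
               ref_codon = NA_character_, alt_codon = NA_character_,
               ref_aa = NA_character_, alt_aa = NA_character_,
               effect = "intergenic", stringsAsFactors = FALSE)
  } else empty
  out <- rbind(genic, inter)
  out <- order_by(out, c("position", "strain_id", "gene_id"))
  rownames(out) <- NULL
  out
}

#' Write an annotated SNP table
#' @param annotations Data frame from [annotate_snps()].
#' @param path Output path.
#' @export
write_snp_annotations <- function(annotations, path) {
  a <- annotations
  a[] <- lapply(a, function(v) ifelse(is.na(v), "-", as.character(v)))
  write_tsv_hash(a, path)
}
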