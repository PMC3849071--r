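# Brute-force oracles and tiny fixture builders. Every oracle is written as
# the simplest possible loop, independent of the implementation it checks.

tiny_genome <- function(sequence, genes, genome_id = "tiny", length = NULL) {
  defaults <- data.frame(name = "-", pid = "1", product = "protein",
                         stringsAsFactors = FALSE)
  for (col in names(defaults))
    if (!col %in% names(genes)) genes[[col]] <- defaults[[col]]
  genome_record(genome_id, genes, sequence = sequence, length = length)
}

# --- best hit / BDBH ---------------------------------------------------

# Slow per-query best hit: explicit pairwise comparisons.
oracle_best_hit <- function(hits, q) {
  h <- hits[hits$query_id == q & hits$query_id != hits$subject_id, ,
            drop = FALSE]
  if (!nrow(h)) return(NULL)
  better <- function(i, j) {
    if (h$bit_score[i] != h$bit_score[j]) return(h$bit_score[i] > h$bit_score[j])
    if (h$e_value[i] != h$e_value[j]) return(h$e_value[i] < h$e_value[j])
    if (h$pct_identity[i] != h$pct_identity[j])
      return(h$pct_identity[i] > h$pct_identity[j])
    h$subject_id[i] < h$subject_id[j]
  }
  best <- 1L
  for (i in seq_len(nrow(h))[-1L]) if (better(i, best)) best <- i
  h[best, , drop = FALSE]
}

# Reciprocity check over every (a, b) gene pair.
oracle_bdbh <- function(hits_ab, hits_ba) {
  out <- list()
  for (a in sort(unique(hits_ab$query_id))) {
    fa <- oracle_best_hit(hits_ab, a)
    if (is.null(fa)) next
    fb <- oracle_best_hit(hits_ba, fa$subject_id)
    if (!is.null(fb) && fb$subject_id == a)
      out[[length(out) + 1L]] <- data.frame(
        ref_gene_id = a, target_gene_id = fa$subject_id,
        bit_score = fa$bit_score, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(ref_gene_id = character(),
                      target_gene_id = character(), bit_score = numeric()))
  do.call(rbind, out)
}

# Random one-direction hit table between gene sets qs and ss.
random_hits <- function(qs, ss, n) {
  data.frame(query_id = sample(qs, n, replace = TRUE),
             subject_id = sample(ss, n, replace = TRUE),
             pct_identity = round(runif(n, 20, 100), 1),
             aln_length = sample(50:500, n, replace = TRUE),
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
             sstart = 1L, send = 100L,
             e_value = signif(10^-sample(0:100, n, replace = TRUE), 3),
             bit_score = sample(seq(30, 800, by = 10), n, replace = TRUE),
             query_cov = round(runif(n, 0.1, 1), 2),
             stringsAsFactors = FALSE)
}

# --- synteny -----------------------------------------------------------

# Maximal-run scanner for max_gap = 0: consecutive ref indices with target
# indices stepping by a constant +1/-1.
oracle_runs <- function(ref_idx, target_idx, min_pairs = 2L) {
  ord <- order(ref_idx)
  r <- ref_idx[ord]; t <- target_idx[ord]
  runs <- list()
  i <- 1L
  while (i <= length(r)) {
    j <- i
    dir <- 0L
    while (j < length(r) && r[j + 1L] == r[j] + 1L) {
      step <- t[j + 1L] - t[j]
      if (abs(step) != 1L) break
      if (dir == 0L) dir <- step
      else if (step != dir) break
      j <- j + 1L
    }
    if (j - i + 1L >= min_pairs)
      runs[[length(runs) + 1L]] <-
        list(ref_first = r[i], ref_last = r[j],
             orientation = if (dir == -1L) "inverted" else "collinear")
    i <- j + 1L
  }
  runs
}

# --- SNP location and effect -------------------------------------------

oracle_locate <- function(position, genes) {
  hits <- character()
  for (k in seq_len(nrow(genes)))
    if (genes$start[k] <= position && position <= genes$end[k])
      hits <- c(hits, genes$gene_id[k])
  hits
}

# Whole-gene translate-and-compare, one SNP at a time.
oracle_effect <- function(position, alt, gene, sequence) {
  glen <- gene$end - gene$start + 1L
  if (glen %% 3L != 0L) return("unknown")
  ref_nt <- substring(sequence, gene$start, gene$end)
  chars <- strsplit(ref_nt, "")[[1]]
  chars[position - gene$start + 1L] <- alt
  alt_nt <- paste(chars, collapse = "")
  if (gene$strand == "-") {
    ref_nt <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref_nt)))
    alt_nt <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt_nt)))
  }
  if (grepl("N", ref_nt) || grepl("N", alt_nt)) return("unknown")
  gc11 <- Biostrings::getGeneticCode("11")
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), genetic.code = gc11, no.init.codon = TRUE))
  p_ref <- tr(ref_nt); p_alt <- tr(alt_nt)
  if (p_ref == p_alt) return("synonymous")
  off <- if (gene$strand == "+") position - gene$start
         else gene$end - position
  ci <- off %/% 3L + 1L
  ra <- substring(p_ref, ci, ci); aa <- substring(p_alt, ci, ci)
  if (aa == "*" && ra != "*") "stop_gained" else "nonsynonymous"
}

# Mirror a genome and its SNPs through reverse complementation.
mirror_genome <- function(genome) {
  L <- genome$length
  g <- genome$genes
  g2 <- g
  g2$start <- L - g$end + 1L
  g2$end <- L - g$start + 1L
  g2$strand <- ifelse(g$strand == "+", "-", "+")
  genome_record(paste0(genome$genome_id, "_rc"), g2,
                sequence = as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(genome$sequence))))
}

mirror_snps <- function(snps, L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  data.frame(strain_id = snps$strain_id, position = L - snps$position + 1L,
             ref_allele = unname(comp[snps$ref_allele]),
             alt_allele = unname(comp[snps$alt_allele]),
             stringsAsFactors = FALSE)
}

# Random genic SNPs with alt != ref drawn uniformly.
random_genic_snps <- function(genome, n) {
  g <- genome$genes
  gi <- sample(nrow(g), n, replace = TRUE)
  pos <- g$start[gi] + vapply(gi, function(i)
    sample.int(g$end[i] - g$start[i] + 1L, 1L) - 1L, 1L)
  ref <- substring(genome$sequence, pos, pos)
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "",
                USE.NAMES = FALSE)
  data.frame(strain_id = sprintf("s%02d", sample(5L, n, replace = TRUE)),
             position = pos, ref_allele = ref, alt_allele = alt,
             stringsAsFactors = FALSE)
}

# Robinson-Foulds distance between two unrooted topologies.
rf_dist <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                            method = "PH85"))
}
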