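# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_syntsnp <- function(...) stop(..., call. = FALSE)

#' Bacterial genetic code lookup (translation table 11)
#'
#' Named character vector mapping codons to one-letter amino acids, with
#' `"*"` for stop codons. Table 11 shares amino-acid assignments with the
#' standard code; it differs only in permitted initiation codons, which are
#' not treated specially here.
#' @keywords internal
genetic_code_11 <- function() {
  Biostrings::getGeneticCode("11")
}

# Translate a character vector of codons; codons containing characters
# outside ACGT (e.g. N) yield NA.
translate_codons <- function(codons) {
  gc11 <- genetic_code_11()
  aa <- unname(gc11[codons])
  aa
}

# Reverse-complement a character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# Validate a nucleotide sequence: uppercase, restrict to ACGTN.
check_sequence <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (any(nzchar(bad))) {
    stop_syntsnp(what, " contains characters outside {A,C,G,T,N}: ",
                 paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
                       collapse = ", "))
  }
  seq
}

# Stable data.frame ordering helper: order by the listed columns in turn.
order_by <- function(df, cols, decreasing = rep(FALSE, length(cols))) {
  args <- lapply(seq_along(cols), function(i) {
    v <- df[[cols[i]]]
    if (decreasing[i]) {
      if (is.numeric(v)) -xtfrm(v) else -xtfrm(v)
    } else xtfrm(v)
  })
  df[do.call(order, args), , drop = FALSE]
}

midpoint <- function(start, end) (start + end) / 2
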