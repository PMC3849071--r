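Package: syntsnp
Title: Synteny, Orthology and SNP Population Summaries for Microbial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable engine for comparative bacterial genomics built
    around an n-genomes-versus-one-reference data model. Computes
    bi-directional best-hit (BDBH) orthology from all-against-all protein
    similarity reports, chains orthologs into collinear and inverted synteny
    blocks, and derives dot-plot, line-plot and phylogenetic-profile data.
    Locates single nucleotide polymorphisms relative to gene annotation and
    classifies their coding effect (synonymous, nonsynonymous, stop gained)
    under the bacterial genetic code. Summarises polymorphism across strain
    collections: per-gene and per-kilobase SNP density maps, allele frequency
    spectra, metadata-grouped differential counts, artificial alignments of
    polymorphic positions, p/Jukes-Cantor distances and neighbor-joining
    trees, mutated-sequence export, low-coverage interval detection and
    strain ordering. Ships a fully seeded simulator (genomes with planted
    gene orders, rearranged derivatives with known ortholog maps, SNPs
    dropped down a known tree with known effects) and a command-line
    interface over every pipeline. Reads GenBank ptt, FASTA, 12-column BLAST
    tabular, tab-delimited SNP/correspondence/metadata tables, bedGraph and
    Newick.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
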