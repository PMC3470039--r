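# In-code fixture builders shared across test files.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# Minimal hand-written GFF3 (gene -> mRNA -> exon chains).
write_tmp_gff3 <- function(body) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", body), f)
  f
}

gff_line <- function(chr, type, start, end, strand, id, parent = NULL) {
  attrs <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
  paste(chr, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# A toy annotation built directly through the constructor.
toy_annotation <- function(n = 5, chr = "chr1") {
  starts <- seq(100, by = 1000, length.out = n)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)), chromosome = chr,
                      strand = "+", start = starts, end = starts + 500)
  genome_annotation(genes)
}

# Random valid MSA for property tests.
random_msa <- function(n_seq = 5, n_col = 40, gap_p = 0.3) {
  rows <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(c("A", "C", "D", "E", "-"), n_col, replace = TRUE,
                    prob = c(rep((1 - gap_p) / 4, 4), gap_p))
    paste(chars, collapse = "")
  }, character(1))
  # make sure no column is needed-empty in a way msa() would reject (msa()
  # accepts all-gap columns; nothing to fix)
  msa(sprintf("s%d", seq_len(n_seq)), rows)
}

# Exon structures with conserved lengths planted at given 5'-anchored
# ordinals; all other lengths are globally unique so no accidental groups
# can arise.
planted_exon_structures <- function(n_genes = 6, n_exons = 9,
                                    planted = c("2" = 80, "3" = 125, "5" = 93)) {
  pool <- setdiff(seq(700, 5000), as.integer(planted))
  used <- 0
  structs <- lapply(seq_len(n_genes), function(g) {
    lens <- pool[used + seq_len(n_exons)]
    used <<- used + n_exons
    for (ord in names(planted)) lens[as.integer(ord)] <- planted[[ord]]
    structure(list(gene_id = sprintf("g%d", g), exon_lengths = as.integer(lens),
                   n_exons = n_exons), class = "exon_structure")
  })
  structs
}
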