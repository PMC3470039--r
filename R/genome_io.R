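#' Read a protein FASTA file
#'
#' Reads protein sequences and validates them against the residue alphabet
#' used throughout the package: the 20 standard amino acids plus `X`
#' (unknown). Lowercase residues are upcased; the record order of the file is
#' preserved. The sequence id is the first whitespace-delimited token of the
#' header; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] named by sequence id, with a
#'   `description` metadata column.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "MKV", ">b", "MA"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop_format("not FASTA: %s (%s)", path, conditionMessage(e)))
  if (length(set) == 0L) stop_format("empty FASTA file: %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop_validation("duplicate sequence id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) stop_validation("empty sequence record in %s", path)
  bad <- grepl("[-.]", seqs)
  if (any(bad))
    stop_validation("gap characters in sequence(s): %s", paste(ids[bad], collapse = ", "))
  off <- grepl(sprintf("[^%s]", AA_LETTERS), seqs)
  if (any(off))
    stop_validation("non-standard residues (outside 20 amino acids + X) in: %s",
                    paste(ids[off], collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWYX"

#' Write protein sequences to FASTA
#'
#' @param seqs A named [Biostrings::AAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Construct a genome annotation
#'
#' The container behind all gene-order computations: an ordered gene table per
#' chromosome plus per-gene exon coordinates. Ordinal positions (0-based,
#' contiguous within each chromosome, assigned by start coordinate) are the
#' coordinate system used by window extraction and collinearity detection;
#' nucleotide coordinates stay 1-based inclusive as in GFF3.
#'
#' @param genes `data.frame` with columns `gene_id`, `chromosome`, `strand`
#'   (`+`/`-`), `start`, `end`, and optionally `protein_id` (defaults to
#'   `gene_id`).
#' @param exons Named list (by `gene_id`) of two-column matrices of exon
#'   `start`,`end` pairs. Genes absent from the list get a single exon
#'   spanning the gene.
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(genes, exons = list()) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chromosome", "strand", "start", "end")
  if (!all(need %in% names(genes)))
    stop_validation("genes table must have columns: %s", paste(need, collapse = ", "))
  if (is.null(genes$protein_id)) genes$protein_id <- genes$gene_id
  if (anyDuplicated(genes$gene_id))
    stop_validation("duplicate gene id(s): %s",
                    paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop_validation("unknown strand value(s): %s",
                    paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  if (any(genes$start > genes$end)) stop_validation("gene with start > end")

  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), , drop = FALSE]
  genes$ordinal <- unlist(lapply(split(seq_len(nrow(genes)), genes$chromosome),
                                 function(ix) seq_along(ix) - 1L), use.names = FALSE)
  rownames(genes) <- NULL

  exon_list <- vector("list", nrow(genes))
  names(exon_list) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ex <- exons[[gid]]
    if (is.null(ex)) ex <- matrix(c(genes$start[i], genes$end[i]), ncol = 2)
    ex <- matrix(as.integer(ex), ncol = 2)
    colnames(ex) <- c("start", "end")
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (any(ex[, 1] > ex[, 2])) stop_validation("exon with start > end in gene %s", gid)
    if (any(ex[, 1] < genes$start[i] | ex[, 2] > genes$end[i]))
      stop_validation("exon outside gene span for gene %s", gid)
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2]))
      stop_validation("overlapping exons in gene %s", gid)
    exon_list[[i]] <- ex
  }

  structure(list(genes = genes, exons = exon_list), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  tab <- table(x$genes$chromosome)
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(tab)))
  for (chr in names(tab)) cat(sprintf("  %s: %d genes\n", chr, tab[[chr]]))
  invisible(x)
}

#' Look up a gene's chromosome and ordinal position
#'
#' @param ann A `genome_annotation`.
#' @param gene_id Gene identifier.
#' @return List with `chromosome` and `ordinal` (0-based).
#' @export
gene_position <- function(ann, gene_id) {
  i <- match(gene_id, ann$genes$gene_id)
  if (is.na(i)) stop_lookup("unknown gene id: %s", gene_id)
  list(chromosome = ann$genes$chromosome[i], ordinal = ann$genes$ordinal[i])
}

#' Read a GFF3 genome annotation
#'
#' Parses gene models from GFF3 via [rtracklayer::import()]. Exons are linked
#' to genes through `Parent` chains (`gene -> mRNA -> exon`, or exons directly
#' under the gene). For multi-isoform genes one isoform is retained: the
#' mRNA with the most exons, ties broken by longest spliced length, then
#' lexicographically smallest mRNA id. Coordinates are kept 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_format("not GFF3: %s (%s)", path, conditionMessage(e)))
  type <- as.character(gr$type)
  gi <- which(type == "gene")
  if (length(gi) == 0L) stop_format("no gene features in %s", path)

  feat_id <- as.character(gr$ID)
  parent <- gr$Parent  # CharacterList
  first_parent <- vapply(parent, function(p) if (length(p)) p[[1]] else NA_character_,
                         character(1))

  mi <- which(type %in% c("mRNA", "transcript"))
  ei <- which(type == "exon")

  genes <- data.frame(
    gene_id    = feat_id[gi],
    chromosome = as.character(GenomicRanges::seqnames(gr))[gi],
    strand     = as.character(GenomicRanges::strand(gr))[gi],
    start      = GenomicRanges::start(gr)[gi],
    end        = GenomicRanges::end(gr)[gi],
    stringsAsFactors = FALSE
  )
  if (!all(genes$strand %in% c("+", "-")))
    stop_validation("unknown strand for gene(s): %s",
                    paste(genes$gene_id[!genes$strand %in% c("+", "-")], collapse = ", "))
  pid <- gr$protein_id
  genes$protein_id <- if (!is.null(pid)) {
    ifelse(is.na(as.character(pid)[gi]), genes$gene_id, as.character(pid)[gi])
  } else genes$gene_id

  # exon coordinate sets keyed by parent feature id
  exon_by_parent <- split(data.frame(start = GenomicRanges::start(gr)[ei],
                                     end = GenomicRanges::end(gr)[ei]),
                          first_parent[ei])

  mrna_by_gene <- split(feat_id[mi], first_parent[mi])

  exons <- list()
  for (k in seq_len(nrow(genes))) {
    gid <- genes$gene_id[k]
    mrnas <- sort(mrna_by_gene[[gid]] %||% character(0))
    if (length(mrnas)) {
      exsets <- lapply(mrnas, function(m) exon_by_parent[[m]])
      keep <- !vapply(exsets, is.null, logical(1))
      mrnas <- mrnas[keep]; exsets <- exsets[keep]
    }
    if (length(mrnas)) {
      n_ex <- vapply(exsets, nrow, integer(1))
      splen <- vapply(exsets, function(e) sum(e$end - e$start + 1L), numeric(1))
      # most exons, then longest spliced length, then lexicographic id
      best <- order(-n_ex, -splen, mrnas)[1]
      ex <- exsets[[best]]
    } else {
      ex <- exon_by_parent[[gid]]
    }
    if (!is.null(ex)) exons[[gid]] <- as.matrix(ex[order(ex$start), , drop = FALSE])
  }
  genome_annotation(genes, exons)
}

#' Write a genome annotation to GFF3
#'
#' Emits `gene`, `mRNA`, and `exon` features (one mRNA per gene) via
#' [rtracklayer::export()], round-trippable through [read_gff3()].
#'
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes
  rows <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ex <- ann$exons[[gid]]
    rows[[i]] <- data.frame(
      seq = g$chromosome[i],
      start = c(g$start[i], g$start[i], ex[, 1]),
      end = c(g$end[i], g$end[i], ex[, 2]),
      strand = g$strand[i],
      type = c("gene", "mRNA", rep("exon", nrow(ex))),
      ID = c(gid, paste0(gid, ".1"), paste0(gid, ".1.exon", seq_len(nrow(ex)))),
      Parent = c(NA, gid, rep(paste0(gid, ".1"), nrow(ex))),
      protein_id = c(g$protein_id[i], NA, rep(NA, nrow(ex))),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seq,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand
  )
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- IRanges::CharacterList(lapply(tab$Parent, function(p)
    if (is.na(p)) character(0) else p))
  gr$protein_id <- tab$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of unique sequence ids.
#' @param rows Character vector of aligned rows (equal length, residues plus
#'   gap `-`).
#' @return An `msa` object holding the ids and the residue matrix.
#' @export
msa <- function(ids, rows) {
  ids <- as.character(ids); rows <- toupper(as.character(rows))
  if (length(ids) != length(rows)) stop_validation("ids and rows differ in length")
  if (anyDuplicated(ids)) stop_validation("duplicate alignment ids")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop_format("ragged alignment: row lengths %s",
                                   paste(sort(w), collapse = ", "))
  if (w < 1L) stop_validation("alignment must have at least one column")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$ids), n_columns(x)))
  invisible(x)
}

#' Number of alignment columns
#' @param x An `msa`.
#' @return Integer column count.
#' @export
n_columns <- function(x) ncol(x$mat)

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (all rows equal length).
#' @return An [msa()] object.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop_format("not FASTA: %s (%s)", path, conditionMessage(e)))
  if (length(set) == 0L) stop_format("empty alignment file: %s", path)
  msa(sub("\\s.*$", "", names(set)), as.character(set))
}

#' Write an alignment as aligned FASTA
#' @param x An `msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  set <- Biostrings::AAStringSet(apply(x$mat, 1, paste, collapse = ""))
  names(set) <- x$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Construct a homology hit table
#'
#' The 12-column blast-tabular dialect is the interchange currency between the
#' aligner, reciprocal-best-hit pairing, and collinearity detection.
#'
#' @param df Data frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`. Extra columns are preserved.
#' @return A `hit_table` (data frame subclass).
#' @export
hit_table <- function(df = NULL) {
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(HIT_COLUMNS)), HIT_COLUMNS))
    df$query_id <- character(0); df$subject_id <- character(0)
  }
  if (!all(HIT_COLUMNS %in% names(df)))
    stop_validation("hit table missing column(s): %s",
                    paste(setdiff(HIT_COLUMNS, names(df)), collapse = ", "))
  key <- do.call(paste, c(df[c("query_id", "subject_id", "qstart", "qend", "sstart", "send")],
                          sep = "\r"))
  if (anyDuplicated(key)) stop_validation("duplicate hit rows (same pair and coordinates)")
  if (any(df$evalue < 0)) stop_validation("negative E-value in hit table")
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Read a 12-column blast-tabular hit file
#' @param path Path to a tab-separated file with no header.
#' @return A [hit_table()].
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- tryCatch(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop_format("cannot parse hits file %s: %s", path, conditionMessage(e)))
  if (ncol(raw) != 12L)
    stop_format("expected 12 tab-separated columns, found %d in %s", ncol(raw), path)
  names(raw) <- HIT_COLUMNS
  for (col in HIT_COLUMNS[-(1:2)]) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(raw[[col]])) stop_format("non-numeric value in column %s of %s", col, path)
  }
  raw$query_id <- as.character(raw$query_id)
  raw$subject_id <- as.character(raw$subject_id)
  hit_table(raw)
}

#' Write a hit table as 12-column blast-tabular TSV
#' @param table A [hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(table, path) {
  out <- as.data.frame(table)[HIT_COLUMNS]
  # full double precision so read_hits(write_hits(x)) is lossless
  for (col in c("pct_identity", "evalue", "bitscore"))
    out[[col]] <- format(out[[col]], digits = 17, trim = TRUE, scientific = NA)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
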