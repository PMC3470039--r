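#' Exon-length profile of a gene
#'
#' Exon lengths in transcription orientation: for minus-strand genes the
#' annotation-order exons are reversed so ordinal 1 is the 5' exon. Lengths
#' are whatever exon features the annotation supplies (UTR inclusion depends
#' on the source GFF3; the output does not attempt to disambiguate).
#'
#' @param ann A [genome_annotation()].
#' @param gene_id Gene identifier.
#' @return An `exon_structure`: list with `gene_id`, `exon_lengths` (5'->3'),
#'   `n_exons`.
#' @export
exon_profile <- function(ann, gene_id) {
  i <- match(gene_id, ann$genes$gene_id)
  if (is.na(i)) stop_lookup("unknown gene id: %s", gene_id)
  ex <- ann$exons[[gene_id]]
  if (is.null(ex) || nrow(ex) == 0L) stop_validation("gene %s has no exons", gene_id)
  len <- ex[, 2] - ex[, 1] + 1L
  if (ann$genes$strand[i] == "-") len <- rev(len)
  structure(list(gene_id = gene_id, exon_lengths = as.integer(len),
                 n_exons = length(len)),
            class = "exon_structure")
}

#' Number of exons of a gene
#' @inheritParams exon_profile
#' @return Integer exon count.
#' @export
count_exons <- function(ann, gene_id) exon_profile(ann, gene_id)$n_exons

#' Exon profiles for all genes of an annotation
#' @param ann A [genome_annotation()].
#' @param gene_ids Genes to profile (default: all).
#' @return List of [exon_profile()] structures.
#' @export
exon_structures <- function(ann, gene_ids = ann$genes$gene_id) {
  lapply(gene_ids, function(g) exon_profile(ann, g))
}

#' Structural class parameters
#'
#' Two structural groups recur in plant gene families: compact genes with few
#' exons (often intronless) and multi-exon genes; defaults 1–3 vs 7+ exons.
#'
#' @param compact_max Maximum exon count of the compact class.
#' @param multi_min Minimum exon count of the multi-exon class.
#' @return A `structure_class_params` object.
#' @export
structure_class_params <- function(compact_max = 3, multi_min = 7) {
  if (!(compact_max < multi_min))
    stop_validation("need compact_max < multi_min")
  structure(list(compact_max = compact_max, multi_min = multi_min),
            class = "structure_class_params")
}

#' Classify a gene by exon count
#'
#' @param structure An [exon_profile()] structure (or an integer exon count).
#' @param p [structure_class_params()].
#' @return `"compact"`, `"multi"`, or `"other"`.
#' @export
classify_structure <- function(structure, p = structure_class_params()) {
  n <- if (inherits(structure, "exon_structure")) structure$n_exons else structure
  if (n <= p$compact_max) "compact" else if (n >= p$multi_min) "multi" else "other"
}

#' Conserved exon-size groups across genes
#'
#' Finds exon positions whose size is conserved across genes: exons are
#' grouped by ordinal anchored from the 5' end, plus a separate pass for the
#' terminal exon anchored from the 3' end (exon counts differ among family
#' members, but last-exon conservation is biologically common — e.g. a
#' C-terminal transmembrane domain encoded by the last exon). Within an
#' anchored ordinal, lengths are clustered greedily in sorted order; every
#' member of a group lies within `tolerance` nt of the group length (the
#' member median). Groups from the 3'-anchored pass that duplicate a
#' 5'-anchored group (same members) are dropped.
#'
#' @param structures List of [exon_profile()] structures (>= 2).
#' @param tolerance Allowed deviation from the group length in nucleotides
#'   (default 0: exact size sharing, suitable for curated annotations).
#' @param min_members Minimum group size to report (default 4).
#' @return List of `conserved_exon_group`s sorted by member count (then
#'   length): each has `members` (data frame `gene_id`, `exon_ordinal`,
#'   `anchor` = `"5p"`/`"3p"`), `length`, `tolerance`.
#' @export
conserved_exon_groups <- function(structures, tolerance = 0, min_members = 4) {
  if (length(structures) < 2L) stop_validation("need at least two structures")
  if (min_members < 2L) stop_validation("min_members must be >= 2")
  exon_rows <- do.call(rbind, lapply(structures, function(s) {
    data.frame(gene_id = s$gene_id,
               ordinal = seq_len(s$n_exons),
               last = seq_len(s$n_exons) == s$n_exons,
               length = s$exon_lengths,
               stringsAsFactors = FALSE)
  }))

  cluster_lengths <- function(df, anchor) {
    df <- df[order(df$length, df$gene_id), , drop = FALSE]
    groups <- list()
    cur <- df[0, ]
    flush <- function(cur) {
      if (nrow(cur) >= min_members) {
        len <- round_half_up(stats::median(cur$length))
        # enforce the group-length invariant after greedy chaining
        keep <- abs(cur$length - len) <= tolerance
        cur <- cur[keep, , drop = FALSE]
        if (nrow(cur) >= min_members)
          return(structure(list(
            members = data.frame(gene_id = cur$gene_id,
                                 exon_ordinal = cur$ordinal,
                                 anchor = anchor,
                                 stringsAsFactors = FALSE),
            length = len, tolerance = tolerance),
            class = "conserved_exon_group"))
      }
      NULL
    }
    for (r in seq_len(nrow(df))) {
      if (nrow(cur) == 0L || df$length[r] - min(cur$length) <= 2 * tolerance) {
        cur <- rbind(cur, df[r, ])
      } else {
        g <- flush(cur); if (!is.null(g)) groups[[length(groups) + 1L]] <- g
        cur <- df[r, , drop = FALSE]
      }
    }
    g <- flush(cur); if (!is.null(g)) groups[[length(groups) + 1L]] <- g
    groups
  }

  groups <- list()
  for (k in sort(unique(exon_rows$ordinal))) {
    sub <- exon_rows[exon_rows$ordinal == k, , drop = FALSE]
    groups <- c(groups, cluster_lengths(sub, "5p"))
  }
  last <- exon_rows[exon_rows$last, , drop = FALSE]
  groups_3p <- cluster_lengths(last, "3p")

  key <- function(g) paste(sort(paste(g$members$gene_id, g$members$exon_ordinal)),
                           collapse = ";")
  seen <- vapply(groups, key, character(1))
  for (g in groups_3p) if (!key(g) %in% seen) groups[[length(groups) + 1L]] <- g

  ord <- order(-vapply(groups, function(g) nrow(g$members), integer(1)),
               vapply(groups, function(g) g$length, numeric(1)))
  groups[ord]
}

#' @export
print.conserved_exon_group <- function(x, ...) {
  cat(sprintf("conserved exon group: %d nt (+/-%g), %d members [%s-anchored]\n",
              x$length, x$tolerance, nrow(x$members), x$members$anchor[1]))
  invisible(x)
}

#' Write a gene-structure table as TSV
#'
#' Columns: `gene_id`, `n_exons`, comma-joined exon lengths (5'->3'), and the
#' structural class under `p`.
#'
#' @param ann A [genome_annotation()].
#' @param path Output path.
#' @param p [structure_class_params()].
#' @return The table, invisibly.
#' @export
write_structure_table <- function(ann, path, p = structure_class_params()) {
  structs <- exon_structures(ann)
  tab <- data.frame(
    gene_id = vapply(structs, `[[`, character(1), "gene_id"),
    n_exons = vapply(structs, `[[`, integer(1), "n_exons"),
    exon_lengths = vapply(structs, function(s) paste(s$exon_lengths, collapse = ","),
                          character(1)),
    class = vapply(structs, classify_structure, character(1), p = p),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write conserved exon groups as TSV
#'
#' @param groups Result of [conserved_exon_groups()].
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_exon_groups <- function(groups, path) {
  if (!length(groups)) {
    tab <- data.frame(group = integer(0), length = integer(0),
                      tolerance = numeric(0), n_members = integer(0),
                      members = character(0))
  } else {
    tab <- do.call(rbind, lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      data.frame(group = i, length = g$length, tolerance = g$tolerance,
                 n_members = nrow(g$members),
                 members = paste(sprintf("%s:%d:%s", g$members$gene_id,
                                         g$members$exon_ordinal, g$members$anchor),
                                 collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
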