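#' Homology search parameters
#'
#' @param evalue_threshold Significance cutoff: hits with E-value above it are
#'   discarded. Default `1e-5`, a common protein homology screen.
#' @param align [align_params()] for the underlying aligner.
#' @param ev [evalue_params()] for the score statistics.
#' @return A `search_params` object.
#' @export
search_params <- function(evalue_threshold = 1e-5,
                          align = align_params(),
                          ev = evalue_params()) {
  if (!(evalue_threshold > 0)) stop_validation("evalue_threshold must be > 0")
  structure(list(evalue_threshold = evalue_threshold, align = align, ev = ev),
            class = "search_params")
}

as_protein_set <- function(x, what) {
  if (is.character(x)) x <- Biostrings::AAStringSet(toupper(x))
  if (!is(x, "AAStringSet")) stop_validation("%s must be an AAStringSet", what)
  if (length(x) == 0L) stop_validation("%s must be non-empty", what)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop_validation("%s sequences must be named", what)
  S4Vectors::mcols(x) <- NULL  # description columns are irrelevant downstream
  x
}

#' All-vs-all protein homology search
#'
#' Aligns every sequence of `set_a` against every sequence of `set_b` with the
#' exact local aligner and keeps the pairs whose E-value passes the threshold.
#' The search-space size `n` in the E-value is the total residue count of
#' `set_b`, so searching in the two directions gives (slightly) different
#' E-values, as in a database search.
#'
#' @param set_a,set_b Named `AAStringSet`s (or named character vectors).
#' @param p [search_params()].
#' @return A [hit_table()] of all significant pairs.
#' @export
all_vs_all <- function(set_a, set_b, p = search_params()) {
  set_a <- as_protein_set(set_a, "set_a")
  set_b <- as_protein_set(set_b, "set_b")
  n_db <- sum(Biostrings::width(set_b))
  m_q <- Biostrings::width(set_a)
  rows <- list()
  for (j in seq_along(set_b)) {
    scores <- local_scores_vs_subject(set_a, set_b[[j]], p$align)
    ev <- evalue(scores, m_q, n_db, p$ev)
    hit_idx <- which(ev <= p$evalue_threshold)
    for (i in hit_idx) {
      h <- local_align(set_a[i], set_b[j], p$align)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(set_a)[i], subject_id = names(set_b)[j],
        pct_identity = 100 * h$identities / h$aln_length,
        aln_length = h$aln_length, mismatches = h$mismatches,
        gap_opens = h$gap_opens,
        qstart = h$q_span[1], qend = h$q_span[2],
        sstart = h$s_span[1], send = h$s_span[2],
        evalue = ev[i], bitscore = bitscore(h$raw_score, p$ev),
        raw_score = h$raw_score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(hit_table())
  hit_table(do.call(rbind, rows))
}

#' Best hit of a query in a hit table
#'
#' Minimal E-value; ties broken by higher bit score, then lexicographically
#' smallest subject id.
#'
#' @param table A [hit_table()].
#' @param query_id Query identifier.
#' @return One-row `hit_table`, or `NULL` if the query has no hits.
#' @export
best_hit <- function(table, query_id) {
  sub <- table[table$query_id == query_id, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  sub <- sub[order(sub$evalue, -sub$bitscore, sub$subject_id), , drop = FALSE]
  out <- sub[1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two sequence sets
#'
#' A pair is reported iff each member is the other's [best_hit()] in the
#' respective search direction — the standard operational ortholog criterion.
#'
#' @param ab Hit table of the a-vs-b search.
#' @param ba Hit table of the b-vs-a search.
#' @return Data frame with `id_a`, `id_b`, `evalue_ab`, `evalue_ba`, sorted by
#'   `id_a`.
#' @export
reciprocal_best_hits <- function(ab, ba) {
  out <- list()
  for (q in unique(ab$query_id)) {
    f <- best_hit(ab, q)
    r <- best_hit(ba, f$subject_id)
    if (!is.null(r) && identical(r$subject_id, q)) {
      out[[length(out) + 1L]] <- data.frame(
        id_a = q, id_b = f$subject_id,
        evalue_ab = f$evalue, evalue_ba = r$evalue,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id_a = character(0), id_b = character(0),
                      evalue_ab = numeric(0), evalue_ba = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$id_a), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Census of a gene family in a proteome
#'
#' Screens a proteome for members of a seed family by reciprocal homology: a
#' candidate is counted iff its best hit against the seed family is
#' significant and that family member significantly hits the candidate back
#' in the reverse search. Enlarging the E-value threshold can only add
#' members, never remove one that still reciprocates.
#'
#' @param seed_family Named `AAStringSet` of known family members.
#' @param proteome Named `AAStringSet` to screen.
#' @param p [search_params()].
#' @return Sorted character vector of member ids (deduplicated).
#' @export
family_census <- function(seed_family, proteome, p = search_params()) {
  seed_family <- as_protein_set(seed_family, "seed_family")
  proteome <- as_protein_set(proteome, "proteome")
  ab <- all_vs_all(proteome, seed_family, p)   # candidates -> family
  if (!nrow(ab)) return(character(0))
  ba <- all_vs_all(seed_family, proteome, p)   # family -> candidates
  members <- character(0)
  for (cand in unique(ab$query_id)) {
    f <- best_hit(ab, cand)
    back <- ba[ba$query_id == f$subject_id & ba$subject_id == cand, , drop = FALSE]
    if (nrow(back) && any(back$evalue <= p$evalue_threshold))
      members <- c(members, cand)
  }
  sort(unique(members))
}
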