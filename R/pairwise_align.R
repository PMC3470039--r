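#' Alignment parameters
#'
#' Scoring scheme for the exact dynamic-programming protein aligner. A gap of
#' length `k` costs `gap_open + k * gap_extend`, the convention under which
#' the default gapped Karlin–Altschul constants (see [evalue_params()]) were
#' published for BLOSUM62 with open 11 / extend 1.
#'
#' @param substitution_matrix Symmetric named integer matrix; default BLOSUM62.
#' @param gap_open Gap opening penalty (positive integer).
#' @param gap_extend Gap extension penalty per gap column (positive integer).
#' @return An `align_params` object.
#' @export
align_params <- function(substitution_matrix = NULL, gap_open = 11, gap_extend = 1) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  m <- substitution_matrix
  if (!is.matrix(m) || is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop_validation("substitution matrix must be square with matching dimnames")
  if (!isTRUE(all.equal(m, t(m)))) stop_validation("substitution matrix must be symmetric")
  if (!(gap_open >= gap_extend && gap_extend >= 1))
    stop_validation("need gap_open >= gap_extend >= 1 (got %s, %s)", gap_open, gap_extend)
  structure(list(substitution_matrix = m,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_params")
}

# BLOSUM62 as shipped with Biostrings, cached per session.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Load a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited matrix files distributed with BLAST
#' (`#`-prefixed comment lines, a header row of residue letters, one labelled
#' row per residue).
#'
#' @param path Path to the matrix file.
#' @return Named integer matrix.
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_format("not a substitution matrix: %s", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  labs <- vapply(body, `[`, character(1), 1)
  vals <- lapply(body, function(x) as.integer(x[-1]))
  if (any(lengths(vals) != length(header)))
    stop_format("ragged matrix rows in %s", path)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labs, header)
  m
}

#' Karlin–Altschul E-value parameters
#'
#' Statistical constants for converting raw alignment scores to E-values and
#' bit scores via `E = K * m * n * exp(-lambda * S)`. Defaults are the
#' published gapped constants for BLOSUM62 with gap costs 11/1.
#'
#' @param lambda Scale parameter (per score unit), strictly positive.
#' @param K Search-space correction constant, strictly positive.
#' @return An `evalue_params` object.
#' @export
evalue_params <- function(lambda = 0.267, K = 0.041) {
  if (!(lambda > 0) || !(K > 0)) stop_validation("lambda and K must be > 0")
  structure(list(lambda = lambda, K = K), class = "evalue_params")
}

#' Expected number of chance hits at a score
#'
#' @param raw_score Raw alignment score `S`.
#' @param m Query length in residues (>= 1).
#' @param n Search-space size: total residue count of the searched set (>= 1).
#' @param ev [evalue_params()].
#' @return The E-value `K * m * n * exp(-lambda * S)`.
#' @export
evalue <- function(raw_score, m, n, ev = evalue_params()) {
  if (any(m < 1) || any(n < 1)) stop_validation("m and n must be >= 1")
  ev$K * as.numeric(m) * as.numeric(n) * exp(-ev$lambda * raw_score)
}

#' Bit score of a raw alignment score
#'
#' Defined so that `E = m * n * 2^(-bitscore)` is consistent with [evalue()].
#'
#' @inheritParams evalue
#' @return Bit score `(lambda * S - ln K) / ln 2`.
#' @export
bitscore <- function(raw_score, ev = evalue_params()) {
  (ev$lambda * raw_score - log(ev$K)) / log(2)
}

as_aa_string <- function(x, what) {
  if (is(x, "AAString")) return(x)
  if (is(x, "AAStringSet")) {
    if (length(x) != 1L) stop_validation("%s must be a single sequence", what)
    return(x[[1]])
  }
  if (is.character(x) && length(x) == 1L) return(Biostrings::AAString(toupper(x)))
  stop_validation("%s must be a single protein sequence", what)
}

seq_id_of <- function(x, default) {
  nm <- names(x)
  if (!is.null(nm) && length(nm) >= 1L && nzchar(nm[1])) nm[1] else default
}

# Shared post-processing of one Biostrings pairwise alignment: identity and
# gap accounting over the aligned strings. X never counts as an identity.
alignment_stats <- function(aln_q, aln_s) {
  q <- strsplit(aln_q, "", fixed = TRUE)[[1]]
  s <- strsplit(aln_s, "", fixed = TRUE)[[1]]
  both_res <- q != "-" & s != "-"
  identities <- sum(both_res & q == s & q != "X")
  mismatches <- sum(both_res) - sum(both_res & q == s)
  gap_opens <- sum(rle(q)$values == "-") + sum(rle(s)$values == "-")
  list(identities = identities, mismatches = mismatches,
       gap_opens = gap_opens, aln_length = length(q))
}

pairwise_core <- function(a, b, params, type) {
  qa <- as_aa_string(a, "a"); qb <- as_aa_string(b, "b")
  if (length(qa) == 0L || length(qb) == 0L)
    stop_validation("sequences must be non-empty")
  p <- Biostrings::pairwiseAlignment(
    qa, qb, type = type,
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pat <- Biostrings::pattern(p)
  sub <- Biostrings::subject(p)
  st <- alignment_stats(as.character(pat), as.character(sub))
  structure(list(
    query_id = seq_id_of(a, "query"),
    subject_id = seq_id_of(b, "subject"),
    raw_score = score(p),
    identities = st$identities,
    mismatches = st$mismatches,
    gap_opens = st$gap_opens,
    aln_length = st$aln_length,
    q_span = c(IRanges::start(pat), IRanges::end(pat)),
    s_span = c(IRanges::start(sub), IRanges::end(sub)),
    type = type
  ), class = "homology_hit")
}

#' Optimal local protein alignment (Smith–Waterman, affine gaps)
#'
#' Exact dynamic-programming local alignment under [align_params()]. Used as
#' the internal homology engine wherever a heuristic protein search would
#' otherwise be run: the gene windows compared here are small enough that the
#' exact optimum is affordable and fully deterministic.
#'
#' @param a,b Single protein sequences (character, `AAString`, or length-1
#'   `AAStringSet`); names supply the hit's query/subject ids.
#' @param params [align_params()].
#' @return A `homology_hit`: raw score, identity count (positions with equal
#'   non-`X` residues), mismatches, gap opens, alignment length, and 1-based
#'   query/subject spans.
#' @export
local_align <- function(a, b, params = align_params()) {
  pairwise_core(a, b, params, "local")
}

#' Optimal global protein alignment (Needleman–Wunsch, affine gaps)
#'
#' End gaps are penalized; `aln_length` is the number of alignment columns.
#'
#' @inheritParams local_align
#' @return A `homology_hit` (see [local_align()]).
#' @export
global_align <- function(a, b, params = align_params()) {
  pairwise_core(a, b, params, "global")
}

#' @export
print.homology_hit <- function(x, ...) {
  cat(sprintf("%s alignment %s vs %s: score %g, %d/%d identities\n",
              x$type, x$query_id, x$subject_id, x$raw_score,
              x$identities, x$aln_length))
  invisible(x)
}

# Vectorized local alignment scores of many queries against one subject.
# Returns only scores; full per-pair statistics are recomputed lazily for
# pairs that pass the significance threshold.
local_scores_vs_subject <- function(queries, subject, params) {
  p <- Biostrings::pairwiseAlignment(
    queries, subject, type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  p
}
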