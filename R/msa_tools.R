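#' Column filter parameters
#'
#' @param min_coverage Minimum site coverage in `[0, 1]`: the fraction of
#'   sequences that must carry a residue (non-gap; `X` counts as a residue)
#'   at a column for it to be kept. `0.8` is the common "eliminate positions
#'   with less than 80% site coverage" pre-phylogenetics filter; `0` keeps
#'   every column (coverage is always `>= 0`).
#' @return A `filter_params` object.
#' @export
filter_params <- function(min_coverage = 0.8) {
  if (!(min_coverage >= 0 && min_coverage <= 1))
    stop_validation("min_coverage must be in [0, 1]")
  structure(list(min_coverage = min_coverage), class = "filter_params")
}

#' Site coverage of an alignment column
#'
#' @param x An [msa()].
#' @param col Column index (1-based).
#' @return Fraction of rows with a non-gap character at the column.
#' @export
column_coverage <- function(x, col) {
  if (any(col < 1L | col > n_columns(x)))
    stop_validation("column index out of range (1..%d)", n_columns(x))
  colMeans(x$mat[, col, drop = FALSE] != "-")
}

#' Filter alignment columns by site coverage
#'
#' Keeps exactly the columns whose coverage is at least `min_coverage`,
#' preserving order. Applying the filter twice gives the same result as
#' applying it once.
#'
#' @param x An [msa()].
#' @param p [filter_params()].
#' @return List with `msa` (the filtered alignment) and `kept` (1-based
#'   indices of retained columns in the input).
#' @export
filter_columns <- function(x, p = filter_params()) {
  cov <- colMeans(x$mat != "-")
  kept <- which(cov >= p$min_coverage)
  if (!length(kept))
    stop_validation("no columns left at min_coverage = %g", p$min_coverage)
  out <- x
  out$mat <- x$mat[, kept, drop = FALSE]
  list(msa = out, kept = kept)
}

IDENTITY_MODES <- c("pair_columns", "msa_length", "min_seq_length", "aligned_pairs")

#' Percent identity of two aligned sequences
#'
#' Identities are columns where both rows carry the same non-`X` residue.
#' The denominator is selectable because "length of the alignment" is
#' ambiguous for a pair embedded in a multiple alignment:
#' * `pair_columns` (default): columns where at least one of the two rows is
#'   non-gap — mutual-gap columns, which belong to other sequences, are
#'   excluded;
#' * `msa_length`: all alignment columns;
#' * `min_seq_length`: the shorter ungapped sequence length;
#' * `aligned_pairs`: columns where both rows are non-gap.
#'
#' @param x An [msa()].
#' @param id_i,id_j Sequence ids.
#' @param mode Denominator convention (see above).
#' @return Percent identity in `[0, 100]`, full precision (round for
#'   presentation with [round_half_up()] semantics via [identity_matrix()]
#'   exports).
#' @export
pairwise_identity <- function(x, id_i, id_j, mode = "pair_columns") {
  mode <- match.arg(mode, IDENTITY_MODES)
  ri <- match(id_i, x$ids); rj <- match(id_j, x$ids)
  if (is.na(ri)) stop_lookup("unknown sequence id: %s", id_i)
  if (is.na(rj)) stop_lookup("unknown sequence id: %s", id_j)
  a <- x$mat[ri, ]; b <- x$mat[rj, ]
  both <- a != "-" & b != "-"
  idents <- sum(both & a == b & a != "X")
  denom <- switch(mode,
    pair_columns   = sum(a != "-" | b != "-"),
    msa_length     = length(a),
    min_seq_length = min(sum(a != "-"), sum(b != "-")),
    aligned_pairs  = sum(both))
  if (denom == 0) return(0)
  100 * idents / denom
}

#' Pairwise percent-identity matrix of an alignment
#'
#' @param x An [msa()] with at least two sequences.
#' @param mode Denominator convention, see [pairwise_identity()].
#' @return An `identity_matrix`: symmetric numeric matrix (diagonal 100) with
#'   the ids as dimnames and the mode recorded as an attribute. Values are
#'   full precision; [write_identity_matrix()] and the print method round
#'   half-up to integers for presentation.
#' @export
identity_matrix <- function(x, mode = "pair_columns") {
  mode <- match.arg(mode, IDENTITY_MODES)
  n <- length(x$ids)
  if (n < 2L) stop_validation("need at least two sequences")
  m <- matrix(100, n, n, dimnames = list(x$ids, x$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- pairwise_identity(x, x$ids[i], x$ids[j], mode)
    m[i, j] <- v; m[j, i] <- v
  }
  structure(m, mode = mode, class = c("identity_matrix", class(m)))
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("identity_matrix (mode: %s), percent identity rounded to integers\n",
              attr(x, "mode")))
  print(matrix(round_half_up(unclass(x)), nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Write an identity matrix as TSV
#'
#' Ids as header row and first column; values rounded half-up to integer
#' percent, matching the usual presentation of such tables.
#'
#' @param m An [identity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(m, path) {
  out <- data.frame(id = rownames(m),
                    matrix(round_half_up(unclass(m)), nrow(m),
                           dimnames = list(NULL, colnames(m))),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write kept-column indices as TSV (0-based)
#'
#' @param kept 1-based column indices as returned by [filter_columns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kept_columns <- function(kept, path) {
  write.table(data.frame(column = kept - 1L), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
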