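#' Collinearity detection parameters
#'
#' Controls the windowed gene-neighborhood comparison: a window of
#' `window_size` genes around each anchor (up to `window_size / 2` per side
#' plus the anchor itself, truncated at chromosome ends), an E-value homology
#' matrix between two windows, and diagonal chaining of matrix hits.
#' "High diagonal homology" is made operational as chain-length thresholds:
#' a chained block needs `min_block_hits` hits to count at all and
#' `high_block_hits` for a *high* call, with consecutive chained hits at most
#' `max_chain_gap` gene positions apart on both axes. Thresholds are
#' configurable and are reported with every call.
#'
#' @param window_size Number of surrounding genes compared per anchor
#'   (default 200).
#' @param evalue_threshold Significance cutoff for matrix cells (default 1e-5).
#' @param max_chain_gap Maximum ordinal distance between consecutive chained
#'   hits on either axis (default 5).
#' @param min_block_hits Minimum chained hits for a reported block (default 3).
#' @param high_block_hits Minimum best-block hits for a *high* verdict
#'   (default 10).
#' @param allow_inversions Also chain anti-diagonals (default `TRUE`):
#'   inversions are common after duplication.
#' @param score_cap Cap for `-log10(E)` cell values; `E = 0` maps to the cap
#'   (default 200).
#' @return A `collinearity_params` object.
#' @export
collinearity_params <- function(window_size = 200, evalue_threshold = 1e-5,
                                max_chain_gap = 5, min_block_hits = 3,
                                high_block_hits = 10, allow_inversions = TRUE,
                                score_cap = 200) {
  if (window_size < 2) stop_validation("window_size must be >= 2")
  if (!(evalue_threshold > 0)) stop_validation("evalue_threshold must be > 0")
  if (max_chain_gap < 1) stop_validation("max_chain_gap must be >= 1")
  if (min_block_hits < 2) stop_validation("min_block_hits must be >= 2")
  if (high_block_hits < min_block_hits)
    stop_validation("high_block_hits must be >= min_block_hits")
  if (!(score_cap > 0)) stop_validation("score_cap must be > 0")
  structure(list(window_size = as.integer(window_size),
                 evalue_threshold = evalue_threshold,
                 max_chain_gap = as.integer(max_chain_gap),
                 min_block_hits = as.integer(min_block_hits),
                 high_block_hits = as.integer(high_block_hits),
                 allow_inversions = isTRUE(allow_inversions),
                 score_cap = score_cap),
            class = "collinearity_params")
}

#' Extract the gene window around an anchor
#'
#' Up to `window_size / 2` genes on each side of the anchor in chromosomal
#' order, truncated at chromosome ends (truncation is recorded in
#' `realized_size`, not padded). The anchor sits at offset 0.
#'
#' @param ann A [genome_annotation()].
#' @param anchor_id Anchor gene id.
#' @param p [collinearity_params()].
#' @return A `gene_window`: `anchor_id`, `chromosome`, `members` (data frame
#'   `offset`, `gene_id`, `protein_id`), `realized_size`.
#' @export
extract_window <- function(ann, anchor_id, p = collinearity_params()) {
  pos <- gene_position(ann, anchor_id)
  side <- p$window_size %/% 2L
  chr_genes <- ann$genes[ann$genes$chromosome == pos$chromosome, , drop = FALSE]
  chr_genes <- chr_genes[order(chr_genes$ordinal), , drop = FALSE]
  keep <- abs(chr_genes$ordinal - pos$ordinal) <= side
  mem <- chr_genes[keep, , drop = FALSE]
  structure(list(anchor_id = anchor_id,
                 chromosome = pos$chromosome,
                 members = data.frame(offset = mem$ordinal - pos$ordinal,
                                      gene_id = mem$gene_id,
                                      protein_id = mem$protein_id,
                                      stringsAsFactors = FALSE),
                 realized_size = nrow(mem)),
            class = "gene_window")
}

#' @export
print.gene_window <- function(x, ...) {
  cat(sprintf("gene_window around %s (%s): %d genes, offsets %d..%d\n",
              x$anchor_id, x$chromosome, x$realized_size,
              min(x$members$offset), max(x$members$offset)))
  invisible(x)
}

#' Homology matrix between two gene windows
#'
#' One cell per significant hit between window members: cell `(i, j)` is
#' present iff the hit of gene `i` (rows, window A) against gene `j`
#' (columns, window B) has `E <= evalue_threshold`; its value is
#' `min(-log10 E, score_cap)` (`E = 0` maps to the cap).
#'
#' @param win_a,win_b [extract_window()] results.
#' @param hits A [hit_table()] over the member proteins (query = window A
#'   protein, subject = window B protein), e.g. from [all_vs_all()].
#' @param p [collinearity_params()].
#' @return A `homology_matrix`: `row_ids`/`col_ids` (gene ids),
#'   `row_offsets`/`col_offsets`, and `cells` (data frame `i`, `j`, `value`,
#'   1-based indices).
#' @export
window_matrix <- function(win_a, win_b, hits, p = collinearity_params()) {
  prot2row <- setNames(seq_len(nrow(win_a$members)), win_a$members$protein_id)
  prot2col <- setNames(seq_len(nrow(win_b$members)), win_b$members$protein_id)
  h <- hits[hits$evalue <= p$evalue_threshold &
              hits$query_id %in% names(prot2row) &
              hits$subject_id %in% names(prot2col), , drop = FALSE]
  cells <- data.frame(i = unname(prot2row[h$query_id]),
                      j = unname(prot2col[h$subject_id]),
                      value = pmin(ifelse(h$evalue == 0, Inf, -log10(h$evalue)),
                                   p$score_cap))
  # one cell per gene pair: keep the strongest hit
  if (nrow(cells)) {
    cells <- cells[order(cells$i, cells$j, -cells$value), , drop = FALSE]
    cells <- cells[!duplicated(cells[c("i", "j")]), , drop = FALSE]
    rownames(cells) <- NULL
  }
  structure(list(row_ids = win_a$members$gene_id,
                 col_ids = win_b$members$gene_id,
                 row_offsets = win_a$members$offset,
                 col_offsets = win_b$members$offset,
                 cells = cells),
            class = "homology_matrix")
}

#' Chain diagonal runs of homology-matrix hits into collinear blocks
#'
#' Sparse dynamic programming over the matrix cells: a hit extends a chain if
#' both index deltas lie in `[1, max_chain_gap]` with consistent orientation
#' (column indices increasing for *forward* chains, decreasing for *inverted*
#' ones when `allow_inversions`). The maximal-score chain is reported, its
#' hits are removed, and the search repeats, so each hit belongs to at most
#' one block (greedy by score). Blocks with at least `min_block_hits` hits
#' are returned, sorted by score descending.
#'
#' @param mat A [window_matrix()].
#' @param p [collinearity_params()].
#' @return List of `collinear_block`s: `pairs` (two-column matrix of `i`,`j`
#'   by increasing row), `orientation`, `n_hits`, `span_rows`, `span_cols`,
#'   `score`.
#' @export
chain_diagonals <- function(mat, p = collinearity_params()) {
  cells <- mat$cells
  blocks <- list()
  orientations <- c("forward", if (p$allow_inversions) "inverted")
  repeat {
    if (is.null(cells) || nrow(cells) < p$min_block_hits) break
    best <- NULL
    for (orient in orientations) {
      ch <- best_chain_dp(cells, p$max_chain_gap, orient)
      if (!is.null(ch) && (is.null(best) || ch$score > best$score)) best <- ch
    }
    if (is.null(best) || best$n_hits < p$min_block_hits) break
    blocks[[length(blocks) + 1L]] <- structure(
      list(pairs = best$pairs, orientation = best$orientation,
           n_hits = best$n_hits,
           span_rows = range(best$pairs[, 1]),
           span_cols = range(best$pairs[, 2]),
           score = best$score),
      class = "collinear_block")
    used <- paste(best$pairs[, 1], best$pairs[, 2])
    cells <- cells[!(paste(cells$i, cells$j) %in% used), , drop = FALSE]
  }
  ord <- order(-vapply(blocks, `[[`, numeric(1), "score"))
  blocks[ord]
}

# Maximal-score chain under the gap/orientation constraints, by sparse DP.
# Deterministic: cells are processed in (i, j) order and ties keep the first
# (lowest-coordinate) optimum.
best_chain_dp <- function(cells, max_gap, orientation) {
  if (!nrow(cells)) return(NULL)
  o <- order(cells$i, cells$j)
  ci <- cells$i[o]; cj <- cells$j[o]; cv <- cells$value[o]
  n <- length(ci)
  dp <- cv
  parent <- rep(NA_integer_, n)
  for (h in seq_len(n)) {
    di <- ci[h] - ci
    dj <- if (orientation == "forward") cj[h] - cj else cj - cj[h]
    pred <- which(di >= 1 & di <= max_gap & dj >= 1 & dj <= max_gap)
    if (length(pred)) {
      b <- pred[which.max(dp[pred])]
      if (dp[b] > 0) { dp[h] <- cv[h] + dp[b]; parent[h] <- b }
    }
  }
  top <- which.max(dp)
  chain <- integer(0)
  k <- top
  while (!is.na(k)) { chain <- c(k, chain); k <- parent[k] }
  pairs <- cbind(i = ci[chain], j = cj[chain])
  list(pairs = pairs, orientation = orientation, n_hits = nrow(pairs),
       score = dp[top])
}

#' @export
print.collinear_block <- function(x, ...) {
  cat(sprintf("collinear_block: %d hits (%s), rows %d..%d, cols %d..%d, score %.1f\n",
              x$n_hits, x$orientation, x$span_rows[1], x$span_rows[2],
              x$span_cols[1], x$span_cols[2], x$score))
  invisible(x)
}

#' Verdict for a pair of gene windows
#'
#' *high* iff the best block (highest score) has at least `high_block_hits`
#' hits; *weak* iff it has at least `min_block_hits` but fewer than
#' `high_block_hits`; *none* otherwise. A lone anchor-vs-anchor hit can never
#' produce a block (`min_block_hits >= 2`), so family homology of the anchors
#' alone is not collinearity.
#'
#' @param blocks Result of [chain_diagonals()].
#' @param p [collinearity_params()].
#' @param anchor_a,anchor_b Anchor ids recorded in the call.
#' @return A `collinearity_call`: `anchor_a`, `anchor_b`, `verdict`,
#'   `best_block` (or `NULL`), `n_blocks`, `params`.
#' @export
classify <- function(blocks, p = collinearity_params(),
                     anchor_a = NA_character_, anchor_b = NA_character_) {
  best <- if (length(blocks)) blocks[[1]] else NULL
  verdict <- if (is.null(best) || best$n_hits < p$min_block_hits) "none"
    else if (best$n_hits >= p$high_block_hits) "high"
    else "weak"
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b, verdict = verdict,
                 best_block = best, n_blocks = length(blocks), params = p),
            class = "collinearity_call")
}

#' @export
print.collinearity_call <- function(x, ...) {
  nh <- if (is.null(x$best_block)) 0L else x$best_block$n_hits
  cat(sprintf("collinearity %s vs %s: %s (%d blocks, best %d hits)\n",
              x$anchor_a, x$anchor_b, x$verdict, x$n_blocks, nh))
  invisible(x)
}

resolve_anchor <- function(anchor, ann_a, ann_b) {
  hit_a <- anchor %in% ann_a$genes$gene_id
  if (hit_a) return(list(ann = ann_a, which = "a"))
  if (!is.null(ann_b) && anchor %in% ann_b$genes$gene_id)
    return(list(ann = ann_b, which = "b"))
  stop_lookup("unknown anchor id: %s", anchor)
}

#' Collinearity scan over anchor pairs
#'
#' For every unordered pair of anchors: extract the two gene windows, compute
#' (or subset) the homology hits between their member proteins, build the
#' E-value matrix, chain diagonals, and classify. Anchors may all live in one
#' genome (paralog mode) or in two genomes.
#'
#' @param ann A [genome_annotation()].
#' @param proteome Named `AAStringSet` supplying the window member proteins
#'   (names = protein ids of the annotation).
#' @param anchors Character vector of at least two anchor gene ids.
#' @param p [collinearity_params()].
#' @param ann_b,proteome_b Optional second genome for cross-species scans;
#'   anchors are looked up in both annotations.
#' @param hits Optional precomputed [hit_table()] (e.g. imported external
#'   search results); when `NULL`, hits are computed per window pair with
#'   [all_vs_all()].
#' @return List of per-pair results, each with the `call`
#'   ([classify()] result), `matrix` ([window_matrix()]), and `blocks`.
#' @export
collinearity_scan <- function(ann, proteome, anchors, p = collinearity_params(),
                              ann_b = NULL, proteome_b = NULL, hits = NULL) {
  if (length(anchors) < 2L) stop_validation("need at least two anchors")
  proteome <- as_protein_set(proteome, "proteome")
  if (!is.null(proteome_b)) proteome_b <- as_protein_set(proteome_b, "proteome_b")
  get_prots <- function(win, which) {
    src <- if (which == "b" && !is.null(proteome_b)) proteome_b else proteome
    missing <- setdiff(win$members$protein_id, names(src))
    if (length(missing))
      stop_validation("no protein for window member(s): %s",
                      paste(head(missing, 5), collapse = ", "))
    src[win$members$protein_id]
  }
  sp <- search_params(evalue_threshold = p$evalue_threshold)
  out <- list()
  combs <- utils::combn(length(anchors), 2)
  for (k in seq_len(ncol(combs))) {
    a <- anchors[combs[1, k]]; b <- anchors[combs[2, k]]
    ra <- resolve_anchor(a, ann, ann_b); rb <- resolve_anchor(b, ann, ann_b)
    win_a <- extract_window(ra$ann, a, p)
    win_b <- extract_window(rb$ann, b, p)
    pair_hits <- if (is.null(hits))
      all_vs_all(get_prots(win_a, ra$which), get_prots(win_b, rb$which), sp)
    else hits
    mat <- window_matrix(win_a, win_b, pair_hits, p)
    blocks <- chain_diagonals(mat, p)
    out[[k]] <- list(call = classify(blocks, p, a, b), matrix = mat,
                     blocks = blocks)
  }
  out
}

#' Write a homology matrix as a dot-plot TSV
#'
#' Dense matrix of capped `-log10(E)` values (0 where no significant hit);
#' rows/columns labelled by window offsets and gene ids.
#'
#' @param mat A [window_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dotplot <- function(mat, path) {
  dense <- matrix(0, length(mat$row_ids), length(mat$col_ids))
  if (nrow(mat$cells))
    dense[cbind(mat$cells$i, mat$cells$j)] <- mat$cells$value
  rownames(dense) <- sprintf("%s@%+d", mat$row_ids, mat$row_offsets)
  colnames(dense) <- sprintf("%s@%+d", mat$col_ids, mat$col_offsets)
  out <- data.frame(row = rownames(dense), dense, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a collinearity calls summary as TSV
#'
#' @param scan Result of [collinearity_scan()].
#' @param path Output path.
#' @return The summary table, invisibly.
#' @export
write_calls <- function(scan, path) {
  tab <- do.call(rbind, lapply(scan, function(r) {
    cl <- r$call
    bb <- cl$best_block
    data.frame(anchor_a = cl$anchor_a, anchor_b = cl$anchor_b,
               verdict = cl$verdict,
               n_hits = if (is.null(bb)) 0L else bb$n_hits,
               score = if (is.null(bb)) 0 else bb$score,
               orientation = if (is.null(bb)) NA_character_ else bb$orientation,
               n_blocks = cl$n_blocks,
               stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
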