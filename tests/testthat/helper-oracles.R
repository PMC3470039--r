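# Independent brute-force oracles. These enumerate full solution spaces and
# share no code with the package implementation.

# All global alignments of a and b, enumerated as explicit column paths with
# affine gap costs (gap of length k costs open + k * extend). Returns the
# maximum score over every alignment.
brute_global_score <- function(a, b, mat, open, extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- mat[av[i], bv[j]] + rec(i + 1, j + 1, "M")
      best <- max(best, s)
    }
    if (i <= length(av)) {  # gap in b, consumes a[i]
      cost <- if (identical(prev, "A")) extend else open + extend
      best <- max(best, rec(i + 1, j, "A") - cost)
    }
    if (j <= length(bv)) {  # gap in a, consumes b[j]
      cost <- if (identical(prev, "B")) extend else open + extend
      best <- max(best, rec(i, j + 1, "B") - cost)
    }
    best
  }
  if (length(av) == 0 || length(bv) == 0) stop("empty sequence")
  rec(1, 1, "none")
}

# Local score: best global score over all substring pairs, floored at 0 (the
# empty local alignment).
brute_local_score <- function(a, b, mat, open, extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av))
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv)) {
      s <- brute_global_score(paste(av[i1:i2], collapse = ""),
                              paste(bv[j1:j2], collapse = ""),
                              mat, open, extend)
      best <- max(best, s)
    }
  best
}

# Exhaustive chain search over homology-matrix cells: every subset of cells
# forming a valid chain (row indices strictly increasing, column indices
# strictly increasing for forward / decreasing for inverted, consecutive
# deltas within max_gap on both axes) is explored by DFS; returns the best
# total cell-value sum, or 0 if there are no cells.
brute_best_chain_score <- function(cells, max_gap, orientations = c("forward", "inverted")) {
  if (nrow(cells) == 0) return(0)
  best <- 0
  n <- nrow(cells)
  for (orient in orientations) {
    extend_ok <- function(p, h) {
      di <- cells$i[h] - cells$i[p]
      dj <- if (orient == "forward") cells$j[h] - cells$j[p] else cells$j[p] - cells$j[h]
      di >= 1 && di <= max_gap && dj >= 1 && dj <= max_gap
    }
    dfs <- function(last, total) {
      best <<- max(best, total)
      for (h in seq_len(n)) if (extend_ok(last, h)) dfs(h, total + cells$value[h])
    }
    for (s in seq_len(n)) dfs(s, cells$value[s])
  }
  best
}

# Chain length (hit count) of the best-scoring chain, via the same DFS.
brute_best_chain <- function(cells, max_gap, orientations = c("forward", "inverted")) {
  if (nrow(cells) == 0) return(list(score = 0, n_hits = 0))
  best <- list(score = 0, n_hits = 0)
  n <- nrow(cells)
  for (orient in orientations) {
    extend_ok <- function(p, h) {
      di <- cells$i[h] - cells$i[p]
      dj <- if (orient == "forward") cells$j[h] - cells$j[p] else cells$j[p] - cells$j[h]
      di >= 1 && di <= max_gap && dj >= 1 && dj <= max_gap
    }
    dfs <- function(last, total, len) {
      if (total > best$score) best <<- list(score = total, n_hits = len)
      for (h in seq_len(n)) if (extend_ok(last, h)) dfs(h, total + cells$value[h], len + 1)
    }
    for (s in seq_len(n)) dfs(s, cells$value[s], 1)
  }
  best
}

random_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
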