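diag_matrix <- function(cells, nrow = 20, ncol = 20) {
  structure(list(row_ids = sprintf("r%d", seq_len(nrow)),
                 col_ids = sprintf("c%d", seq_len(ncol)),
                 row_offsets = seq_len(nrow) - 1L,
                 col_offsets = seq_len(ncol) - 1L,
                 cells = cells),
            class = "homology_matrix")
}

test_that("windows center on the anchor and truncate at chromosome ends", {
  ann <- toy_annotation(n = 400)
  w <- extract_window(ann, "g151", collinearity_params(window_size = 200))
  expect_equal(range(w$members$offset), c(-100, 100))
  expect_equal(w$realized_size, 201)
  expect_equal(w$members$gene_id[w$members$offset == 0], "g151")

  ann10 <- toy_annotation(n = 10)
  w2 <- extract_window(ann10, "g04", collinearity_params(window_size = 200))
  expect_equal(w2$realized_size, 10)
  expect_error(extract_window(ann10, "nope"), class = "syntrace_lookup_error")
})

test_that("window matrices hold capped -log10 E-values for passing hits only", {
  ann <- toy_annotation(n = 4)
  w <- extract_window(ann, "g02", collinearity_params(window_size = 4))
  hits <- hit_table(data.frame(
    query_id = c("g01", "g02", "g03"), subject_id = c("g01", "g02", "g04"),
    pct_identity = 90, aln_length = 100, mismatches = 10, gap_opens = 0,
    qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = c(1e-30, 1e-3, 0), bitscore = 100))
  p <- collinearity_params(window_size = 4, evalue_threshold = 1e-5, score_cap = 200)
  m <- window_matrix(w, w, hits, p)
  expect_equal(nrow(m$cells), 2)  # the 1e-3 hit fails the threshold
  expect_equal(m$cells$value[m$cells$i == 1], 30)
  expect_equal(m$cells$value[m$cells$i == 3], 200)  # E = 0 maps to the cap

  empty <- window_matrix(w, w, hit_table(), p)
  expect_equal(nrow(empty$cells), 0)
  expect_equal(length(chain_diagonals(empty, p)), 0)
})

test_that("perfect diagonals chain into single forward or inverted blocks", {
  p <- collinearity_params(window_size = 20)
  fwd <- diag_matrix(data.frame(i = 1:10, j = 1:10, value = 50))
  b <- chain_diagonals(fwd, p)
  expect_length(b, 1)
  expect_equal(b[[1]]$n_hits, 10)
  expect_equal(b[[1]]$orientation, "forward")
  expect_equal(b[[1]]$score, 500)

  inv <- diag_matrix(data.frame(i = 1:10, j = 10:1, value = 50))
  bi <- chain_diagonals(inv, p)
  expect_length(bi, 1)
  expect_equal(bi[[1]]$orientation, "inverted")
  expect_equal(bi[[1]]$n_hits, 10)

  no_inv <- chain_diagonals(inv, collinearity_params(allow_inversions = FALSE))
  expect_length(no_inv, 0)
})

test_that("chained best-block scores equal exhaustive chain enumeration", {
  set.seed(33)
  p <- collinearity_params(window_size = 8, max_chain_gap = 3, min_block_hits = 2)
  for (rep in 1:30) {
    n_hits <- sample(3:12, 1)
    cells <- unique(data.frame(i = sample(1:8, n_hits, TRUE),
                               j = sample(1:8, n_hits, TRUE)))
    cells$value <- round(runif(nrow(cells), 1, 60), 1)
    m <- diag_matrix(cells, 8, 8)
    blocks <- chain_diagonals(m, p)
    oracle <- brute_best_chain(cells, p$max_chain_gap)
    got <- if (length(blocks)) blocks[[1]]$score else NA
    if (oracle$n_hits >= p$min_block_hits) {
      expect_equal(blocks[[1]]$score, oracle$score, tolerance = 1e-9,
                   info = sprintf("rep %d", rep))
    } else if (length(blocks)) {
      # implementation may only report blocks meeting the hit minimum
      expect_gte(oracle$score, blocks[[1]]$score)
    }
  }
})

test_that("verdicts follow the block-size thresholds", {
  p <- collinearity_params()
  mk <- function(n) diag_matrix(data.frame(i = 1:n, j = 1:n, value = 30))
  expect_equal(classify(chain_diagonals(mk(10), p), p)$verdict, "high")
  expect_equal(classify(chain_diagonals(mk(4), p), p)$verdict, "weak")
  expect_equal(classify(list(), p)$verdict, "none")
  # a lone anchor-anchor hit is never collinearity
  lone <- diag_matrix(data.frame(i = 5, j = 5, value = 200))
  expect_equal(classify(chain_diagonals(lone, p), p)$verdict, "none")
})

test_that("scan verdicts are symmetric with a transposed matrix", {
  spec <- simulation_spec(seed = 41, n_genes = 30, n_chromosomes = 1,
    protein_length = c(120, 200), family_size = 0,
    events = list(sim_event("segmental_duplication", "chr1", c(5, 24),
                            divergence = 0.2, gene_loss = 0.1)))
  sim <- simulate_genome(spec)
  tp <- sim$truth$ortholog_pairs
  mid <- ceiling(nrow(tp) / 2)
  a <- tp$id_a[mid]; b <- tp$id_b[mid]
  p <- collinearity_params(window_size = 40)
  s1 <- collinearity_scan(sim$annotation, sim$proteome, c(a, b), p)
  s2 <- collinearity_scan(sim$annotation, sim$proteome, c(b, a), p)
  expect_equal(s1[[1]]$call$verdict, s2[[1]]$call$verdict)
  m1 <- s1[[1]]$matrix$cells
  m2 <- s2[[1]]$matrix$cells
  expect_setequal(paste(m1$i, m1$j), paste(m2$j, m2$i))
})

test_that("a stricter E-value threshold never increases best-block size", {
  spec <- simulation_spec(seed = 42, n_genes = 30, n_chromosomes = 1,
    protein_length = c(120, 200), family_size = 0,
    events = list(sim_event("segmental_duplication", "chr1", c(5, 24),
                            divergence = 0.3, gene_loss = 0.1)))
  sim <- simulate_genome(spec)
  tp <- sim$truth$ortholog_pairs
  a <- tp$id_a[3]; b <- tp$id_b[3]
  prev <- Inf
  for (thr in c(1e-5, 1e-30, 1e-60, 1e-120)) {
    p <- collinearity_params(window_size = 40, evalue_threshold = thr)
    s <- collinearity_scan(sim$annotation, sim$proteome, c(a, b), p)
    nh <- if (is.null(s[[1]]$call$best_block)) 0 else s[[1]]$call$best_block$n_hits
    expect_lte(nh, prev)
    prev <- nh
  }
})

test_that("a tandem-duplicated segment is called high; shuffled anchors are not", {
  spec <- simulation_spec(seed = 43, n_genes = 40, n_chromosomes = 2,
    protein_length = c(120, 200), family_size = 0,
    events = list(sim_event("tandem_duplication", "chr1", c(10, 21),
                            divergence = 0.1)))
  sim <- simulate_genome(spec)
  tp <- sim$truth$ortholog_pairs
  a <- tp$id_a[6]; b <- tp$id_b[6]
  p <- collinearity_params(window_size = 30)
  s <- collinearity_scan(sim$annotation, sim$proteome, c(a, b), p)
  expect_equal(s[[1]]$call$verdict, "high")

  # an anchor on the untouched, unrelated chromosome shows nothing
  s2 <- collinearity_scan(sim$annotation, sim$proteome, c(a, "chr2g020"), p)
  expect_equal(s2[[1]]$call$verdict, "none")
})

test_that("scans over k anchors produce choose(k, 2) calls and valid exports", {
  spec <- simulation_spec(seed = 44, n_genes = 25, n_chromosomes = 2,
                          protein_length = c(100, 160), family_size = 4)
  sim <- simulate_genome(spec)
  p <- collinearity_params(window_size = 10)
  scan <- collinearity_scan(sim$annotation, sim$proteome,
                            sim$truth$family_members, p)
  expect_length(scan, choose(4, 2))

  calls_f <- tempfile(fileext = ".tsv")
  tab <- write_calls(scan, calls_f)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$verdict %in% c("high", "weak", "none")))

  dot_f <- tempfile(fileext = ".tsv")
  write_dotplot(scan[[1]]$matrix, dot_f)
  dot <- read.delim(dot_f, check.names = FALSE)
  expect_equal(nrow(dot), length(scan[[1]]$matrix$row_ids))
  expect_equal(ncol(dot), 1 + length(scan[[1]]$matrix$col_ids))
})

test_that("cross-genome mode resolves anchors in either annotation", {
  spec <- simulation_spec(seed = 45, n_genes = 30, n_chromosomes = 1,
    protein_length = c(120, 200), family_size = 0,
    events = list(sim_event("segmental_duplication", "chr1", c(5, 24),
                            divergence = 0.15, gene_loss = 0)))
  sim <- simulate_genome(spec)
  # split: chr1 = genome A, chr2 (the duplicated copy) = genome B
  g <- sim$annotation$genes
  ann_a <- genome_annotation(g[g$chromosome == "chr1", ],
                             sim$annotation$exons[g$gene_id[g$chromosome == "chr1"]])
  ann_b <- genome_annotation(g[g$chromosome == "chr2", ],
                             sim$annotation$exons[g$gene_id[g$chromosome == "chr2"]])
  tp <- sim$truth$ortholog_pairs
  s <- collinearity_scan(ann_a, sim$proteome, c(tp$id_a[10], tp$id_b[10]),
                         collinearity_params(window_size = 30),
                         ann_b = ann_b, proteome_b = sim$proteome)
  expect_equal(s[[1]]$call$verdict, "high")
})
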