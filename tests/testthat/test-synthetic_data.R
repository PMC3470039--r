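test_that("generation is fully deterministic under a fixed seed", {
  spec <- simulation_spec(seed = 99, n_genes = 15, n_chromosomes = 2,
                          protein_length = c(50, 80), family_size = 3,
                          events = list(sim_event("shuffle", "chr2")))
  p1 <- random_proteome(spec)
  p2 <- random_proteome(spec)
  expect_identical(as.character(p1), as.character(p2))

  s1 <- simulate_genome(spec)
  s2 <- simulate_genome(spec)
  expect_identical(as.character(s1$proteome), as.character(s2$proteome))
  expect_identical(s1$annotation$genes, s2$annotation$genes)
  expect_identical(s1$truth, s2$truth)
})

test_that("proteome lengths respect the spec range", {
  spec <- simulation_spec(seed = 2, n_genes = 50, n_chromosomes = 2,
                          protein_length = c(73, 91), family_size = 0)
  w <- Biostrings::width(random_proteome(spec))
  expect_true(all(w >= 73 & w <= 91))
})

test_that("residue frequencies converge to the background table", {
  spec <- simulation_spec(seed = 6, n_genes = 250, n_chromosomes = 2,
                          protein_length = c(200, 200), family_size = 0)
  prot <- random_proteome(spec)  # 10^5 residues
  counts <- colSums(Biostrings::alphabetFrequency(prot)[, syntrace:::AA20])
  bg <- syntrace:::aa_background()
  chi <- stats::chisq.test(counts, p = bg[names(counts)])
  expect_gt(chi$p.value, 1e-4)
})

test_that("diverge_sequence leaves d = 0 untouched and rejects bad rates", {
  s <- "MKVLAWDECHI"
  expect_equal(diverge_sequence(s, 0), s)
  expect_error(diverge_sequence(s, 1), class = "syntrace_validation_error")
  expect_error(diverge_sequence(s, -0.1), class = "syntrace_validation_error")
})

test_that("substitution counts match the binomial expectation", {
  set.seed(13)
  L <- 100; d <- 0.2; reps <- 1000
  base <- strrep("A", L)
  subs <- vapply(seq_len(reps), function(i) {
    out <- diverge_sequence(base, d)
    sum(strsplit(out, "")[[1]] != "A")
  }, numeric(1))
  se <- sqrt(L * d * (1 - d) / reps)
  expect_lt(abs(mean(subs) - L * d), 3 * se)
  # substitutions never keep the original residue
  expect_true(all(strsplit(diverge_sequence(base, 0.9), "")[[1]] != "" ))
})

test_that("tandem duplication inserts diverged copies immediately downstream", {
  spec <- simulation_spec(seed = 8, n_genes = 10, n_chromosomes = 1,
                          protein_length = c(50, 80), family_size = 0)
  sim <- simulate_genome(spec)
  ev <- sim_event("tandem_duplication", "chr1", c(3, 4), divergence = 0.05)
  res <- apply_event(sim$annotation, sim$proteome, ev, seed = 303)
  expect_equal(nrow(res$annotation$genes), 12)
  ords <- res$annotation$genes
  chr1 <- ords[order(ords$ordinal), ]
  # originals at ordinals 3,4; copies right after at 5,6
  expect_equal(chr1$gene_id[4:7],
               c(res$truth$ortholog_pairs$id_a, res$truth$ortholog_pairs$id_b))
  expect_equal(nrow(res$truth$ortholog_pairs), 2)
})

test_that("lossless segmental duplication plants a full ortholog block", {
  spec <- simulation_spec(seed = 9, n_genes = 30, n_chromosomes = 1,
                          protein_length = c(50, 80), family_size = 0)
  sim <- simulate_genome(spec)
  ev <- sim_event("segmental_duplication", "chr1", c(5, 24), divergence = 0.1,
                  gene_loss = 0)
  res <- apply_event(sim$annotation, sim$proteome, ev, seed = 304)
  expect_equal(nrow(res$truth$ortholog_pairs), 20)
  expect_equal(res$truth$planted_blocks$start_b, 0)
  expect_equal(res$truth$planted_blocks$end_b, 19)
  expect_true("chr2" %in% res$annotation$genes$chromosome)

  expect_error(apply_event(sim$annotation, sim$proteome,
                           sim_event("segmental_duplication", "chr1", c(25, 40))),
               class = "syntrace_validation_error")
})

test_that("segmental gene loss is binomial across replicates", {
  spec <- simulation_spec(seed = 10, n_genes = 25, n_chromosomes = 1,
                          protein_length = c(50, 60), family_size = 0)
  sim <- simulate_genome(spec)
  ev <- sim_event("segmental_duplication", "chr1", c(0, 19), divergence = 0,
                  gene_loss = 0.2)
  reps <- 500
  survivors <- vapply(seq_len(reps), function(i) {
    nrow(apply_event(sim$annotation, sim$proteome, ev, seed = 7000 + i)$truth$ortholog_pairs)
  }, numeric(1))
  se <- sqrt(20 * 0.2 * 0.8 / reps)
  expect_lt(abs(mean(survivors) - 16), 3 * se)
})

test_that("translocation preserves content and order; shuffle permutes", {
  spec <- simulation_spec(seed = 11, n_genes = 12, n_chromosomes = 2,
                          protein_length = c(50, 60), family_size = 0)
  sim <- simulate_genome(spec)
  tr <- apply_event(sim$annotation, sim$proteome,
                    sim_event("translocation", "chr1", c(2, 5), to_chromosome = "chr2"))
  expect_equal(nrow(tr$annotation$genes), nrow(sim$annotation$genes))
  moved <- sim$annotation$genes$gene_id[sim$annotation$genes$chromosome == "chr1"][3:6]
  g2 <- tr$annotation$genes[tr$annotation$genes$chromosome == "chr2", ]
  expect_equal(tail(g2$gene_id[order(g2$ordinal)], 4), moved)

  sh <- apply_event(sim$annotation, sim$proteome,
                    sim_event("shuffle", "chr1"), seed = 5)
  expect_setequal(sh$annotation$genes$gene_id, sim$annotation$genes$gene_id)
})

test_that("planted ortholog pairs always align significantly at moderate divergence", {
  for (seed in 1:5) {
    spec <- simulation_spec(seed = seed, n_genes = 12, n_chromosomes = 1,
      protein_length = c(200, 300), family_size = 0,
      events = list(sim_event("segmental_duplication", "chr1", c(2, 9),
                              divergence = 0.3, gene_loss = 0)))
    sim <- simulate_genome(spec)
    tp <- sim$truth$ortholog_pairs
    tab <- all_vs_all(sim$proteome[tp$id_a], sim$proteome[tp$id_b])
    found <- paste(tab$query_id, tab$subject_id)
    expect_true(all(paste(tp$id_a, tp$id_b) %in% found),
                info = sprintf("seed %d", seed))
  }
})

test_that("emitted fixtures round-trip and are byte-identical per seed", {
  spec <- simulation_spec(seed = 12, n_genes = 10, n_chromosomes = 2,
    protein_length = c(50, 80), family_size = 3,
    events = list(sim_event("tandem_duplication", "chr1", c(2, 3), divergence = 0.1)))
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  sim <- emit_fixture(spec, d1)
  emit_fixture(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  prot <- read_fasta(file.path(d1, "proteome.fasta"))
  expect_equal(as.character(prot), as.character(sim$proteome))
  ann <- read_gff3(file.path(d1, "annotation.gff3"))
  expect_equal(ann$genes$gene_id, sim$annotation$genes$gene_id)
  expect_equal(ann$exons, sim$annotation$exons)
  truth_pairs <- read.delim(file.path(d1, "truth_ortholog_pairs.tsv"))
  expect_equal(truth_pairs$id_b, sim$truth$ortholog_pairs$id_b)
})
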