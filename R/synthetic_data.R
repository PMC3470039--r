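AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Robinson-Robinson amino-acid background frequencies (normalized).
aa_background <- function() {
  f <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
         E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
         M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
         Y = 0.032, V = 0.064)
  (f / sum(f))[AA20]
}

#' Simulation specification
#'
#' Conditions for the synthetic genomes on which the pipeline is validated:
#' chromosomes of background genes carrying i.i.d. background-frequency
#' proteins, a planted gene family sharing a common ancestor and a conserved
#' exon architecture, and an ordered list of evolutionary events
#' ([sim_event()]). Gene order (ordinals), not physical distance, drives all
#' downstream detection; intergenic spacing is fixed at 1 kb and introns at
#' 100 nt when coordinates are laid out.
#'
#' @param seed Integer RNG seed; the full simulation is reproducible from it.
#' @param n_genes Genes per chromosome (default 60).
#' @param n_chromosomes Number of chromosomes (default 2).
#' @param protein_length Length range `(min, max)`, sampled uniformly
#'   (default 200–400 residues, typical of plant membrane proteins).
#' @param family_size Planted family members (default 7), diverged copies of
#'   one ancestor placed at random gene slots.
#' @param family_divergence Per-site substitution probability applied
#'   independently to each member relative to the ancestor (default 0.15, so
#'   members pairwise share roughly 72% identity).
#' @param events List of [sim_event()]s, applied in order.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(seed = 1, n_genes = 60, n_chromosomes = 2,
                            protein_length = c(200, 400), family_size = 7,
                            family_divergence = 0.15, events = list()) {
  if (n_genes < 1 || n_chromosomes < 1 || family_size < 0)
    stop_validation("counts must be positive")
  if (length(protein_length) != 2L || protein_length[1] > protein_length[2] ||
      protein_length[1] < 1)
    stop_validation("protein_length must be (min, max) with 1 <= min <= max")
  if (family_size > n_genes * n_chromosomes)
    stop_validation("family_size exceeds total gene count")
  if (!(family_divergence >= 0 && family_divergence < 1))
    stop_validation("family_divergence must be in [0, 1)")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 protein_length = as.integer(protein_length),
                 family_size = as.integer(family_size),
                 family_divergence = family_divergence,
                 events = events),
            class = "simulation_spec")
}

#' Planted evolutionary event
#'
#' @param kind One of `"tandem_duplication"` (copy of the gene span inserted
#'   immediately downstream), `"segmental_duplication"` (copy of the span
#'   appended as a new region, each copied gene deleted with probability
#'   `gene_loss`, survivors diverged; the block is recorded as truth),
#'   `"translocation"` (span moved, order preserved), `"shuffle"` (gene order
#'   of a chromosome permuted uniformly).
#' @param chromosome Chromosome name the region lives on.
#' @param span Ordinal span `(first, last)`, 0-based inclusive (ignored for
#'   `shuffle`).
#' @param divergence Per-site substitution probability applied to copies.
#' @param gene_loss Per-gene deletion probability for segmental copies.
#' @param to_chromosome Target chromosome for segmental/translocation; `NULL`
#'   means a fresh chromosome (segmental) or the span's own chromosome end
#'   (translocation).
#' @return A `sim_event` object.
#' @export
sim_event <- function(kind, chromosome = NULL, span = NULL, divergence = 0,
                      gene_loss = 0, to_chromosome = NULL) {
  kind <- match.arg(kind, c("tandem_duplication", "segmental_duplication",
                            "translocation", "shuffle"))
  if (!(divergence >= 0 && divergence < 1)) stop_validation("divergence must be in [0, 1)")
  if (!(gene_loss >= 0 && gene_loss < 1)) stop_validation("gene_loss must be in [0, 1)")
  if (kind != "shuffle" && (is.null(span) || length(span) != 2L || span[1] > span[2]))
    stop_validation("span must be (first, last) ordinals")
  structure(list(kind = kind, chromosome = chromosome,
                 span = if (!is.null(span)) as.integer(span),
                 divergence = divergence, gene_loss = gene_loss,
                 to_chromosome = to_chromosome),
            class = "sim_event")
}

random_protein <- function(len, bg = aa_background()) {
  paste(sample(AA20, len, replace = TRUE, prob = bg), collapse = "")
}

#' Random background proteome
#'
#' One i.i.d. background-frequency protein per gene slot of the spec, with
#' lengths uniform in `protein_length`. Fully reproducible from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return Named `AAStringSet` (names are the gene ids of
#'   [simulate_genome()]).
#' @export
random_proteome <- function(spec) {
  with_seed(spec$seed, {
    ids <- unlist(lapply(seq_len(spec$n_chromosomes), function(c)
      sprintf("chr%dg%03d", c, seq_len(spec$n_genes))))
    lens <- sample(seq(spec$protein_length[1], spec$protein_length[2]),
                   length(ids), replace = TRUE)
    seqs <- vapply(lens, random_protein, character(1))
    setNames(Biostrings::AAStringSet(seqs), ids)
  })
}

#' Substitute residues of a protein at a fixed per-site rate
#'
#' Each site is independently replaced, with probability `d`, by a uniformly
#' chosen *different* residue, so the expected fraction of changed sites is
#' exactly `d` and the expected percent identity to the original is
#' `100 * (1 - d)` — the analytic relation exploited by the
#' parameter-recovery tests.
#'
#' @param seq Single protein sequence (character or `AAString`).
#' @param d Per-site substitution probability in `[0, 1)`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Character sequence of the same length.
#' @export
diverge_sequence <- function(seq, d, seed = NULL) {
  if (!(d >= 0 && d < 1)) stop_validation("d must be in [0, 1)")
  run <- function() {
    chars <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < d)
    for (i in hit) {
      alt <- AA20[AA20 != chars[i]]
      chars[i] <- alt[sample.int(length(alt), 1L)]
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

empty_truth <- function() {
  list(ortholog_pairs = data.frame(id_a = character(0), id_b = character(0),
                                   stringsAsFactors = FALSE),
       planted_blocks = data.frame(chrom_a = character(0), start_a = integer(0),
                                   end_a = integer(0), chrom_b = character(0),
                                   start_b = integer(0), end_b = integer(0),
                                   stringsAsFactors = FALSE),
       family_members = character(0),
       family_seed = NA_character_,
       conserved_exon_plants = data.frame(ordinal = integer(0),
                                          length = integer(0)))
}

merge_truth <- function(a, b) {
  list(ortholog_pairs = rbind(a$ortholog_pairs, b$ortholog_pairs),
       planted_blocks = rbind(a$planted_blocks, b$planted_blocks),
       family_members = union(a$family_members, b$family_members),
       family_seed = if (!is.na(b$family_seed)) b$family_seed else a$family_seed,
       conserved_exon_plants = unique(rbind(a$conserved_exon_plants,
                                            b$conserved_exon_plants)))
}

# internal mutable genome representation: ordered ids per chromosome plus
# per-gene strand / exon lengths, laid out into coordinates on demand
ann_to_state <- function(ann, proteome) {
  g <- ann$genes
  chrom_order <- lapply(split(g[order(g$ordinal), ], g$chromosome[order(g$ordinal)]),
                        function(d) d$gene_id[order(d$ordinal)])
  genes <- setNames(lapply(seq_len(nrow(g)), function(i) {
    ex <- ann$exons[[g$gene_id[i]]]
    list(strand = g$strand[i], exon_lengths = as.integer(ex[, 2] - ex[, 1] + 1L))
  }), g$gene_id)
  list(chrom_order = chrom_order, genes = genes,
       proteins = setNames(as.character(proteome), names(proteome)))
}

INTRON_NT <- 100L
INTERGENIC_NT <- 1000L

state_to_ann <- function(state) {
  rows <- list(); exons <- list()
  for (chr in names(state$chrom_order)) {
    pos <- 1L
    for (gid in state$chrom_order[[chr]]) {
      gl <- state$genes[[gid]]
      k <- length(gl$exon_lengths)
      glen <- sum(gl$exon_lengths) + INTRON_NT * (k - 1L)
      starts <- pos + cumsum(c(0L, head(gl$exon_lengths, -1) + INTRON_NT))
      ends <- starts + gl$exon_lengths - 1L
      exons[[gid]] <- cbind(start = starts, end = ends)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, chromosome = chr, strand = gl$strand,
        start = pos, end = pos + glen - 1L, protein_id = gid,
        stringsAsFactors = FALSE)
      pos <- pos + glen + INTERGENIC_NT
    }
  }
  genome_annotation(do.call(rbind, rows), exons)
}

state_proteome <- function(state) {
  setNames(Biostrings::AAStringSet(unname(state$proteins)), names(state$proteins))
}

copy_id <- function(id, existing) {
  k <- 1L
  repeat {
    cand <- sprintf("%s_d%d", id, k)
    if (!cand %in% existing) return(cand)
    k <- k + 1L
  }
}

apply_event_state <- function(state, event) {
  truth <- empty_truth()
  if (event$kind == "shuffle") {
    chr <- event$chromosome
    if (is.null(chr) || !chr %in% names(state$chrom_order))
      stop_validation("unknown chromosome: %s", chr %||% "<missing>")
    ids <- state$chrom_order[[chr]]
    state$chrom_order[[chr]] <- ids[sample.int(length(ids))]
    return(list(state = state, truth = truth))
  }
  chr <- event$chromosome
  if (is.null(chr) || !chr %in% names(state$chrom_order))
    stop_validation("unknown chromosome: %s", chr %||% "<missing>")
  ids <- state$chrom_order[[chr]]
  a <- event$span[1] + 1L; b <- event$span[2] + 1L  # to 1-based
  if (a < 1L || b > length(ids)) stop_validation("region overflows chromosome %s", chr)
  span_ids <- ids[a:b]

  if (event$kind == "translocation") {
    target <- event$to_chromosome %||% chr
    if (!target %in% names(state$chrom_order))
      stop_validation("unknown target chromosome: %s", target)
    state$chrom_order[[chr]] <- ids[-(a:b)]
    state$chrom_order[[target]] <- c(state$chrom_order[[target]], span_ids)
    return(list(state = state, truth = truth))
  }

  all_ids <- names(state$genes)
  if (event$kind == "tandem_duplication") {
    new_ids <- character(length(span_ids))
    for (k in seq_along(span_ids)) {
      nid <- copy_id(span_ids[k], c(all_ids, new_ids))
      new_ids[k] <- nid
      state$genes[[nid]] <- state$genes[[span_ids[k]]]
      state$proteins[[nid]] <- diverge_sequence(state$proteins[[span_ids[k]]],
                                                event$divergence)
    }
    state$chrom_order[[chr]] <- append(ids, new_ids, after = b)
    truth$ortholog_pairs <- data.frame(id_a = span_ids, id_b = new_ids,
                                       stringsAsFactors = FALSE)
    return(list(state = state, truth = truth))
  }

  # segmental_duplication
  survive <- runif(length(span_ids)) >= event$gene_loss
  src_ids <- span_ids[survive]
  new_ids <- character(length(src_ids))
  for (k in seq_along(src_ids)) {
    nid <- copy_id(src_ids[k], c(all_ids, new_ids))
    new_ids[k] <- nid
    state$genes[[nid]] <- state$genes[[src_ids[k]]]
    state$proteins[[nid]] <- diverge_sequence(state$proteins[[src_ids[k]]],
                                              event$divergence)
  }
  target <- event$to_chromosome
  if (is.null(target)) {
    target <- sprintf("chr%d", length(state$chrom_order) + 1L)
    state$chrom_order[[target]] <- character(0)
  } else if (!target %in% names(state$chrom_order)) {
    state$chrom_order[[target]] <- character(0)
  }
  tgt_start <- length(state$chrom_order[[target]])
  state$chrom_order[[target]] <- c(state$chrom_order[[target]], new_ids)
  truth$ortholog_pairs <- data.frame(id_a = src_ids, id_b = new_ids,
                                     stringsAsFactors = FALSE)
  if (length(new_ids))
    truth$planted_blocks <- data.frame(
      chrom_a = chr, start_a = event$span[1], end_a = event$span[2],
      chrom_b = target, start_b = tgt_start,
      end_b = tgt_start + length(new_ids) - 1L,
      stringsAsFactors = FALSE)
  list(state = state, truth = truth)
}

#' Apply one planted evolutionary event to a genome
#'
#' @param ann A [genome_annotation()].
#' @param proteome Named `AAStringSet` matching the annotation's protein ids.
#' @param event A [sim_event()].
#' @param seed Optional seed for the event's randomness (`NULL` uses the
#'   current RNG stream).
#' @return List with updated `annotation`, `proteome`, and the `truth`
#'   increment (ortholog pairs, planted block coordinates).
#' @export
apply_event <- function(ann, proteome, event, seed = NULL) {
  run <- function() {
    st <- ann_to_state(ann, proteome)
    res <- apply_event_state(st, event)
    list(annotation = state_to_ann(res$state),
         proteome = state_proteome(res$state),
         truth = res$truth)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# family members share a multi-exon architecture with conserved sizes at
# ordinals 2, 3, 4 and the terminal exon; background genes draw random
# architectures
FAMILY_EXONS <- c(NA, 80L, 125L, 122L, NA, 93L, NA, 101L, 125L)
CONSERVED_PLANTS <- data.frame(ordinal = c(2L, 3L, 4L, 6L, 8L, 9L),
                               length = c(80L, 125L, 122L, 93L, 101L, 125L))

random_exon_lengths <- function(n, forbid = integer(0)) {
  pool <- setdiff(seq(50L, 600L), forbid)
  sample(pool, n, replace = FALSE)
}

family_exon_lengths <- function() {
  out <- FAMILY_EXONS
  out[is.na(out)] <- random_exon_lengths(sum(is.na(out)),
                                         forbid = FAMILY_EXONS[!is.na(FAMILY_EXONS)])
  as.integer(out)
}

#' Simulate a genome with planted events and machine-readable truth
#'
#' Builds the background genome (annotation + proteome), plants the gene
#' family (diverged copies of one ancestor, sharing a conserved exon
#' architecture), applies the spec's events in order, and records everything
#' a downstream scorer needs: ortholog pairs, planted block ordinal
#' intervals, family member ids, the family ancestor sequence, and the
#' planted conserved exon sizes.
#'
#' @param spec A [simulation_spec()].
#' @return List with `annotation`, `proteome`, `truth`, and `spec`.
#' @export
simulate_genome <- function(spec) {
  with_seed(spec$seed, {
    ids <- unlist(lapply(seq_len(spec$n_chromosomes), function(c)
      sprintf("chr%dg%03d", c, seq_len(spec$n_genes))))
    chroms <- rep(sprintf("chr%d", seq_len(spec$n_chromosomes)),
                  each = spec$n_genes)
    lens <- sample(seq(spec$protein_length[1], spec$protein_length[2]),
                   length(ids), replace = TRUE)
    proteins <- setNames(vapply(lens, random_protein, character(1)), ids)
    strands <- sample(c("+", "-"), length(ids), replace = TRUE)

    genes <- setNames(lapply(seq_along(ids), function(i) {
      n_ex <- sample(c(1L, 2L, 3L, 5L, 7L, 8L, 10L, 12L), 1L)
      list(strand = strands[i],
           exon_lengths = random_exon_lengths(n_ex,
             forbid = CONSERVED_PLANTS$length))
    }), ids)

    truth <- empty_truth()
    if (spec$family_size > 0) {
      anc_len <- round(mean(spec$protein_length))
      ancestor <- random_protein(anc_len)
      slots <- sample(ids, spec$family_size)
      for (s in slots) {
        proteins[[s]] <- diverge_sequence(ancestor, spec$family_divergence)
        fe <- family_exon_lengths()
        # exon lengths are stored in genomic order; lay the 5'->3' template
        # out reversed on minus-strand genes
        if (genes[[s]]$strand == "-") fe <- rev(fe)
        genes[[s]] <- list(strand = genes[[s]]$strand, exon_lengths = fe)
      }
      truth$family_members <- sort(slots)
      truth$family_seed <- ancestor
      truth$conserved_exon_plants <- CONSERVED_PLANTS
    }

    state <- list(
      chrom_order = split(ids, factor(chroms, levels = unique(chroms))),
      genes = genes,
      proteins = proteins)

    for (ev in spec$events) {
      res <- apply_event_state(state, ev)
      state <- res$state
      truth <- merge_truth(truth, res$truth)
    }

    list(annotation = state_to_ann(state),
         proteome = state_proteome(state),
         truth = truth, spec = spec)
  })
}

#' Write a simulated genome as a file fixture
#'
#' Emits `proteome.fasta`, `annotation.gff3`, and the truth tables
#' (`truth_ortholog_pairs.tsv`, `truth_planted_blocks.tsv`,
#' `truth_family_members.tsv`, `truth_conserved_exons.tsv`). The files parse
#' back via [read_fasta()] / [read_gff3()] into the in-memory objects, and a
#' given seed always produces byte-identical files.
#'
#' @param spec A [simulation_spec()].
#' @param outdir Output directory (created if needed).
#' @return The [simulate_genome()] result, invisibly.
#' @export
emit_fixture <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(spec)
  write_fasta(sim$proteome, file.path(outdir, "proteome.fasta"))
  write_gff3(sim$annotation, file.path(outdir, "annotation.gff3"))
  tw <- function(df, name) write.table(df, file.path(outdir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  tw(sim$truth$ortholog_pairs, "truth_ortholog_pairs.tsv")
  tw(sim$truth$planted_blocks, "truth_planted_blocks.tsv")
  fam <- sim$truth$family_members
  tw(data.frame(gene_id = fam,
                family_seed = rep(sim$truth$family_seed, length(fam))),
     "truth_family_members.tsv")
  tw(sim$truth$conserved_exon_plants, "truth_conserved_exons.tsv")
  invisible(sim)
}
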