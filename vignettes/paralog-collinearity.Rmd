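---
title: "Tracing paralog origins from gene order, homology, and exon structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing paralog origins from gene order, homology, and exon structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntrace)
```

## The question and the evidence

Small gene families in plant genomes — the seven-member *Arabidopsis
thaliana* PILS family of ER-localized putative auxin carriers is the
motivating case — typically arise through a mixture of tandem duplication,
segmental or whole-genome duplication followed by gene loss, and long
in-place divergence. Which member arose how is not readable from sequence
similarity alone: two paralogs can be 80% identical because they duplicated
recently or because they evolve slowly. `syntrace` combines four lines of
evidence, each implemented as an independent module with a file-format
surface, so that the duplication history can be reconstructed and
cross-checked:

* **collinearity** of the gene neighborhoods around two anchor genes —
  conserved gene content *and order* is the signature of shared segmental
  ancestry, and distinguishes segmental duplicates from mere family
  homologs;
* **reciprocal best hits** and a reciprocal **family census** — the standard
  operational ortholog/membership criterion;
* **percent-identity matrices** and **site-coverage filtering** of multiple
  alignments — the quantitative similarity scale;
* **exon-architecture conservation** — intron/exon structure changes slowly
  and carries signal that is independent of protein similarity.

## The homology engine

Windows compared here contain at most a few hundred genes, so instead of a
heuristic database search the package uses exact dynamic-programming
alignment (Smith–Waterman locally, Needleman–Wunsch globally, both with
affine gaps) through Biostrings' aligner. A gap of length $k$ costs
$\mathrm{open} + k\cdot\mathrm{extend}$; defaults are BLOSUM62 with open 11,
extend 1, the scheme for which published gapped Karlin–Altschul constants
exist. Raw scores map to E-values as

$$E = K\,m\,n\,e^{-\lambda S},\qquad \lambda = 0.267,\; K = 0.041,$$

with $m$ the query length and $n$ the total residue count of the searched
set, recomputed per search direction as a database search would. The bit
score $(\lambda S - \ln K)/\ln 2$ satisfies $E = m\,n\,2^{-\mathrm{bits}}$.
Exactness is not assumed: the test suite compares local and global scores
against a brute-force enumerator of *all* gapped alignment paths for short
sequences, under two gap-cost settings.

Two conventions worth noting: `X` (unknown residue) is aligned with its
BLOSUM62 scores but **never** counts as an identity anywhere in the package;
and best-hit selection breaks ties deterministically (lower E-value, then
higher bit score, then lexicographic subject id).

## Collinearity detection

For each anchor, `extract_window()` takes up to `window_size/2` genes per
side (default window 200 — i.e. 100 per side plus the anchor; a stated
"row of 200 surrounding genes" does not specify sidedness, and the
symmetric reading is the natural one). Truncation at chromosome ends is
recorded in `realized_size`, never padded. All window arithmetic uses
0-based gene ordinals; nucleotide coordinates stay 1-based GFF3 throughout.

`window_matrix()` keeps one cell per gene pair with $E \le 10^{-5}$, valued
$\min(-\log_{10} E, 200)$; $E = 0$ (score beyond double-precision E-values)
maps to the cap. `chain_diagonals()` then finds maximal-score chains by
sparse dynamic programming: a hit extends a chain when both ordinal deltas
lie in $[1, \texttt{max\_chain\_gap}]$ (default 5 — tolerant of the
single-gene insertions, deletions and local losses that accumulate after
duplication), with column order increasing for forward chains and
decreasing for inverted ones. Inverted diagonals are detected by default
because inversions are common after segmental duplication. The best chain
is extracted, its hits removed, and the search repeated, so every hit
belongs to at most one block (greedy by score). The chaining DP is itself
checked against an exhaustive enumeration of all valid chains on small
random matrices.

"High diagonal homology" needs an operational definition; the package uses
block-size thresholds: **none** below 3 chained hits, **weak** at 3–9,
**high** at ≥ 10 (all configurable, and reported with every call). Two
deliberate consequences: a lone anchor-vs-anchor hit — family homology
without neighborhood conservation — can never produce a block, and the
verdict is monotone under threshold tightening (a stricter E-value cutoff
can only shrink blocks; this is a tested property).

On the planted-truth benchmark (segmental duplications of 20 genes at
substitution rate 0.3 with 20% gene loss, 20 independent simulations) the
test suite requires the best block to recover the surviving ortholog pairs
with Jaccard ≥ 0.8 and a *high* verdict in at least 19 of 20 simulations;
shuffling both chromosomes of a 200-gene-per-chromosome genome (homologs
present, order destroyed) must produce *none* in at least 95 of 100
shuffles. `scripts/acceptance.R` recomputes both rates from scratch.

## Identity matrices and column filtering

"Identities divided by the length of the alignment" is ambiguous once a
pair of sequences is embedded in a multiple alignment: columns where *both*
rows are gaps belong to other sequences and deflate the ratio. The default
denominator (`pair_columns`) therefore counts columns where at least one of
the two rows has a residue; `msa_length`, `min_seq_length`, and
`aligned_pairs` are selectable for comparison with other tools. Values are
kept at full precision and rounded half-up to integer percent only for
presentation, matching how such tables are printed.

Site coverage of a column is the fraction of rows with a residue there
(`X` counts as a residue; gaps do not). `filter_columns()` keeps exactly
the columns at or above `min_coverage` (0.8 is the common
pre-phylogenetics setting; 0 keeps everything) and is idempotent and
monotone in the threshold — both tested properties.

## Exon structures

Exon lengths are reported 5′→3′ (minus-strand genes reversed), taken from
whatever exon features the input GFF3 supplies — whether those include UTRs
depends on the annotation source, and the package does not second-guess it.
For multi-isoform genes the isoform with the most exons is retained (ties:
longest spliced length, then lexicographic mRNA id), since structure
comparison wants the fullest model and annotation releases rarely say which
isoform a published schematic used.

Conserved exon groups are found per ordinal anchored at the 5′ end, plus a
separate pass for the terminal exon anchored at the 3′ end: exon counts
differ between family members, but terminal exons (often encoding a
C-terminal transmembrane domain) stay conserved, so the 3′ anchor catches
groups the 5′ ordinals miss. Default tolerance is 0 nt because curated
annotations report exact shared sizes; a positive tolerance clusters
lengths greedily in sorted order and then enforces that every member lies
within the tolerance of the group median. Structural classes use the
compact (≤ 3 exons) / multi-exon (≥ 7) bands observed across plant PILS-like
families.

## The synthetic-data module

The simulator is first-class, tested code — full-scale reference inputs
(published proteomes and annotations) cannot ship with a package, so every
detector is validated against planted truth. A simulation draws i.i.d.
background-frequency proteins (Robinson–Robinson frequencies; uniform
lengths, default 200–400 residues, typical of plant membrane proteins) for
`n_genes` genes per chromosome (default 60, two chromosomes), plants a
family of diverged copies of one ancestor (default 7 members at rate 0.15,
sharing a conserved exon architecture: sizes 80/125/122/93/101 nt at fixed
ordinals and a 125 nt terminal exon), and applies events in order: tandem
duplication, segmental duplication with per-gene loss, translocation,
shuffle.

Substitution is uniform over the 19 alternative residues rather than
matrix-weighted, which keeps the identity–divergence relation analytic
($\mathbb{E}[\mathrm{identity}] = 1 - d$) for parameter-recovery tests: at
rate 0.2 and length 400 the globally aligned identity recovers 80% within
±3 points. Intergenic spacing is fixed at 1 kb and introns at 100 nt:
ordinals, not physical distance, drive all detection. Everything is
reproducible from a single integer seed, including byte-identical emitted
fixtures.

What the simulator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: matrix-structured substitution and
indels (real paralogs gain/lose residues; identity–divergence is then no
longer analytic), nucleotide-level evolution and codon structure, realistic
gene density variation, transposons and tandem arrays in the background,
and annotation noise (wrong gene models, missing genes). The qualitative
*A. thaliana* checks in the acceptance tier exist precisely because of this
gap; they require externally supplied reference files
(`inst/extdata/external/README.md`).

## Numerical and design choices

* Problem sizes in the routine test runs: 20 simulations for planted-block
  recovery (60 genes/chromosome), 100 shuffles for the negative control
  (200 genes/chromosome, hit table computed once and reused — homology does
  not depend on gene order), brute-force oracle checks at sequence length
  ≤ 5 and matrices ≤ 8×8. These sizes give stable rates while keeping a
  routine run fast.
* Criterion choice for the planted benchmark: blocks of 20 genes at loss
  0.2 leave ~16 expected ortholog pairs, comfortably above the high-verdict
  threshold of 10; planting a block whose expected survivorship sits *at*
  the verdict boundary would test binomial noise, not the detector.
* The family census's "reciprocal" rule: a candidate is a member iff its
  best hit against the seed family is significant *and* that family member
  hits the candidate back at the threshold. Strict mutual-best would be
  wrong here — several family members share one closest seed, and all of
  them are genuine members.
* The simulation spec file for the `simulate` subcommand is YAML: it is the
  structured-config format the package's R dependencies read natively, and
  one config dialect is enough.
* E-value ties in best-hit selection are broken by bit score and then
  subject id; chain-DP ties keep the lowest-coordinate optimum; both make
  every output byte-reproducible under a fixed seed.
* `read_hits()`/`write_hits()` round-trip the 12-column tabular dialect
  losslessly (17 significant digits), so externally computed search results
  can replace the internal aligner without information loss.

## Limitations

The collinearity thresholds (3/10 hits, gap 5) are operational settings,
not estimated quantities; on real genomes they should be read as a
screening classification and tuned against known duplication blocks where
available. E-value constants are the published gapped BLOSUM62-11-1 values,
not estimated from the actual score distribution of each window. The
package deliberately does not build multiple alignments, infer trees, date
duplications, or map genome-wide synteny — it analyses the neighborhoods of
a handful of anchors with exact methods.
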