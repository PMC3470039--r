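# Optional external reference inputs

The qualitative *Arabidopsis thaliana* checks in the test suite run against
published reference data that cannot be redistributed with this package.
They are activated by dropping the following plain-text files into this
directory before installing:

- `atpils_family_clustalw.fasta` — ClustalW multiple alignment of the seven
  *A. thaliana* PILS proteins (aligned FASTA; record ids must contain
  `PILS1` … `PILS7`).
- `pils_broad_alignment.fasta` — the broad cross-species PILS multiple
  alignment used for family-wide column accounting (aligned FASTA).
- `tair_genes.gff3` — a current TAIR genome annotation containing the seven
  *PILS* gene models (`AT1G20925`, `AT1G71090`, `AT1G76520`, `AT1G76530`,
  `AT2G17500`, `AT5G01990`, `AT5G65980`) with exon features.
- `tair_proteome.fasta` — the matching representative proteome (one protein
  per gene, ids matching the annotation's protein ids).

Without these files the corresponding acceptance checks fail (they are
external-data checks by construction); every synthetic-data check runs
self-contained.
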