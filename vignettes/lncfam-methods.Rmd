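---
title: "Discovering lncRNA gene families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering lncRNA gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncfam)
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts of at least 200 nt with no
annotated protein-coding capacity. In plant genomes — rice is the motivating
case — thousands of loci are annotated as lncRNA, most of them functionally
uncharacterised. One productive way in is sequence: if groups of lncRNA loci
share long, highly conserved blocks, those groups behave like *gene
families*, and family membership is a handle for functional analysis that
positional approaches miss. `lncfam` implements a sequence-based family
discovery pipeline:

1. **Catalog** — read a genome annotation (GFF3 + genome FASTA, or an NCBI
   RNA GenBank flat file), keep transcripts by biotype, and tabulate locus
   id, length and exon count.
2. **Representative isoforms** — keep one isoform per locus (longest by
   default; shortest and restrict-to-a-locus-list modes are available).
3. **Homology** — align every representative lncRNA against a target
   transcript set with a built-in seed-and-extend local aligner, or import
   external BLASTN tabular output.
4. **Filter cascade** — drop alignments to ribosomal RNA, drop intra-locus
   (self and isoform–isoform) hits, and require a minimum significant match
   length of 100 nt (inclusive).
5. **Classify** — split surviving matches into same-species non-coding,
   same-species coding, and other-species (the last annotated with the
   species name via an accession-to-taxon map).
6. **Families** — build an undirected locus graph from the same-species
   non-coding matches; gene families are connected components with at
   least three members. Loci matching exactly one or exactly two partners
   are tallied separately.
7. **TE screen** — align family members against a transposable-element
   library and flag families whose shared signal is explained by a common
   TE insertion; flagged families are excluded from the reported family
   spectrum.

A separate branch of the package ingests rMATS-style differential-splicing
event tables (SE, RI, A5SS, A3SS; MXE is parsed but excluded from the
standard report), applies the significance filter *p* < 0.005 and
FDR < 0.05 (strict inequalities), deduplicates events to loci, intersects
locus sets across comparisons, and counts events on lncRNA loci.

## The aligner

The homology stage is the package's own seed-and-extend implementation,
deliberately reconstructing megablast-style behaviour:

* scoring: match +1, mismatch −2, linear gap penalty −2.5 per gap column
  (all configurable via `align_params()`);
* seeding: word size *k* = 11; a query/target pair (each target strand is
  scanned) becomes a candidate when **two** word hits fall on nearby
  diagonals — the classic two-hit trigger. Any alignment containing an
  exact run of *k* + 1 nt produces two overlapping same-diagonal words, so
  only alignments with no 12 nt exact run anywhere can be missed, and
  those sit at or below the significance threshold in practice;
* extension: candidates get a full Smith–Waterman dynamic program
  (compiled code), and non-overlapping alternative alignments of the same
  pair are extracted greedily by score, masking the aligned rows and
  columns between iterations (Waterman–Eggert style). Ties break toward
  the leftmost query end, so output is deterministic;
* significance: Karlin–Altschul statistics,
  \(E = K m n e^{-\lambda S}\), with \(m\) the query length, \(n\) the
  total target length, \(\lambda\) solved from the scoring scheme under
  uniform base composition and \(K\) fixed at 0.621, the conventional
  ungapped value for +1/−2 scoring. The default threshold is
  \(E \le 10^{-6}\). Any monotone transform of the score would do for
  thresholding; the BLAST convention is used so imported BLASTN results
  and built-in results live on comparable scales.
* `N` bases mismatch everything, including `N`, and never count as
  identities.

Because the exact parameters of the original genome-wide search are not
recoverable, all of these are explicit configuration with defensible
defaults rather than hidden constants. External BLASTN output in the
standard 12-column tabular format can be substituted at any point via
`import_blast_tabular()`; coordinates are converted to the package's
internal 0-based half-open convention at that boundary (GFF3's 1-based
closed coordinates are converted at parsing, once, for the same reason).

The test suite checks the aligner against two independent oracles: a
plain-R Smith–Waterman dynamic program written separately from the
package, and `Biostrings::pairwiseAlignment()`. On mixed sets of random
and planted-homology sequences, every alignment whose oracle score reaches
the significance threshold must be found with exactly the oracle's score.

## Filters and families

* The ≥100 nt match-length boundary is **inclusive** (a 100 nt alignment
  passes) and applies to alignment columns, not query coverage.
* The *p* and FDR thresholds on splicing events are **strict** (an event
  at exactly *p* = 0.005 fails); a `strict = FALSE` switch flips both to
  inclusive. Missing statistics fail every threshold.
* Families are connected components (single linkage) of the locus graph —
  the minimal-assumption reading of "sharing significant matches", and the
  one that makes family sizes well defined. `extract_families()` also
  reports the degree tallies (loci matching exactly one / exactly two
  partners), computed on the full pre-screen graph.
* The TE flag rule: a member is TE-supported when its TE-library
  alignments of ≥100 nt together cover at least half of the member's
  family-supporting matched span; a family is flagged when at least half
  its members are TE-supported. Coverage uses the union of TE hits
  because a single TE insertion can be split into several alignments by a
  representative isoform's intron structure. Both fractions and the
  length floor are arguments of `screen_te()` and the reason string is
  recorded on each flagged family.

## The synthetic-data generator

`generate_genome()` builds a toy annotated genome in which the truth of
every downstream stage is known and machine-readable
(`$truth`): lncRNA families sharing mutated copies of a common block,
two-locus pairs (which must *not* become families but populate the
degree-1 tally), background loci, TE-fragment decoy families, ribosomal
loci plus one lncRNA carrying an rRNA fragment (work for the rRNA
filter), coding genes — some embedding a lncRNA block, emulating
lncRNA-to-coding sequence sharing — and cross-species transcripts outside
the annotation for the species-classification path.

Default parameters are chosen to mirror the magnitudes the pipeline is
meant to detect in real data: shared blocks of 605, 382 and 208 nt, a 3%
per-base substitution rate (within-family identity ≈ 97%, comfortably
above a 95% working notion of "highly conserved"), family sizes from 3 to
35, and primary transcripts of 800–1600 nt. Background composition is
i.i.d. uniform over ACGT (GC = 0.5, configurable) so that family detection
cannot secretly depend on composition. Mutations are substitutions only by
default; an indel rate is a separate knob for exercising gapped alignment.

Two structural choices matter:

* Planted conserved blocks are **exonic**: intron insertion points avoid
  the block interior, so no isoform structure fragments a block. A
  retained-intron isoform that splits a 150 nt block into two sub-100 nt
  alignments would make the planted family undetectable by construction
  — a property of the annotation's isoform geometry, not of the family
  logic the fixture is meant to exercise — and conserved blocks confined
  to exons are also the biologically typical case.
* Multi-isoform loci carry skipped-exon and retained-intron variants, so
  the longest isoform is not always the "primary" one, and isoform
  selection is exercised non-trivially.

`generate_event_tables()` emits rMATS-dialect tables where a planted
subset of rows passes the significance filter and everything else fails
at least one threshold. Defaults plant 217/247/85/131 significant
SE/RI/A5SS/A3SS rows (of which 17/55/11/23 on lncRNA loci) in tables of
300/350/150/200 rows, echoing the scale of a seed-development comparison.
`required_loci` forces chosen loci into the significant set, which is how
multi-comparison intersection cores (for example a 29-locus three-way
core) are planted; comparisons use disjoint locus pools so the planted
core is exactly the expected intersection.

What passing on synthetic data does **not** show: performance on real
annotations with biased composition, repeat-rich background, fragmented
assemblies, or lncRNA families conserved below ~90% identity; nor does the
generator simulate reads or the splicing-caller statistics (tables are
ingested, never re-derived).

## Numerical and degenerate-input choices

* Isoform-length ties break by lexicographically smallest transcript id.
* An empty result from restrict-to-locus-list selection is a warning and
  an empty catalog, not an error; empty match tables pass through every
  filter unchanged; an empty TE library makes the screen a warning no-op.
* A seed length exceeding the shortest query, a family size floor below 2,
  planted event counts exceeding table sizes, and blocks longer than the
  largest locus are configuration errors.
* Generation is a deterministic function of the seed (integer-based
  sampling only), and the test suite asserts byte-identical output files
  across repeated runs.

## Problem sizes used in the checks

The bundled verification runs use 20 generator seeds with families of
sizes {3, 4, 5, 35}, blocks of {208, 150, 120} nt and loci of 400–900 nt
for family recovery; 20 further seeds with two TE decoy families each for
the screen; and 50 sequences of 200–1000 nt (including five planted
homologous pairs at 0–10% divergence) for the aligner-vs-oracle
comparison. These sizes keep each end-to-end genome run in the seconds
range while covering the full family-size span.

## Known limitations

* The aligner is designed for transcript-scale sequences (up to a few kb);
  it runs a full quadratic DP per candidate pair and is not a genome-scale
  aligner. For large real datasets, run BLASTN externally and import the
  tabular output.
* E-values use a fixed ungapped *K*; with non-default scoring the absolute
  E-value scale shifts (ordering is unaffected). The threshold is
  configuration, reported with the outputs.
* Species classification is a flat accession-to-species lookup; there is
  no taxonomy-tree reasoning.
* The GenBank flat-file reader covers the NCBI RNA record dialect
  (per-transcript records with `gene`, RNA-type and `exon` features); it
  is not a general GenBank parser.
* Whether the original analysis applied its match-length filter per
  alignment or per aggregated subject is unknowable from the description;
  this package filters per alignment and exposes the choice.
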