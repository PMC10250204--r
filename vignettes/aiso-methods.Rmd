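---
title: "Quantifying adjacent introns' splicing order: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adjacent introns' splicing order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Splicing is largely co-transcriptional, but the two introns flanking an
internal exon are not necessarily removed in the order they are transcribed.
For a focus exon we call the relative removal order of its two flanking
introns the *adjacent introns' splicing order* (AISO). A sequencing fragment
is informative about AISO when it simultaneously shows one intron spliced
(an exon–exon junction) and the other still present (contiguous alignment
into intronic sequence). `aiso` extracts these configurations from spliced
RNA-seq alignments (BAM) around user-specified exons:

* **upfi** — junction to an upstream exon *and* unspliced downstream
  intron: the upstream intron was removed first;
* **dofi** — the mirror image: unspliced upstream intron plus a junction to
  a downstream exon;
* **bus** / **bos** — both introns unspliced / both spliced on one
  fragment;
* **inup**, **indo**, **skip** — exon-inclusion junctions on either side
  and exon-skipping junctions.

The headline statistic is `Fupfi = upfi / (upfi + dofi)`: near 1 the
upstream intron is usually removed first, near 0 the downstream one.
Additionally `PSI = ((inup+indo)/2) / ((inup+indo)/2 + skip)` measures exon
inclusion and, per flanking intron, `PIR = ((EI+IE)/2) / ((EI+IE)/2 + J)`
measures retention, where `EI`/`IE` count fragments spanning the intron's
two exon/intron boundaries unspliced and `J` the spliced junctions across
it. Because nascent transcripts are the object of study, chromatin-bound or
total ribo-depleted RNA is the appropriate input material; PIR from matched
cytoplasmic/polyA data is the standard way to discard stably retained
introns before interpreting AISO.

## Exon entities and exon types

Genome annotations describe exons per transcript; AISO is a property of an
exonic locus. `extract_exon_table()` therefore clusters overlapping exon
instances of one gene (single-linkage, any overlap) into *exon entities*
carrying every observed start and end coordinate, plus the neighbor
coordinates that delimit the flanking introns across all member
transcripts. Entities whose interval exactly spans two transcript-adjacent
exons plus the intron between them are intron-retention variants, not true
exons; they are detected *before* clustering (otherwise they would glue
their parts together) and excluded from the table by default.

Each entity gets a positional type: `first`, `sfrst` (second-first in every
transcript containing it), `internal`, `slst` (second-last), `last`, or
`diverse` when memberships disagree. Two conventions were genuinely open
and are fixed as follows: within one transcript the label precedence is
first > last > sfrst > slst (so the middle exon of a 3-exon transcript is
`sfrst`), and single-exon transcripts contribute an ambiguous label that
forces `diverse`, since the typing scheme has no category for them.
Membership is judged over the transcripts *containing* the exon, not all
transcripts of the gene.

## Counting model

For each entity the full flanking introns run from the exon's maximal
extent to the nearest annotated neighbor coordinate on each side. To
neutralize the length asymmetry of the two introns (a longer intron catches
proportionally more intronic fragments), both introns are reduced to
*effective regions* of equal length — the length of the shorter intron —
adjacent to the exon. With a 500-nt upstream and a 3000-nt downstream
intron, only the 500 nt nearest the exon count on both sides. The
simulation study below verifies that this removes intron-length-driven bias
in Fupfi.

Evidence per fragment (a single-end read, a mate pair merged into one
evidence set, or a long read):

* *junction evidence* on a side: some junction whose donor/acceptor
  fuzzy-match a neighbor coordinate and an exon boundary (tolerance
  `tol = 3` nt by default, symmetric, making the caller's 0- vs 1-based
  convention irrelevant);
* *intronic evidence* in a region: an aligned block overlapping the
  effective region by at least `min_intron_overlap = 6` nt — `tol + 3`, so
  boundary jitter inside the fuzzy window cannot fabricate intron evidence
  — provided no junction of the same fragment splices that intron out. A
  junction "splices the intron out" when its gap covers the intron within
  `tol` at each edge; this includes skipping junctions that remove intron,
  exon and intron together.

A fragment with a block inside an effective region *and* a junction
removing that same intron is self-contradictory (typically a misassigned
mate) and is discarded from all counts for that exon; discarded totals are
reported for diagnosis. The unsequenced insert between mates asserts
nothing. Per exon a fragment increments at most one of upfi/dofi/bus/bos.
PE interior evidence is accepted: a mate lying fully inside an intron
counts as intronic evidence even without touching the exon boundary, as
does a boundary-spanning block.

Strandedness is never required from the user: pairedness comes from the
FLAG majority and strandedness from a vote of junction-bearing fragments
matched to annotated genes (read-1 orientation vs gene strand; >80% one
way declares a stranded library). In stranded data, fragments antisense to
the focus exon are ignored; unstranded data counts all orientations.

## Long-read truncation bias and its correction

Long reads are processed like single-end reads, but reads that do not
cover the transcript end-to-end bias AISO at the terminal covered exons:
a 5'-truncated molecule cannot show the upstream junction of its 5'-most
covered exon (depleting upfi), and a 3'-truncated nascent molecule
symmetrically depletes dofi. With `biascorr = TRUE` each long read is cut
at its first and last covered annotated exons (coverage = block overlap of
at least `min_intron_overlap` nt with the entity extent): those exons and
all evidence beyond them are removed, and only interior exons of the read
can still yield counts. Both terminals are trimmed unconditionally. The
correction can only remove evidence — per-exon `upfi + dofi` never
increases — which is why it is off by default and left to the user's
discretion. Mate pairs are never truncated.

## The synthetic validation world

The simulator generates what the validation design needs and nothing more:
single-transcript genes on one synthetic contig (2 kb apart), one focus
internal exon per gene, and per gene 10–20 pre-mRNA molecules in which
exactly one flanking intron of the focus exon is retained while all other
introns are spliced out. The proportion of downstream-retained molecules —
the true Fupfi, since a downstream-retained molecule is upstream-first
evidence — is drawn uniformly from the grid 0, 0.1, ..., 1. Reads (75 or
150 nt; SE or PE with mean insert 250 or 500 nt) are placed uniformly along
molecules, or tiled exhaustively for saturating-depth experiments, and
emitted as *exact* precomputed spliced alignments: no mapper and no
sequencing error enter the test surface, so every validation failure
implicates the counting logic rather than upstream tooling.

Values the stated design leaves open were fixed once, before any
measurement, at what is realistic for desk-scale work: exon lengths
lognormal (meanlog log 130, sdlog 0.45) clamped to 20–400 nt (human
internal-exon scale); intron lengths uniform 300–1000 nt standing in for
genomic intron sampling; PE insert s.d. 10% of the mean; half the genes on
the minus strand; long-read truncation probability `1 - exp(-L/3000)` for
molecule length `L` (increasing in length, as for broken or
still-transcribing RNA), truncation point uniform along the molecule.

What a green test does establish: the classifier implements the
configuration definitions exactly (it is checked against an independent
brute-force classifier on randomized scenes), quantification is unbiased
across exon- and intron-length strata, the detection bound follows read
geometry, and the truncation correction removes the bias it targets. What
it does not establish: behavior under mapper errors, sequencing errors,
soft-clips, antisense overlap of real genes, or annotation incompleteness —
none of which the generator emulates.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere (GTF/IRanges convention);
  the ±3-nt fuzzy matching absorbs residual off-by-one from foreign exon
  tables.
* The exact PSI/PIR composition is not uniquely determined by their
  definitions alone; the average-of-two-boundaries forms above are the
  package's documented, unit-tested choice.
* Fuzzy ties (two candidates at equal distance) resolve toward the smaller
  coordinate; detection of "nearest neighbor" among multiple annotated
  neighbor coordinates uses the one closest to the exon.
* Output rows always preserve the input exon-table row order; unavailable
  estimates are the literal `NA`. An exon lacking a neighbor on either
  side yields zero counts and all-`NA` metrics.
* Category thresholds for cross-sample comparison default to
  `Fupfi >= 0.8` (upfi exon), `<= 0.2` (dofi exon) with
  `N(upfi + dofi) >= 10`; these are post-hoc filters, never baked into
  counting. Consistency between samples is scored per query category as
  the fraction keeping the category in the target sample versus the
  target's genome-wide background, with a one-sided binomial test, plus
  Pearson/Spearman correlations of Fupfi.

## Known limitations

Ordering information is inherently local: fragments shorter than the exon
cannot produce upfi/dofi counts at all (with 75-nt SE reads only exons
short enough to fit junction anchor + exon + 6 nt of intron are
detectable), and order beyond the two adjacent introns is out of scope.
Genes with transcripts on both strands are rejected as annotation errors.
The strandedness vote assumes junctions mostly match annotated genes; a
library dominated by unannotated splicing would fall back to unstranded
counting. The truncation correction trades variance for bias — it
discards a large share of informative long-read counts.
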