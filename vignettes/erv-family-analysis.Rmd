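---
title: "Annotating and dating a young ERV family with ervkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and dating a young ERV family with ervkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervkit)
```

## The problem

A long-terminal-repeat (LTR) retroelement integrates as a provirus —
LTR + internal region + LTR — and duplicates a few bases of host sequence
on both sides of the insertion (the target-site duplication, TSD). Three
observations identify a family that is transpositionally young, possibly
still active:

1. copies nearly identical to each other (terminal branch lengths on a
   family tree below ~0.01 substitutions/site, and near-identical LTR
   pairs within individual proviruses);
2. presence/absence polymorphism of individual insertions between
   conspecific genome assemblies, ideally with a perfect TSD at the
   occupied site and a single TSD copy at the empty site — the hallmark
   of a genuine, recent integration rather than an assembly artifact;
3. intact protein-coding capacity (here a single Gag open reading frame;
   the families modelled are nonautonomous and encode neither *pol* nor
   *env*).

`ervkit` implements this whole chain against a synthetic-genome benchmark
with planted truth, so that every stage's accuracy is measurable without
downloading assemblies.

## The synthetic generator: what it emulates, and what it does not

`simulateErvStudy()` is first-class, tested code, not a fixture. It
emulates:

* a random host genome (default 4 × 500 kb, GC 0.41 — a compact stand-in
  for a fish-like nuclear background);
* a family consensus built by `synthFamilyModel()`: 400-bp LTRs, an
  internal region carrying a 617-amino-acid Gag ORF between untranslated
  pads, a 5-bp TSD. The Gag length matches the single long ORF of the
  motivating family; the element total (~3.3 kb) sits comfortably inside
  the 1000–8750-bp length window used for tree building;
* 60 planted insertions (40 full, 15 solo LTRs, 5 truncated), strands
  mixed, with per-copy divergence drawn uniformly on [0, 0.02]
  substitutions/site — the ceiling a "recently replicating" family shows;
* 3 derived strains with 20 presence/absence events (precise absence,
  solo-LTR conversion, locus deletion), emulating the handful of
  conspecific assemblies such a study compares.

The substitution process is independent per site, uniform over the three
alternative bases, with no indels by default — divergence is measured in
substitutions/site, so the generator plants exactly that. TSD length
defaults to 5 bp and is configurable per event; real families vary and
the modelled family's TSD length is not established, so the value is a
model parameter, not a claim.

What the generator does **not** emulate: segmental duplications and
low-complexity repeats (anchor ambiguity in real assemblies is therefore
under-represented), indel mutation, assembly gaps and collapsed repeats,
transposition dynamics over generations, and selection. Passing the
recovery suite therefore demonstrates correctness of the decision
procedures on clean signal at realistic divergence — not robustness to
assembly pathology.

## Coordinates

All in-memory coordinates are 1-based closed, the GRanges/Biostrings
convention this package is built on; BED output and PAF input are
converted at the format boundary (BED 0-based half-open, PAF 0-based
half-open starts). Choosing the container's native convention removes a
whole class of off-by-one translation errors inside the package.

## Annotation

`scanHits()` seeds with exact, non-overlapping 15-mers from each
consensus part on both strands, clusters seed diagonals (cluster gap
200 bp), and refines each cluster by local alignment (match +2, mismatch
−3, gap open 5, extend 2 — BLAST-like scoring that tolerates the few
percent divergence expected within a young family while keeping local
alignments from leaking into flanking sequence). At 2% divergence an
individual 15-mer survives with probability 0.98^15 ≈ 0.74, and an LTR
contributes ~26 seeds, so missing all seeds of a copy is vanishingly
rare. One numerical subtlety: a mutated terminal base makes a local
alignment trim the hit by 1–2 bp, which would break exact TSD detection
downstream; when the trim is ≤5 bp the hit is snapped out to the
consensus part boundary. The extension is capped at the part's consensus
span, so it cannot walk into host sequence even on truncated copies.

`defragment()` merges same-chromosome, same-strand, same-family hits
separated by ≤500 bp (configurable) when they continue the element in
consensus order. Fragments of one part rejoin only if their consensus
coordinates advance (tolerating 20 bp of overlap); two complete LTRs
never merge without an internal region between them, which keeps
adjacent solo LTRs from fusing into chimeric calls. Greedy left-to-right
(element-order) grouping makes ties resolve deterministically toward the
smallest genomic gap.

`detectTsd()` is deliberately strict: the longest k in [2, 20] with the
k bp immediately 5′ of the call exactly equal to the k bp immediately 3′
of it. A mismatched-TSD mode is deliberately absent — the evidence the
polymorphism caller relies on is the *perfect* duplication.

## Gag assessment

`assessGag()` anchors the family's known ORF start on each copy by local
alignment of the internal consensus and reads codons from there: the
copy is intact when the ATG survives and the first in-frame stop does
not precede 95% of the expected protein length (`intact_fraction`,
default 0.95 — "full-length" with slack for a little terminal
variation). Anchoring, rather than taking the longest ORF of the copy,
is what makes a premature stop at codon k report `protein_len = k − 1`
instead of silently switching to a shorter downstream ORF. Protein
identity uses global alignment with a fixed simple scheme (match +1,
mismatch 0, gap −1) and counts matches over aligned columns excluding
terminal gaps; with near-identical proteins of equal length this equals
the position-by-position count, which the tests verify.

## Recency

Copies passing the length filter are projected onto the consensus by
pairwise alignment (copy-global / consensus-local; insertions relative
to the consensus are dropped, deletions become gap columns). This
consensus-anchored pseudo-alignment replaces a multiple aligner at desk
scale; LTR and internal regions are projected as one concatenated
consensus rather than modelled separately, noted here as a simplification.
Pairwise p-distances over shared non-gap columns (guard: ≥100 columns,
else the pair is reported missing, never 0) are Jukes–Cantor corrected.
Trees come from neighbor joining — exact on additive matrices, which the
acceptance suite verifies to 1e-9 on a 4-taxon case — with negative
branch lengths clamped to zero and a message logged. Maximum-likelihood
inference and bootstrap supports are intentionally out of scope: the
statistics consumed downstream are terminal branch lengths and their
median/threshold summaries, for which NJ terminal branches are a proxy,
not a numerically identical substitute. `ltrLtrDivergence()` adds the
classic per-provirus clock: the two LTRs are identical at integration,
so their JC distance dates the copy.

## Polymorphism calling

For each reference provirus, the 50-kb flanks (default) are extracted
and the `minAnchor` = 500 bp immediately adjacent to the element on each
side are placed in the query by exact matching on both strands; any
ambiguity (multiple placements) is surfaced as UNDETERMINED rather than
guessed. The observed inter-anchor gap is compared with three expected
windows: element length (SHARED_FULL), one LTR (SOLO_LTR), and −TSD
(PRECISE_ABSENCE — the anchors overlap on the single remaining copy of
the target site). Gap tolerance is max(50 bp, 10% of the expected
length) per window; the caller verifies at construction that the
windows cannot overlap for the family at hand and raises a configuration
error otherwise, so SHARED_FULL and SOLO_LTR can never compete for the
same evidence. A PRECISE_ABSENCE candidate must additionally pass the
empty-site check (exactly one TSD copy spanning the junction; a
zero-length TSD passes vacuously but is flagged low-evidence). When the
immediate flanks cannot be placed, outer probes at 2/5/20 kb distinguish
a deleted locus region (outer sequence present, junction gone →
LOCUS_DELETED) from an undeterminable one. The reference assembly
carries the insertion by construction and counts as one determinable
SHARED_FULL cell when deciding whether a locus is polymorphic, so a
locus converted to a solo LTR in every query strain is still (correctly)
polymorphic. Nested loci are genotyped against the innermost element;
their flanks are repetitive, so in practice they surface as UNDETERMINED
and are excluded from the polymorphism determination — the honest
answer for a junction that cannot be anchored uniquely.

## Oligo targeting

An antisense oligo (LNA or morpholino — chemistry is metadata; the
computation is identical) binds the reverse complement of its own
sequence, so a copy is a target when that site occurs in its
element-sense sequence with at most `max_mismatches` substitutions
(no indels, matching a zero-mismatch design criterion). Minus-strand
copies are reverse-complemented before scanning because oligos act on
the transcript. Copies whose annotation clips a candidate site (a ≥8-bp
piece of the site flush at a call edge) are listed separately: their
true status depends on sequence outside the annotation, and folding them
into either count would overstate the evidence.

## Pipeline and reproducibility

`runPipeline()` executes simulate → annotate → gag → recency →
polymorph → oligo from a YAML configuration, writing FASTA, BED, TSV and
Newick outputs plus a checksum manifest. All randomness derives from one
top-level seed through a deterministic per-stage derivation, so reruns
with the same configuration are byte-identical — asserted in the test
suite by comparing manifests. Every effective threshold is dumped to
`run_config.yaml` alongside the outputs.

## Problem sizes

The bundled benchmark runs at: 2-Mb reference, 60 insertions, 3 strains,
20 events (recovery suite and the acceptance script); a 300-kb / 10-copy
configuration for the pipeline demo and determinism checks; and
two extra assemblies planted with 4 and 44 near-full-length copies for
the cross-assembly copy-number statistic. These sizes were chosen so a
single run exercises every code path with enough copies for the
percentage statistics to be meaningful.

## Known limitations

* Exact-match anchoring (default 0 mismatches) assumes query flanks
  essentially identical to the reference, which holds within a species
  but not across species; raise `maxMismatch` (at real computational
  cost) or supply minimap2 PAF alignments instead.
* The scanner is built for one family model at a time and for young,
  low-divergence families; it is not a general repeat annotator, and
  `max_divergence` defaults to 10%.
* Indels are not modelled by the generator, so the pseudo-alignment's
  insertion-dropping behaviour is exercised only by constructed tests.
* Population genetics (allele frequencies, read-backed genotyping from
  BAMs) is out of scope; the caller genotypes assemblies, not reads.
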