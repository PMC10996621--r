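# ervkit

Desk-scale analysis of young endogenous retrovirus (ERV) families in genome
assemblies.

Vertebrate genomes carry LTR retroelements — proviruses of the form
LTR–internal–LTR flanked by a short target-site duplication (TSD) created at
integration. Over time a provirus can recombine its two LTRs into a **solo
LTR**, accumulate truncations, or remain absent from some individuals
altogether: these presence/absence **insertional polymorphisms**, together
with low sequence divergence among copies, are the genomic signature of a
family that transposed recently. `ervkit` packages the desk-side analyses a
study of such a family needs:

* **Synthetic-genome generator** — plants full proviruses (with perfect
  TSDs), solo LTRs, truncated fragments and nested copies into a random
  reference, then derives strain genomes differing by precise absences,
  solo-LTR conversions and locus deletions, emitting FASTA plus a
  machine-readable truth table. Every downstream stage is testable against
  planted truth, with no downloads.
* **Insertion annotator** — a k-mer-anchored scanner plus a defragmenter
  that reconstructs insertion calls from per-fragment hits (RepeatMasker
  `.out` tables are also accepted), classifies each call
  (`FULL_PROVIRUS` / `SOLO_LTR` / `TRUNCATED`), applies length filters and
  detects perfect TSDs.
* **Gag ORF assessment** — finds and translates the family's Gag open
  reading frame per copy, flags premature stops, and computes pairwise
  protein identity.
* **Recency statistics** — consensus-anchored pseudo-alignment, p-distance
  with the Jukes–Cantor correction *d* = −(3/4)·ln(1 − (4/3)·*p*), a
  neighbor-joining tree (exact on additive matrices), terminal-branch
  summaries (median; fraction below 0.01 substitutions/site), per-provirus
  LTR–LTR divergence dating, and near-full-length copy counts across
  assemblies.
* **Polymorphism caller** — anchors each reference locus's flanks in a
  query assembly and reads the gap between them: element-length gap =
  `SHARED_FULL`, one-LTR gap = `SOLO_LTR`, overlapping anchors with a
  single TSD copy = `PRECISE_ABSENCE` (verified by the empty-site check),
  junction sequence missing while outer flanks survive = `LOCUS_DELETED`.
  Precomputed PAF alignments can stand in for the built-in anchoring.
* **Antisense-oligo targeting** — enumerates which family copies an LNA or
  morpholino oligo can target at a given mismatch allowance (a copy is a
  target when the reverse complement of the oligo occurs in its
  element-sense sequence), plus a gene/insertion proximity report for
  differential-expression tables.

## Worked example

Simulate a small study (a 300-kb reference with 10 planted insertions and
two derived strains), annotate it, and genotype the proviral loci:

```r
library(ervkit)

sim <- simulateErvStudy(seed = 7, nFull = 6, nSolo = 3, nTrunc = 1,
                        nChroms = 2, chromLen = 150000,
                        nStrains = 2, nEvents = 4)
sim$model
#> ErvFamilyModel 'ERVSim-1'
#>   LTR: 400 bp; internal: 2454 bp; element: 3254 bp
#>   TSD length: 5 bp; expected Gag: 617 aa

calls <- defragment(scanHits(sim$reference, sim$model))
censusCalls(calls)$by_class
#> FULL_PROVIRUS      SOLO_LTR     TRUNCATED
#>             6             3             1
```

The census matches the planted composition exactly. Genotyping the six
proviral loci across the two strains recovers each planted event:

```r
loci <- calls[calls$structure_class == "FULL_PROVIRUS"]
pm <- polymorphismMatrix(sim$reference, loci, sim$strains, sim$model,
                         flank = 20000)
pm$status
#>           strain1           strain2
#> call_0002 "PRECISE_ABSENCE" "SHARED_FULL"
#> call_0003 "SHARED_FULL"     "SHARED_FULL"
#> call_0005 "SHARED_FULL"     "PRECISE_ABSENCE"
#> call_0006 "SHARED_FULL"     "SHARED_FULL"
#> call_0007 "SHARED_FULL"     "LOCUS_DELETED"
#> call_0009 "PRECISE_ABSENCE" "SHARED_FULL"
```

`call_0002`, `call_0005` and `call_0009` are insertionally polymorphic
(present in the reference, precisely absent — with a single TSD copy at the
empty site — in one strain). Gag assessment and recency statistics follow
the same pattern:

```r
gag <- assessGagCalls(sim$reference, calls, sim$model)
sum(gag$intact)          # copies encoding a near-full-length Gag
#> [1] 3

kept <- lengthFilter(calls, 1000, 8750)
proj <- anchorAlign(getCallSeqs(sim$reference, kept),
                    consensusSeq(sim$model))
d <- divergenceMatrix(proj)
st <- recencyStats(njTree(d), threshold = 0.01, dist = d)
round(st$median_terminal, 4)   # substitutions/site
#> [1] 0.0129
round(st$fraction_below, 3)    # fraction of copies below 0.01
#> [1] 0.429
```

Short terminal branches — many copies nearly identical to their closest
relative — are the tree-side signature of recent transposition.

The whole chain (simulate → annotate → gag → recency → polymorph → oligo)
also runs as one reproducible pipeline from a YAML configuration:

```r
runPipeline(system.file("extdata", "demo-config.yaml", package = "ervkit"))
```

which writes FASTA/BED/TSV/Newick outputs and a checksum manifest to the
configured output directory; reruns with the same seed are byte-identical.

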