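## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## Compact simulated study reused by annotator / gag / polymorphism tests.
smallSim <- function() {
  if (is.null(.fixtures$smallSim)) {
    .fixtures$smallSim <- simulateErvStudy(
      seed = 101, nFull = 8, nSolo = 4, nTrunc = 2, nChroms = 2,
      chromLen = 120000, nStrains = 2, nEvents = 6)
  }
  .fixtures$smallSim
}

smallCalls <- function() {
  if (is.null(.fixtures$smallCalls)) {
    sim <- smallSim()
    hits <- scanHits(sim$reference, sim$model)
    .fixtures$smallCalls <- defragment(hits)
  }
  .fixtures$smallCalls
}

## Map truth locus_id -> recovered call_id by coordinate overlap.
truthCallMap <- function(truth, calls) {
  trGr <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$start, truth$end))
  ov <- GenomicRanges::findOverlaps(trGr, calls)
  stats::setNames(calls$call_id[S4Vectors::subjectHits(ov)],
                  truth$locus_id[S4Vectors::queryHits(ov)])
}

## Tiny family for fast sequence-level unit tests.
tinyFam <- function() {
  if (is.null(.fixtures$tinyFam)) {
    .fixtures$tinyFam <- synthFamilyModel(
      seed = 5, ltrLen = 150L, gagAa = 120L, padUp = 60L, padDown = 60L,
      tsdLen = 5L)
  }
  .fixtures$tinyFam
}

## Expected polymorphism status implied by a strain truth row.
truthStatus <- function(structure_class) {
  c(FULL_PROVIRUS = "SHARED_FULL", SOLO_LTR = "SOLO_LTR",
    TRUNCATED = "SHARED_FULL", ABSENT = "PRECISE_ABSENCE",
    DELETED = "LOCUS_DELETED")[structure_class]
}

## Brute-force oracles -------------------------------------------------

## All ATG-initiated, stop-terminated ORFs on the sense strand.
bruteForceOrfs <- function(seq) {
  seq <- toupper(seq)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  n <- nchar(seq)
  for (s in seq_len(n - 2)) {
    if (substr(seq, s, s + 2) != "ATG") next
    i <- s + 3
    while (i + 2 <= n) {
      cod <- substr(seq, i, i + 2)
      if (cod %in% stops) {
        res[[length(res) + 1L]] <- list(start = s, end = i + 2,
                                        protein_len = (i - s) / 3)
        break
      }
      i <- i + 3
    }
  }
  res
}

## Longest TSD by brute force over every k in range.
bruteForceTsd <- function(seq, s, e, minTsd, maxTsd) {
  best <- NULL
  for (k in minTsd:maxTsd) {
    if (s - k < 1 || e + k > nchar(seq)) next
    l <- substr(seq, s - k, s - 1)
    r <- substr(seq, e + 1, e + k)
    if (l == r) best <- list(tsd_seq = l, length = k)
  }
  best
}

## Sliding-window count of site occurrences with <= mm mismatches.
bruteForceSiteHits <- function(site, seq, mm = 0L) {
  w <- nchar(site); n <- nchar(seq)
  if (n < w) return(integer(0))
  sv <- strsplit(site, "")[[1]]
  hits <- integer(0)
  for (p in seq_len(n - w + 1L)) {
    d <- sum(strsplit(substr(seq, p, p + w - 1L), "")[[1]] != sv)
    if (d <= mm) hits <- c(hits, p)
  }
  hits
}

randomDnaStr <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
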