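test_that("random genomes are deterministic, length-exact and composition-calibrated", {
  g1 <- makeRandomGenome(1, 1000, 0.5, seed = 7)
  g2 <- makeRandomGenome(1, 1000, 0.5, seed = 7)
  expect_identical(as.character(g1), as.character(g2))

  g <- makeRandomGenome(2, c(500, 300), 0.5, seed = 1)
  expect_equal(sum(Biostrings::width(g)), 800)
  expect_named(g, c("chr1", "chr2"))

  ## GC within 3 binomial standard deviations of the target
  g3 <- makeRandomGenome(1, 100000, 0.3, seed = 3)
  gc <- sum(Biostrings::letterFrequency(g3[[1]], c("G", "C"))) / 100000
  expect_lt(abs(gc - 0.3), 3 * sqrt(0.3 * 0.7 / 100000))

  expect_error(makeRandomGenome(1, 0, 0.5, 1), "positive")
  expect_error(makeRandomGenome(1, 100, 1.2, 1), "gc")
})

test_that("planting duplicates the target site and preserves sequence at zero divergence", {
  fam <- tinyFam()
  g <- makeRandomGenome(1, 5000, 0.5, seed = 2)
  res <- plantInsertion(g, fam, "chr1", 2000, divergence = 0)
  tr <- res$truth
  chrom <- as.character(res$genome[["chr1"]])
  tsd <- tsdLen(fam)

  expect_equal(nchar(chrom), 5000 + elementLength(fam) + tsd)
  expect_identical(substr(chrom, tr$start, tr$end),
                   as.character(consensusSeq(fam)))
  expect_identical(substr(chrom, tr$start - tsd, tr$start - 1), tr$tsd_seq)
  expect_identical(substr(chrom, tr$end + 1, tr$end + tsd), tr$tsd_seq)
  expect_identical(tr$structure_class, "FULL_PROVIRUS")
  expect_true(tr$gag_intact)

  ## zero-length TSD: no duplicated flanks, length grows by element only
  res0 <- plantInsertion(g, fam, "chr1", 2000, divergence = 0,
                         tsdLenUsed = 0L)
  expect_equal(nchar(as.character(res0$genome[["chr1"]])),
               5000 + elementLength(fam))
  expect_identical(res0$truth$tsd_seq, "")

  expect_error(plantInsertion(g, fam, "chr1", 6000), "out of range")
  expect_error(plantInsertion(g, fam, "chr1", 2000,
                              truncation = c(1, elementLength(fam))),
               "entire element")
})

test_that("divergence draws substitutions at the requested rate", {
  fam <- synthFamilyModel(seed = 9)      # ~3.2 kb element
  g <- makeRandomGenome(1, 20000, 0.5, seed = 4)
  res <- plantInsertion(g, fam, "chr1", 10000, divergence = 0.02, seed = 8)
  tr <- res$truth
  planted <- substr(as.character(res$genome[["chr1"]]), tr$start, tr$end)
  cons <- as.character(consensusSeq(fam))
  ham <- sum(strsplit(planted, "")[[1]] != strsplit(cons, "")[[1]])
  n <- nchar(cons)
  expect_lt(abs(ham - n * 0.02), 3 * sqrt(n * 0.02 * 0.98))
})

test_that("strain derivation inverts planting and keeps the books straight", {
  fam <- tinyFam()
  g <- makeRandomGenome(1, 8000, 0.5, seed = 6)
  res <- plantInsertion(g, fam, "chr1", 3000, divergence = 0)
  tr <- res$truth
  L <- length(ltrSeq(fam)); tsd <- tsdLen(fam)

  ## ABSENT_PRECISE restores the pre-integration chromosome byte-for-byte
  abs_ <- deriveStrain(res$genome, tr,
                       data.frame(locus_id = tr$locus_id,
                                  kind = "ABSENT_PRECISE"), fam, "sA")
  expect_identical(as.character(abs_$genome[["chr1"]]),
                   as.character(g[["chr1"]]))
  expect_identical(abs_$truth$structure_class, "ABSENT")

  ## SOLO_LTR_CONVERSION leaves TSD + one LTR + TSD
  solo <- deriveStrain(res$genome, tr,
                       data.frame(locus_id = tr$locus_id,
                                  kind = "SOLO_LTR_CONVERSION"), fam, "sB")
  st <- solo$truth
  chrom <- as.character(solo$genome[["chr1"]])
  expect_identical(substr(chrom, st$start, st$end),
                   as.character(ltrSeq(fam)))
  expect_identical(substr(chrom, st$start - tsd, st$start - 1), tr$tsd_seq)
  expect_identical(substr(chrom, st$end + 1, st$end + tsd), tr$tsd_seq)
  expect_identical(st$structure_class, "SOLO_LTR")

  ## LOCUS_DELETION shortens the chromosome by span + element + tsd
  del <- deriveStrain(res$genome, tr,
                      data.frame(locus_id = tr$locus_id,
                                 kind = "LOCUS_DELETION",
                                 deletion_span = 2000L), fam, "sC")
  expect_equal(nchar(as.character(del$genome[["chr1"]])),
               nchar(as.character(res$genome[["chr1"]])) -
                 (2000 + elementLength(fam) + tsd))
  expect_true(is.na(del$truth$start))

  expect_error(deriveStrain(res$genome, tr,
                            data.frame(locus_id = "nope",
                                       kind = "ABSENT_PRECISE"),
                            fam, "sD"), "unknown locus_id")
})

test_that("truth-table coordinates always slice correctly classified sequence", {
  sim <- smallSim()
  cons <- as.character(consensusSeq(sim$model))
  L <- length(ltrSeq(sim$model))
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    s <- substr(as.character(sim$reference[[tr$chrom]]), tr$start, tr$end)
    if (tr$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    if (tr$structure_class == "SOLO_LTR")
      expect_equal(nchar(s), L)
    if (tr$structure_class == "FULL_PROVIRUS") {
      expect_equal(nchar(s), nchar(cons))
      ## low divergence: the slice still matches the consensus closely
      d <- mean(strsplit(s, "")[[1]] != strsplit(cons, "")[[1]])
      expect_lt(d, 0.04)
    }
  }
})

test_that("nested insertions grow the host locus and are flagged", {
  fam <- tinyFam()
  g <- makeRandomGenome(1, 10000, 0.5, seed = 12)
  res <- plantInsertion(g, fam, "chr1", 4000, divergence = 0)
  host <- res$truth
  mid <- host$start + round((host$end - host$start) / 2)
  res2 <- plantInsertion(res$genome, fam, "chr1", mid, divergence = 0,
                         truth = res$truth, locusId = "inner")
  tr2 <- res2$truth
  expect_true(tr2$nested[tr2$locus_id == "inner"])
  expect_equal(tr2$end[1] - tr2$start[1] + 1,
               (host$end - host$start + 1) + elementLength(fam) +
                 tsdLen(fam))
})

test_that("truth table round-trips through the tab-separated format", {
  sim <- smallSim()
  f <- tempfile(fileext = ".tsv")
  writeTruthTable(sim$truth, f)
  back <- readTruthTable(f)
  expect_equal(back$start, sim$truth$start)
  expect_equal(back$tsd_seq, sim$truth$tsd_seq)
  bed <- tempfile(fileext = ".bed")
  truthToBed(sim$truth, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V2, sim$truth$start - 1L)  # BED is 0-based half-open
  expect_equal(b$V3, sim$truth$end)
})
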