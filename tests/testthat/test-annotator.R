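test_that("scanner recovers exact planted copies at their true coordinates", {
  fam <- tinyFam()
  g <- makeRandomGenome(1, 6000, 0.5, seed = 21)
  chrom <- as.character(g[["chr1"]])
  internal <- as.character(internalSeq(fam))
  g[["chr1"]] <- Biostrings::DNAString(
    paste0(substr(chrom, 1, 3000), internal, substr(chrom, 3001, 6000)))
  hits <- scanHits(g, fam, minHitLen = 50)
  ih <- hits[hits$part == "INTERNAL"]
  expect_length(ih, 1)
  expect_equal(GenomicRanges::start(ih), 3001)
  expect_equal(GenomicRanges::end(ih), 3000 + nchar(internal))
  expect_equal(ih$divergence_pct, 0)

  ## genome sharing no seed k-mer with the model yields nothing
  empty <- Biostrings::DNAStringSet(paste(rep("AC", 2000), collapse = ""))
  names(empty) <- "chr1"
  expect_length(scanHits(empty, fam, minHitLen = 50), 0)

  expect_error(scanHits(Biostrings::DNAStringSet(), fam), "empty genome")
})

test_that("scanner finds minus-strand copies with correct consensus coordinates", {
  fam <- tinyFam()
  g <- makeRandomGenome(1, 6000, 0.5, seed = 22)
  res <- plantInsertion(g, fam, "chr1", 2500, divergence = 0, strand = "-")
  hits <- scanHits(res$genome, fam, minHitLen = 50)
  expect_true(all(as.character(GenomicRanges::strand(hits)) == "-"))
  expect_setequal(unique(hits$part), c("LTR", "INTERNAL"))
  ih <- hits[hits$part == "INTERNAL"]
  expect_equal(ih$cons_start, 1L)
  expect_equal(ih$cons_end, length(internalSeq(fam)))
})

test_that("defragmentation merges canonical structures and respects the gap rule", {
  mk <- function(starts, ends, parts, cs, ce, strand = "+") {
    ervkit:::newHits("chr1", starts, ends, rep(strand, length(starts)),
                     rep("fam", length(starts)), parts, cs, ce,
                     rep(0, length(starts)), (ends - starts + 1) * 2)
  }
  ## LTR + INTERNAL + LTR adjacent -> one full provirus
  h <- mk(c(1000, 1401, 3001), c(1400, 3000, 3401),
          c("LTR", "INTERNAL", "LTR"), c(1, 1, 1), c(400, 1600, 400))
  calls <- defragment(h)
  expect_length(calls, 1)
  expect_identical(calls$structure_class, "FULL_PROVIRUS")
  expect_equal(calls$n_components, 3L)

  ## isolated LTR -> solo
  solo <- defragment(mk(5000, 5400, "LTR", 1, 400))
  expect_identical(solo$structure_class, "SOLO_LTR")

  ## two LTRs 100 kb apart never merge
  far <- defragment(mk(c(1000, 101000), c(1400, 101400), c("LTR", "LTR"),
                       c(1, 1), c(400, 400)), maxMergeGap = 500)
  expect_length(far, 2)
  expect_true(all(far$structure_class == "SOLO_LTR"))

  ## two complete adjacent LTRs do not fuse (no internal between them)
  adj <- defragment(mk(c(1000, 1450), c(1400, 1850), c("LTR", "LTR"),
                       c(1, 1), c(400, 400)))
  expect_length(adj, 2)

  ## but split fragments of one LTR do rejoin (consensus continuity)
  frag <- defragment(mk(c(1000, 1230), c(1200, 1430), c("LTR", "LTR"),
                        c(1, 202), c(201, 400)))
  expect_length(frag, 1)
  expect_identical(frag$structure_class, "SOLO_LTR")

  ## empty input
  expect_length(defragment(ervkit:::newHits()), 0)
})

test_that("every hit lands in exactly one call (partition invariant)", {
  sim <- smallSim()
  hits <- scanHits(sim$reference, sim$model)
  calls <- smallCalls()
  compIds <- unlist(lapply(seq_along(calls), function(i) {
    comp <- calls$components[[i]]
    paste(as.character(GenomicRanges::seqnames(comp)),
          GenomicRanges::start(comp), comp$part)
  }))
  hitIds <- paste(as.character(GenomicRanges::seqnames(hits)),
                  GenomicRanges::start(hits), hits$part)
  expect_setequal(compIds, hitIds)
  expect_equal(sum(lengths(calls$components)), length(hits))
})

test_that("classification covers the canonical part patterns", {
  calls <- smallCalls()
  for (i in seq_along(calls)) {
    parts <- strsplit(calls$parts[i], ",")[[1]]
    want <- if (identical(rle(parts)$values, c("LTR", "INTERNAL", "LTR")))
      "FULL_PROVIRUS"
    else if (identical(unique(parts), "LTR") && length(parts) == 1)
      "SOLO_LTR" else "TRUNCATED"
    expect_identical(calls$structure_class[i], want)
  }
})

test_that("length filter applies the published windows and is idempotent", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 100, 5000), width = c(1200, 900, 9000)))
  gr$call_id <- paste0("c", 1:3)
  keep1 <- lengthFilter(gr, 1000, 8750)   # the tighter family window
  expect_identical(keep1$call_id, "c1")   # 1200 bp kept; 900 and 9000 out
  keep2 <- lengthFilter(gr, 1000, 9350)   # the larger-element window
  expect_setequal(keep2$call_id, c("c1", "c3"))
  expect_identical(lengthFilter(keep2, 1000, 9350)$call_id, keep2$call_id)
  expect_error(lengthFilter(gr, -1, 100), "non-negative")
})

test_that("TSD detection matches brute force and the generator round-trips", {
  sim <- smallSim()
  calls <- smallCalls()
  tr <- sim$truth
  map <- truthCallMap(tr, calls)
  for (k in seq_len(nrow(tr))) {
    call <- calls[calls$call_id == map[tr$locus_id[k]]]
    if (length(call) != 1) next
    got <- detectTsd(sim$reference, call)
    expect_false(is.null(got))
    expect_identical(got$tsd_seq, tr$tsd_seq[k])
    ## agreement with exhaustive scan over k
    bf <- bruteForceTsd(as.character(sim$reference[[tr$chrom[k]]]),
                        GenomicRanges::start(call),
                        GenomicRanges::end(call), 2, 20)
    expect_identical(got, bf)
  }

  ## constructed flanks with no shared prefix -> no TSD
  g <- Biostrings::DNAStringSet(paste0(strrep("A", 50), strrep("G", 30),
                                       strrep("C", 50)))
  names(g) <- "chr1"
  fake <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 80))
  expect_null(detectTsd(g, fake))

  ## engineered 4-mer and 6-mer duplications: the longest wins
  core <- randomDnaStr(40, seed = 31)
  g2 <- Biostrings::DNAStringSet(paste0("TTTTCACGTA", core, "CACGTATTTT"))
  names(g2) <- "chr1"
  call2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 10 + 40))
  got2 <- detectTsd(g2, call2, minTsd = 2, maxTsd = 8)
  expect_identical(got2$tsd_seq, "CACGTA")
  expect_equal(got2$length, 6)
})

test_that("census agrees exactly with the planted truth", {
  sim <- smallSim()
  calls <- smallCalls()
  cen <- censusCalls(calls)
  want <- table(sim$truth$structure_class)
  expect_equal(cen$by_class[["FULL_PROVIRUS"]],
               as.integer(want[["FULL_PROVIRUS"]]))
  expect_equal(cen$by_class[["SOLO_LTR"]], as.integer(want[["SOLO_LTR"]]))
  expect_equal(cen$by_class[["TRUNCATED"]], as.integer(want[["TRUNCATED"]]))
  expect_equal(censusCalls(ervkit:::emptyCalls())$by_class,
               c(FULL_PROVIRUS = 0L, SOLO_LTR = 0L, TRUNCATED = 0L))
})

test_that("RepeatMasker .out tables are parsed, strand-converted and deduplicated", {
  out <- c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin  end  (left)   repeat  class/family  begin end (left) ID",
    "",
    "  800  1.5  0.0  0.0  chr1  1001  1400  (8600)  +  famX_LTR  LTR/ERV  1  400  (0)  1",
    "  750  2.0  0.0  0.0  chr1  1005  1400  (8600)  +  famX_LTR  LTR/ERV  5  400  (0)  2  *",
    " 2400  1.0  0.0  0.0  chr1  1401  3000  (7000)  C  famX_I  LTR/ERV  (0)  1600  1  3")
  f <- tempfile(fileext = ".out")
  writeLines(out, f)
  hits <- readRepeatMaskerOut(f)
  expect_length(hits, 2)   # the asterisked overlap drops out
  ltr <- hits[hits$part == "LTR"]
  expect_equal(GenomicRanges::start(ltr), 1001)
  expect_equal(ltr$score, 800)
  int <- hits[hits$part == "INTERNAL"]
  expect_identical(as.character(GenomicRanges::strand(int)), "-")
  expect_equal(int$cons_start, 1L)
  expect_equal(int$cons_end, 1600L)
  expect_identical(unique(hits$family), "famX")
})
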