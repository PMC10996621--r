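test_that("consensus projection is exact on identity and marks deletions as gaps", {
  fam <- tinyFam()
  cons <- consensusSeq(fam)
  consChr <- as.character(cons)

  proj <- anchorAlign(c(id = consChr), cons)
  expect_identical(unname(proj["id"]), consChr)

  ## 10-bp internal deletion -> exactly 10 gap columns at those positions
  del <- paste0(substr(consChr, 1, 200), substr(consChr, 211, nchar(consChr)))
  pd <- anchorAlign(c(d = del), cons)
  v <- strsplit(unname(pd["d"]), "")[[1]]
  expect_equal(sum(v == "-"), 10)

  ## a sequence unrelated to the consensus is excluded with a warning
  expect_warning(
    out <- anchorAlign(c(bad = randomDnaStr(300, 61)), cons),
    "alignable")
  expect_length(out, 0)
})

test_that("projected pairwise differences track direct alignment on diverged copies", {
  fam <- tinyFam()
  cons <- consensusSeq(fam)
  set.seed(71)
  mutate <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  a <- mutate(as.character(cons), 0.02)
  b <- mutate(as.character(cons), 0.02)
  proj <- anchorAlign(c(a = a, b = b), cons)
  pProj <- pDistance(proj["a"], proj["b"], minShared = 100)
  ## direct count (equal length, no indels): exact mismatch fraction
  pDirect <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(pProj, pDirect, tolerance = 0.01 * max(pDirect, 1e-9))
})

test_that("p-distance and Jukes-Cantor behave as the closed forms dictate", {
  expect_equal(pDistance("ACGT", "ACGT", minShared = 1), 0)
  expect_equal(pDistance("ACGT", "ACGA", minShared = 1), 0.25)
  expect_true(is.na(pDistance("ACGT", "ACGA", minShared = 100)))

  expect_equal(jcDistance(0), 0)
  expect_equal(jcDistance(0.25), -0.75 * log(1 - (4 / 3) * 0.25),
               tolerance = 1e-12)
  expect_equal(jcDistance(0.25), 0.30409883, tolerance = 1e-8)
  expect_error(jcDistance(0.8), "undefined")

  ## monotone and >= p on [0, 3/4)
  ps <- seq(0, 0.7, by = 0.01)
  js <- jcDistance(ps)
  expect_true(all(diff(js) > 0))
  expect_true(all(js >= ps))
})

test_that("neighbor-joining recovers additive trees exactly", {
  ## 2 taxa: one edge split evenly
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  t2 <- njTree(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  ## 4 taxa from ((A:1,B:2):1,(C:3,D:4)): pairwise path lengths
  labs <- c("A", "B", "C", "D")
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, byrow = TRUE,
               dimnames = list(labs, labs))
  t4 <- njTree(d4)
  ## terminal branches 1,2,3,4 and internal branch 1, to 1e-9
  st <- recencyStats(t4, threshold = 0.01)
  expect_equal(unname(st$terminal_branches[labs]), c(1, 2, 3, 4),
               tolerance = 1e-9)
  internal <- t4$edge.length[!(t4$edge[, 2] %in% seq_len(4))]
  expect_equal(unname(internal), 1, tolerance = 1e-9)
  ## path lengths on the tree reproduce the input matrix exactly
  paths <- ape::cophenetic.phylo(t4)[labs, labs]
  expect_equal(paths, d4, tolerance = 1e-9)

  ## ties resolve deterministically
  dEq <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(dEq) <- 0
  expect_identical(ape::write.tree(njTree(dEq)),
                   ape::write.tree(njTree(dEq)))

  expect_error(njTree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("recency statistics summarize terminal branches and degenerate inputs", {
  ## identical copies: star tree with zero branches
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  st <- recencyStats(njTree(d))
  expect_equal(st$median_terminal, 0)
  expect_equal(st$fraction_below, 1)

  ## single copy: flagged degenerate, no crash
  st1 <- recencyStats(NULL)
  expect_true(st1$degenerate)
  expect_true(is.na(st1$median_terminal))

  ## two age classes at ~0.005 and ~0.05 substitutions/site: about half
  ## the copies sit below the 0.01 threshold
  fam <- tinyFam()
  cons <- as.character(consensusSeq(fam))
  set.seed(81)
  mutate <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  copies <- c(vapply(1:10, function(i) mutate(cons, 0.005), ""),
              vapply(1:10, function(i) mutate(cons, 0.05), ""))
  names(copies) <- paste0("c", 1:20)
  proj <- anchorAlign(copies, consensusSeq(fam))
  dm <- divergenceMatrix(proj)
  st2 <- recencyStats(njTree(dm), threshold = 0.01, dist = dm)
  expect_lt(abs(st2$fraction_below - 0.5), 0.2)
  expect_length(st2$nearest_neighbor, 20)
})

test_that("LTR-LTR divergence dates a provirus from its own two LTRs", {
  fam <- tinyFam()
  g <- makeRandomGenome(1, 8000, 0.5, seed = 91)
  res <- plantInsertion(g, fam, "chr1", 3000, divergence = 0)
  hits <- scanHits(res$genome, fam, minHitLen = 50)
  call <- defragment(hits)
  expect_identical(call$structure_class, "FULL_PROVIRUS")
  v0 <- ltrLtrDivergence(call, res$genome)
  expect_equal(v0$p, 0)
  expect_equal(v0$jc, 0)

  ## plant 2 substitutions into one 150-bp LTR -> p = 2/150
  chrom <- as.character(res$genome[["chr1"]])
  tr <- res$truth
  for (off in c(10, 50)) {
    pos <- tr$start + off
    old <- substr(chrom, pos, pos)
    substr(chrom, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  g2 <- res$genome
  g2[["chr1"]] <- Biostrings::DNAString(chrom)
  v2 <- ltrLtrDivergence(call, g2)
  expect_equal(v2$p, 2 / 150, tolerance = 1e-9)
  expect_equal(v2$jc, jcDistance(2 / 150), tolerance = 1e-9)

  solo <- call
  solo$components <- GenomicRanges::GRangesList(
    call$components[[1]][call$components[[1]]$part == "INTERNAL"])
  expect_error(ltrLtrDivergence(solo, res$genome), "missing LTR")
})

test_that("near-full-length counting reproduces planted per-assembly copy numbers", {
  ## two synthetic assemblies carrying 4 and 44 near-full-length copies;
  ## the per-assembly window count must recover them and their range
  fam <- tinyFam()
  mkAssembly <- function(n, seed) {
    len <- max(60000, n * 1300)
    g <- makeRandomGenome(1, len, 0.5, seed = seed)
    pos <- round(seq(1000, len - 1000, length.out = n))
    ev <- data.frame(chrom = "chr1", pos = pos)
    plantInsertions(g, fam, ev, seed = seed)
  }
  low <- mkAssembly(4, 201)
  high <- mkAssembly(44, 202)
  callsOf <- function(sim) defragment(scanHits(sim$genome, fam,
                                               minHitLen = 50))
  sets <- list(breedA = callsOf(low), breedB = callsOf(high),
               empty = ervkit:::emptyCalls())
  win <- c(round(0.9 * elementLength(fam)), round(1.1 * elementLength(fam)))
  cnt <- countNearFullLength(sets, win[1], win[2])
  expect_equal(unname(cnt$counts["breedA"]), 4L)
  expect_equal(unname(cnt$counts["breedB"]), 44L)
  expect_equal(unname(cnt$counts["empty"]), 0L)
  expect_equal(cnt$min, 0L)
  expect_equal(cnt$max, 44L)

  ## a window with min above a call's length excludes it
  short <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
  short$call_id <- "s"
  expect_equal(unname(countNearFullLength(list(x = short),
                                          2333, 5133)$counts["x"]), 0L)
})
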