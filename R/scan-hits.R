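#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

## Alignment scoring used by the scanner (BLAST-like; tolerant of the
## few-percent divergence expected within a young family).
scanSubstMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = TRUE)
}

newHits <- function(chrom = character(), start = integer(),
                    end = integer(), strand = character(),
                    family = character(), part = character(),
                    consStart = integer(), consEnd = integer(),
                    divergencePct = numeric(), score = numeric()) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr) <- DataFrame(family = family, part = part,
                         cons_start = as.integer(consStart),
                         cons_end = as.integer(consEnd),
                         divergence_pct = divergencePct, score = score)
  gr
}

#' Scan a genome for fragments of an ERV family
#'
#' A k-mer-anchored extend-and-trim matcher: exact seed k-mers drawn from
#' the consensus LTR and internal sequences are located genome-wide
#' (both strands), seed matches are clustered per candidate locus, and each
#' cluster is refined by local alignment of the consensus part against the
#' candidate region. Suited to desk-scale genomes and young (low-divergence)
#' families; it stands in for an external repeat annotator.
#'
#' @param genome A named \code{DNAStringSet}.
#' @param model An \code{\link{ErvFamilyModel}}.
#' @param minSeedKmer Exact seed length in bp.
#' @param minHitLen Minimum reported hit length in bp.
#' @param maxDivergence Maximum divergence of a reported hit (fraction).
#' @return A \code{GRanges} of fragment hits with metadata columns
#'   \code{family}, \code{part} (LTR/INTERNAL), \code{cons_start},
#'   \code{cons_end} (1-based consensus coordinates of the matched part),
#'   \code{divergence_pct} and \code{score}.
#' @export
scanHits <- function(genome, model, minSeedKmer = 15L, minHitLen = 80L,
                     maxDivergence = 0.1) {
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  parts <- list(LTR = ltrSeq(model), INTERNAL = internalSeq(model))
  if (any(vapply(parts, length, 1L) <= minSeedKmer))
    stop("model part shorter than minSeedKmer")
  mat <- scanSubstMat()
  out <- list()

  for (partName in names(parts)) {
    partSeq <- parts[[partName]]
    plen <- length(partSeq)
    for (str in c("+", "-")) {
      probe <- if (str == "+") partSeq
               else Biostrings::reverseComplement(partSeq)
      offs <- seq(1L, plen - minSeedKmer + 1L, by = minSeedKmer)
      seeds <- Biostrings::DNAStringSet(probe,
        start = offs, width = minSeedKmer)
      pd <- Biostrings::PDict(seeds)
      for (chrom in names(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[chrom]])
        cand <- integer(0)
        for (i in seq_along(m)) {
          s <- BiocGenerics::start(m[[i]])
          if (length(s)) cand <- c(cand, s - (offs[i] - 1L))
        }
        if (!length(cand)) next
        cand <- sort(cand)
        grp <- cumsum(c(1L, diff(cand) > 200L))
        for (g in unique(grp)) {
          c0 <- min(cand[grp == g])
          a <- max(1L, c0 - 30L)
          b <- min(length(genome[[chrom]]), c0 + plen + 29L)
          region <- Biostrings::subseq(genome[[chrom]], a, b)
          aln <- Biostrings::pairwiseAlignment(
            probe, region, type = "local", substitutionMatrix = mat,
            gapOpening = 5, gapExtension = 2)
          sw <- Biostrings::subject(aln)
          pw <- Biostrings::pattern(aln)
          gStart <- a + BiocGenerics::start(sw) - 1L
          gEnd <- a + BiocGenerics::end(sw) - 1L
          ncolAln <- Biostrings::nchar(aln)
          div <- 100 * (1 - Biostrings::nmatch(aln) / ncolAln)
          if (gEnd - gStart + 1L < minHitLen) next
          if (div > 100 * maxDivergence) next
          ps <- BiocGenerics::start(pw); pe <- BiocGenerics::end(pw)
          ## snap to the consensus part boundary when a mutated terminal
          ## base made the local alignment trim a few bp; the extension
          ## stays within the part's consensus span, never host sequence
          if (ps > 1L && ps - 1L <= 5L) {
            ext <- min(ps - 1L, gStart - 1L)
            gStart <- gStart - ext; ps <- ps - ext
          }
          if (pe < plen && plen - pe <= 5L) {
            ext <- min(plen - pe, length(genome[[chrom]]) - gEnd)
            gEnd <- gEnd + ext; pe <- pe + ext
          }
          if (str == "-") {
            cs <- plen - pe + 1L; ce <- plen - ps + 1L
          } else {
            cs <- ps; ce <- pe
          }
          out[[length(out) + 1L]] <- newHits(
            chrom, gStart, gEnd, str, familyName(model), partName,
            cs, ce, round(div, 3), Biostrings::score(aln))
        }
      }
    }
  }
  if (!length(out)) return(newHits())
  hits <- suppressWarnings(do.call(c, out))
  BiocGenerics::sort(hits, ignore.strand = TRUE)
}
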