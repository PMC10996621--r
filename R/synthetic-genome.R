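#' Generate a random genome
#'
#' Samples chromosomes of the requested lengths with independent bases at a
#' target GC fraction. Deterministic for a fixed seed.
#'
#' @param nChroms Number of chromosomes.
#' @param lengths Integer vector of chromosome lengths in bp (recycled to
#'   \code{nChroms} if length 1).
#' @param gc Target GC fraction, in (0, 1).
#' @param seed Integer seed.
#' @return A named \code{\link[Biostrings]{DNAStringSet}} (\code{chr1} ...).
#' @examples
#' g <- makeRandomGenome(2, c(500, 300), gc = 0.5, seed = 1)
#' sum(Biostrings::width(g))
#' @export
makeRandomGenome <- function(nChroms, lengths, gc = 0.5, seed = 1L) {
  if (length(lengths) == 1L) lengths <- rep(lengths, nChroms)
  stopifnot(length(lengths) == nChroms)
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  seqs <- withSeed(seed, lapply(lengths, randomDna, gc = gc))
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- paste0("chr", seq_len(nChroms))
  g
}

emptyTruthTable <- function() {
  data.frame(
    locus_id = character(), genome_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    structure_class = character(), tsd_seq = character(),
    divergence = numeric(), gag_intact = logical(), nested = logical(),
    stringsAsFactors = FALSE
  )
}

## Structure class implied by a truncation interval in element coordinates.
## LTR1 = [1, L], internal = [L+1, L+I], LTR2 = [L+I+1, 2L+I].
truncationClass <- function(model, truncation) {
  L <- length(ltrSeq(model)); I <- length(internalSeq(model))
  if (is.null(truncation)) return("FULL_PROVIRUS")
  a <- truncation[1]; b <- truncation[2]
  if (a < 1 || b > 2L * L + I || a > b)
    stop("truncation interval outside element coordinates")
  if (a == 1 && b == 2L * L + I) stop("truncation removes entire element")
  keep <- setdiff(seq_len(2L * L + I), a:b)
  ltr1 <- all(seq_len(L) %in% keep)
  int <- all((L + 1L):(L + I) %in% keep)
  ltr2 <- all((L + I + 1L):(2L * L + I) %in% keep)
  anyInt <- any((L + 1L):(L + I) %in% keep)
  if (ltr1 && int && ltr2) return("FULL_PROVIRUS")
  if ((ltr1 && !anyInt && !ltr2 && !any((L + I + 1L):(2L * L + I) %in% keep)) ||
      (ltr2 && !anyInt && !any(seq_len(L) %in% keep)))
    return("SOLO_LTR")
  "TRUNCATED"
}

## Gag intactness of a (possibly truncated) mutated element, sense strand.
## Requires the model to know its ORF start; the first codon must still be
## ATG and the first in-frame stop must not precede `fraction` of the
## expected protein length.
gagIntactTruth <- function(elementSense, model, truncation = NULL,
                           fraction = 0.95) {
  if (is.na(model@gagOrfStart) || is.na(expectedGagAa(model))) return(NA)
  L <- length(ltrSeq(model))
  aa <- expectedGagAa(model)
  orfStart <- L + model@gagOrfStart            # element coords, 1-based
  orfEnd <- orfStart + 3L * (aa + 1L) - 1L     # incl. terminal stop
  if (!is.null(truncation)) {
    a <- truncation[1]; b <- truncation[2]
    if (a <= orfEnd && b >= orfStart) return(FALSE)  # ORF clipped
    if (b < orfStart) {
      shift <- b - a + 1L
      orfStart <- orfStart - shift
      orfEnd <- orfEnd - shift
    }
  }
  if (orfEnd > nchar(elementSense)) return(FALSE)
  orf <- substr(elementSense, orfStart, orfEnd)
  codons <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
  if (codons[1] != "ATG") return(FALSE)
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  stops <- stops[stops <= aa]                  # internal positions only
  if (!length(stops)) return(TRUE)
  (min(stops) - 1L) >= ceiling(fraction * aa)
}

#' Plant one ERV insertion into a genome
#'
#' Inserts a (possibly truncated, possibly diverged) copy of the family
#' element at the given position, duplicating the \code{tsdLen} bp found at
#' the site on both flanks — the target-site duplication (TSD) created by
#' retroviral integration. The chromosome grows by element length +
#' \code{tsdLen}. Divergence is applied as independent uniform substitutions
#' (no indels), matching a substitutions-per-site measure of copy age.
#'
#' @param genome A named \code{DNAStringSet}.
#' @param model An \code{\link{ErvFamilyModel}}.
#' @param chrom Chromosome name.
#' @param pos Insertion point: the element is inserted after base
#'   \code{pos} (1-based; 0 = chromosome start). The \code{tsdLen} bases at
#'   \code{pos + 1 ...} become the TSD.
#' @param divergence Substitutions/site in [0, 0.5) applied to the element.
#' @param strand \code{"+"} or \code{"-"}; minus-strand copies are inserted
#'   as the reverse complement.
#' @param truncation Optional \code{c(start, end)} 1-based closed interval
#'   of element coordinates removed before mutation (e.g. removing
#'   internal + one LTR yields a solo LTR).
#' @param tsdLenUsed TSD length for this event; defaults to the model's.
#' @param locusId Locus identifier (autogenerated if \code{NULL}).
#' @param genomeId Genome identifier recorded in the truth table.
#' @param truth Existing truth table to update (coordinates of downstream
#'   rows are shifted; a row whose element contains \code{pos} is grown and
#'   the new row is flagged \code{nested}).
#' @param seed Optional integer seed for the substitution draw.
#' @return \code{list(genome = <DNAStringSet>, truth = <data.frame>)}; the
#'   last row of \code{truth} describes the new insertion (1-based closed
#'   element coordinates, excluding the TSD copies, which sit immediately
#'   outside).
#' @export
plantInsertion <- function(genome, model, chrom, pos, divergence = 0,
                           strand = "+", truncation = NULL,
                           tsdLenUsed = NULL, locusId = NULL,
                           genomeId = "ref", truth = NULL, seed = NULL) {
  stopifnot(chrom %in% names(genome))
  if (is.null(truth)) truth <- emptyTruthTable()
  tsd <- as.integer(tsdLenUsed %||% tsdLen(model))
  chromSeq <- as.character(genome[[chrom]])
  len <- nchar(chromSeq)
  if (pos < 0 || pos + tsd > len)
    stop("insertion position out of range (need pos in [0, length - tsdLen])")
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)")

  cls <- truncationClass(model, truncation)
  element <- as.character(consensusSeq(model))
  if (!is.null(truncation))
    element <- paste0(substr(element, 1, truncation[1] - 1L),
                      substr(element, truncation[2] + 1L, nchar(element)))
  mut <- if (is.null(seed)) mutateSeq(element, divergence)
         else withSeed(seed, mutateSeq(element, divergence))
  elementSense <- mut$seq
  gag <- if (cls == "SOLO_LTR") FALSE
         else gagIntactTruth(elementSense, model, truncation)
  inserted <- if (strand == "-") revcompChr(elementSense) else elementSense

  site <- substr(chromSeq, pos + 1L, pos + tsd)   # "" when tsd == 0
  newSeq <- paste0(substr(chromSeq, 1, pos + tsd), inserted,
                   substr(chromSeq, pos + 1L, len))
  genome[[chrom]] <- Biostrings::DNAString(newSeq)

  inc <- nchar(inserted) + tsd
  idx <- truth$genome_id == genomeId & truth$chrom == chrom & !is.na(truth$start)
  nested <- FALSE
  if (any(idx)) {
    host <- idx & truth$start <= pos & truth$end > pos
    after <- idx & truth$start > pos
    truth$end[host] <- truth$end[host] + inc
    truth$start[after] <- truth$start[after] + inc
    truth$end[after] <- truth$end[after] + inc
    nested <- any(host)
  }
  if (is.null(locusId)) locusId <- sprintf("locus_%04d", nrow(truth) + 1L)
  row <- data.frame(
    locus_id = locusId, genome_id = genomeId, chrom = chrom,
    start = pos + tsd + 1L, end = pos + tsd + nchar(inserted),
    strand = strand, structure_class = cls, tsd_seq = site,
    divergence = divergence,
    gag_intact = if (is.na(gag)) NA else isTRUE(gag), nested = nested,
    stringsAsFactors = FALSE
  )
  list(genome = genome, truth = rbind(truth, row))
}

#' Plant a batch of insertions
#'
#' Positions refer to the \emph{original} genome; events are applied from
#' highest to lowest coordinate so that all positions stay valid. Nested
#' events (a position inside another event's element) are not expressible in
#' original coordinates; plant those with a separate \code{plantInsertion}
#' call on the result.
#'
#' @param genome A named \code{DNAStringSet}.
#' @param model An \code{ErvFamilyModel}.
#' @param events \code{data.frame} with columns \code{chrom}, \code{pos} and
#'   optionally \code{divergence}, \code{strand}, \code{trunc_start},
#'   \code{trunc_end}, \code{locus_id}.
#' @param genomeId Genome identifier for the truth table.
#' @param truth Optional truth table to extend.
#' @param seed Integer seed; per-event seeds are derived from it.
#' @return \code{list(genome, truth)} as in \code{\link{plantInsertion}}.
#' @export
plantInsertions <- function(genome, model, events, genomeId = "ref",
                            truth = NULL, seed = 1L) {
  if (is.null(truth)) truth <- emptyTruthTable()
  if (!nrow(events)) return(list(genome = genome, truth = truth))
  if (is.null(events$divergence)) events$divergence <- 0
  if (is.null(events$strand)) events$strand <- "+"
  if (is.null(events$locus_id))
    events$locus_id <- sprintf("locus_%04d", seq_len(nrow(events)) + nrow(truth))
  if (anyDuplicated(events[, c("chrom", "pos")]))
    stop("duplicate insertion positions on one chromosome")
  ord <- order(events$chrom, -events$pos)
  for (i in ord) {
    ev <- events[i, ]
    trunc <- NULL
    if (!is.null(ev$trunc_start) && !is.na(ev$trunc_start))
      trunc <- c(ev$trunc_start, ev$trunc_end)
    res <- plantInsertion(genome, model, ev$chrom, ev$pos,
                          divergence = ev$divergence, strand = ev$strand,
                          truncation = trunc, locusId = ev$locus_id,
                          genomeId = genomeId, truth = truth,
                          seed = deriveSeed(seed, paste0("plant", i)))
    genome <- res$genome
    truth <- res$truth
  }
  list(genome = genome, truth = truth)
}

#' Derive a strain genome from a reference with planted loci
#'
#' Applies presence/absence events to reference loci, emulating the
#' insertional polymorphism observed between individuals of one species:
#' \describe{
#'   \item{ABSENT_PRECISE}{restores the pre-integration site exactly —
#'     the element and one TSD copy are removed, leaving a single copy of
#'     the target site (the empty-allele hallmark).}
#'   \item{SOLO_LTR_CONVERSION}{replaces LTR + internal + LTR by the single
#'     5' LTR, both TSD copies retained — the product of ectopic
#'     recombination between the two LTRs of a provirus.}
#'   \item{LOCUS_DELETION}{removes the element, its TSD and
#'     \code{deletion_span} bp of flanking sequence — transpositional
#'     history at such a locus is no longer determinable.}
#'   \item{NOVEL_INSERTION}{plants a new insertion present only in the
#'     strain (columns \code{chrom}, \code{position}, \code{divergence}).}
#' }
#'
#' @param genome Reference \code{DNAStringSet}.
#' @param truth Truth table for the reference genome (one \code{genome_id}).
#' @param events \code{data.frame} with columns \code{locus_id},
#'   \code{kind}, and optionally \code{deletion_span}, \code{chrom},
#'   \code{position}, \code{divergence}.
#' @param model The \code{ErvFamilyModel} used to plant the reference.
#' @param strainId Identifier of the derived genome.
#' @param seed Integer seed (used by NOVEL_INSERTION draws).
#' @return \code{list(genome, truth)} where \code{truth} rows carry
#'   \code{genome_id = strainId} and classes
#'   FULL_PROVIRUS/SOLO_LTR/TRUNCATED/ABSENT/DELETED.
#' @export
deriveStrain <- function(genome, truth, events, model, strainId,
                         seed = 1L) {
  refId <- unique(truth$genome_id)
  stopifnot(length(refId) == 1L)
  if (anyDuplicated(events$locus_id[events$kind != "NOVEL_INSERTION"]))
    stop("overlapping events on one locus")
  st <- truth
  st$genome_id <- strainId
  L <- length(ltrSeq(model))

  coordOf <- function(ev) {
    if (ev$kind == "NOVEL_INSERTION") return(ev$position)
    r <- st[st$locus_id == ev$locus_id, ]
    if (!nrow(r)) stop("unknown locus_id: ", ev$locus_id)
    r$start
  }
  ord <- order(-vapply(seq_len(nrow(events)), function(i) coordOf(events[i, ]),
                       numeric(1)))
  shiftAfter <- function(st, chrom, from, delta) {
    idx <- st$chrom == chrom & !is.na(st$start) & st$start > from
    st$start[idx] <- st$start[idx] + delta
    st$end[idx] <- st$end[idx] + delta
    st
  }
  cut <- function(seq, a, b) paste0(substr(seq, 1, a - 1L),
                                    substr(seq, b + 1L, nchar(seq)))

  for (i in ord) {
    ev <- events[i, ]
    if (ev$kind == "NOVEL_INSERTION") {
      res <- plantInsertion(genome, model, ev$chrom, ev$position,
                            divergence = ev$divergence %||% 0,
                            locusId = paste0(strainId, "_novel_", i),
                            genomeId = strainId, truth = st,
                            seed = deriveSeed(seed, paste0("novel", i)))
      genome <- res$genome; st <- res$truth
      next
    }
    j <- which(st$locus_id == ev$locus_id)
    if (!length(j)) stop("unknown locus_id: ", ev$locus_id)
    r <- st[j, ]
    tsd <- nchar(r$tsd_seq)
    seq <- as.character(genome[[r$chrom]])
    if (ev$kind == "SOLO_LTR_CONVERSION") {
      if (r$structure_class != "FULL_PROVIRUS")
        stop("SOLO_LTR_CONVERSION requires a FULL_PROVIRUS locus")
      seq <- cut(seq, if (r$strand == "+") r$start + L else r$start,
                 if (r$strand == "+") r$end else r$end - L)
      delta <- -(r$end - r$start + 1L - L)
      st[j, c("end", "structure_class", "gag_intact")] <-
        list(r$start + L - 1L, "SOLO_LTR", FALSE)
      st <- shiftAfter(st, r$chrom, r$end, delta)
      genome[[r$chrom]] <- Biostrings::DNAString(seq)
    } else if (ev$kind == "ABSENT_PRECISE") {
      seq <- cut(seq, r$start, r$end + tsd)
      delta <- -(r$end - r$start + 1L + tsd)
      st$structure_class[j] <- "ABSENT"
      st$start[j] <- r$start - tsd
      st$end[j] <- r$start - 1L          # the single remaining site copy
      st$gag_intact[j] <- FALSE
      st <- shiftAfter(st, r$chrom, r$end, delta)
      genome[[r$chrom]] <- Biostrings::DNAString(seq)
    } else if (ev$kind == "LOCUS_DELETION") {
      span <- ev$deletion_span
      if (is.null(span) || is.na(span)) span <- 2000L
      a <- max(1L, r$start - tsd - floor(span / 2))
      b <- min(nchar(seq), r$end + ceiling(span / 2))
      other <- st$chrom == r$chrom & !is.na(st$start) &
        st$locus_id != r$locus_id & st$start <= b & st$end >= a
      if (any(other)) stop("deletion span overlaps another locus")
      seq <- cut(seq, a, b)
      st$structure_class[j] <- "DELETED"
      st$start[j] <- NA_integer_; st$end[j] <- NA_integer_
      st$gag_intact[j] <- FALSE
      st <- shiftAfter(st, r$chrom, b, -(b - a + 1L))
      genome[[r$chrom]] <- Biostrings::DNAString(seq)
    } else {
      stop("unknown strain event kind: ", ev$kind)
    }
  }
  list(genome = genome, truth = st)
}

#' Truth-table and genome I/O
#'
#' Truth tables are written as tab-separated text with a header; genomes as
#' multi-FASTA; planted loci additionally as BED6 (0-based half-open, score
#' column carries divergence in percent).
#'
#' @param truth A truth table \code{data.frame}.
#' @param path Output path.
#' @return The path, invisibly (\code{readTruthTable} returns the table).
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(tsd_seq = "character"))
}

#' @rdname writeTruthTable
#' @export
truthToBed <- function(truth, path) {
  ok <- !is.na(truth$start)
  bed <- data.frame(truth$chrom[ok], truth$start[ok] - 1L, truth$end[ok],
                    truth$locus_id[ok],
                    round(100 * truth$divergence[ok], 2), truth$strand[ok])
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
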