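#' Extract a locus with flanking sequence
#'
#' Returns the left flank, element and right flank of a reference locus;
#' their concatenation reproduces the reference region exactly. Flanks
#' are clipped (with a warning) at chromosome ends.
#'
#' @param genome A named \code{DNAStringSet}.
#' @param call A single-element call \code{GRanges}.
#' @param flank Flank length in bp (default 50 kb, a region wide enough
#'   to anchor a locus uniquely in another assembly of the same species).
#' @return \code{list(left, element, right)} of character sequences.
#' @export
extractLocus <- function(genome, call, flank = 50000L) {
  stopifnot(length(call) == 1L)
  seq <- genome[[as.character(seqnames(call))]]
  s <- start(call); e <- end(call)
  a <- max(1L, s - flank); b <- min(length(seq), e + flank)
  if (s - flank < 1L || e + flank > length(seq))
    warning("flank clipped at chromosome end")
  list(left = as.character(Biostrings::subseq(seq, a, s - 1L)),
       element = as.character(Biostrings::subseq(seq, s, e)),
       right = as.character(Biostrings::subseq(seq, e + 1L, b)))
}

## Unique placement of a probe in a query genome (both strands).
## Returns NULL with attr(reason) "unplaced"/"ambiguous", or a list
## (chrom, start, end, strand).
findUniqueMatch <- function(probe, query, maxMismatch = 0L) {
  probe <- Biostrings::DNAString(probe)
  rc <- Biostrings::reverseComplement(probe)
  hits <- list()
  for (chrom in names(query)) {
    for (str in c("+", "-")) {
      m <- Biostrings::matchPattern(if (str == "+") probe else rc,
                                    query[[chrom]],
                                    max.mismatch = maxMismatch)
      if (length(m)) for (i in seq_along(m)) {
        hits[[length(hits) + 1L]] <- list(
          chrom = chrom, start = BiocGenerics::start(m)[i],
          end = BiocGenerics::end(m)[i], strand = str)
      }
    }
  }
  if (length(hits) == 0L) return(list(status = "unplaced"))
  if (length(hits) > 1L) return(list(status = "ambiguous"))
  c(hits[[1]], list(status = "placed"))
}

#' Anchor a locus's flanks in a query assembly
#'
#' Places the flank sequence immediately adjacent to the element on each
#' side (\code{minAnchor} bp) in the query by exact (or near-exact)
#' matching on both strands, and reports the gap between the anchors.
#' The gap is the length of query sequence standing where the reference
#' element stands: element length for a shared insertion, one LTR for a
#' solo-LTR allele, and \code{-tsdLen} for a precise absence (the two
#' anchors then overlap on the single remaining copy of the target
#' site). Ambiguous (multiply-placed) anchors are reported as such, not
#' guessed.
#'
#' @param left,right Flank sequences from \code{\link{extractLocus}}.
#' @param query A named \code{DNAStringSet}.
#' @param minAnchor Anchor length in bp.
#' @param maxMismatch Mismatches tolerated per anchor.
#' @return A list: \code{chrom}, \code{left_end}, \code{right_start},
#'   \code{strand}, \code{gap} (NA when unanchored), \code{left_status}
#'   and \code{right_status} (\code{placed}/\code{unplaced}/
#'   \code{ambiguous}), \code{concordant}.
#' @export
anchorFlanks <- function(left, right, query, minAnchor = 500L,
                         maxMismatch = 0L) {
  if (nchar(left) < minAnchor || nchar(right) < minAnchor)
    stop("flanks shorter than minAnchor")
  la <- substr(left, nchar(left) - minAnchor + 1L, nchar(left))
  ra <- substr(right, 1L, minAnchor)
  lh <- findUniqueMatch(la, query, maxMismatch)
  rh <- findUniqueMatch(ra, query, maxMismatch)
  res <- list(chrom = NA_character_, left_end = NA_integer_,
              right_start = NA_integer_, strand = NA_character_,
              gap = NA_integer_,
              left_status = lh$status, right_status = rh$status,
              concordant = FALSE)
  if (lh$status != "placed" || rh$status != "placed") return(res)
  if (lh$chrom != rh$chrom || lh$strand != rh$strand) return(res)
  if (lh$strand == "+") {
    gap <- rh$start - lh$end - 1L
    res$left_end <- lh$end; res$right_start <- rh$start
  } else {
    gap <- lh$start - rh$end - 1L
    res$left_end <- lh$start; res$right_start <- rh$end
  }
  res$chrom <- lh$chrom; res$strand <- lh$strand; res$gap <- gap
  res$concordant <- gap >= -(minAnchor)  # anchors may overlap by a TSD
  res
}

#' Check that an empty site carries exactly one copy of the TSD
#'
#' A precise excision (or the true pre-integration allele) leaves exactly
#' one copy of the target-site sequence spanning the junction; an
#' imprecise excision can leave both copies. With a zero-length TSD the
#' check is vacuously true and flagged as low evidence.
#'
#' @param query A named \code{DNAStringSet}.
#' @param anchor Anchor result from \code{\link{anchorFlanks}} for this
#'   locus (an absence candidate: anchors overlapping by the TSD).
#' @param tsdSeq The reference TSD sequence (possibly \code{""}).
#' @return \code{list(ok, low_evidence)}.
#' @export
verifyEmptySite <- function(query, anchor, tsdSeq) {
  t <- nchar(tsdSeq)
  if (t == 0L) return(list(ok = TRUE, low_evidence = TRUE))
  seq <- query[[anchor$chrom]]
  slice <- function(a, b) {
    if (a < 1L || b > length(seq)) return("")
    as.character(Biostrings::subseq(seq, a, b))
  }
  if (anchor$strand == "+") {
    hasOne <- slice(anchor$left_end - t + 1L, anchor$left_end) == tsdSeq
    hasTwo <- slice(anchor$left_end + 1L, anchor$left_end + t) == tsdSeq
  } else {
    rcS <- revcompChr(tsdSeq)
    hasOne <- slice(anchor$left_end, anchor$left_end + t - 1L) == rcS
    hasTwo <- slice(anchor$left_end - t, anchor$left_end - 1L) == rcS
  }
  list(ok = hasOne && !hasTwo, low_evidence = FALSE)
}

## Gap tolerance rule: manual-inspection-era calls carry no stated
## tolerance; max(50 bp, 10% of the expected length) is used.
gapTolerance <- function(expected) max(50, 0.1 * abs(expected))

#' Classify the status of one reference locus in one query assembly
#'
#' Automates the per-locus decision: anchor the immediate flanks, read
#' the gap, and compare it with the expected gap for a shared full
#' insertion, a solo LTR, and a precise absence (with the empty-site
#' TSD check). When the immediate flanks cannot be placed, outer flank
#' probes distinguish a deleted locus region (outer sequence present,
#' junction gone: LOCUS_DELETED) from an undeterminable one.
#'
#' @param genome Reference \code{DNAStringSet}.
#' @param call A single FULL_PROVIRUS call \code{GRanges}.
#' @param query Query assembly \code{DNAStringSet}.
#' @param model The family \code{ErvFamilyModel}.
#' @param assemblyId Label for the query assembly.
#' @param flank Flank length extracted around the locus, bp.
#' @param minAnchor Anchor length, bp.
#' @param probeOffsets Offsets (bp from the element) of the outer
#'   deletion probes.
#' @return A one-row \code{data.frame} (the polymorphism call):
#'   \code{locus_id}, \code{assembly_id}, \code{status},
#'   \code{observed_gap}, \code{expected_full}, \code{expected_solo},
#'   \code{tsd_len}, \code{tsd_evidence}, \code{strand},
#'   \code{left_status}, \code{right_status}.
#' @export
classifyLocus <- function(genome, call, query, model,
                          assemblyId = "query", flank = 50000L,
                          minAnchor = 500L,
                          probeOffsets = c(2000L, 5000L, 20000L)) {
  stopifnot(length(call) == 1L)
  loc <- suppressWarnings(extractLocus(genome, call, flank))
  tsdHit <- detectTsd(genome, call, minTsd = 1L, maxTsd = 25L)
  tsdSeq <- if (is.null(tsdHit)) "" else tsdHit$tsd_seq
  t <- nchar(tsdSeq)
  expFull <- nchar(loc$element)
  expSolo <- length(ltrSeq(model))
  expAbs <- -t
  tolFull <- gapTolerance(expFull); tolSolo <- gapTolerance(expSolo)
  tolAbs <- 45
  if (expSolo - tolSolo <= expAbs + tolAbs ||
      expFull - tolFull <= expSolo + tolSolo)
    stop("expected-gap windows overlap: tolerance too large for this family")

  anc <- anchorFlanks(loc$left, loc$right, query, minAnchor = minAnchor)
  row <- data.frame(
    locus_id = call$call_id, assembly_id = assemblyId,
    status = "UNDETERMINED", observed_gap = anc$gap,
    expected_full = expFull, expected_solo = expSolo, tsd_len = t,
    tsd_evidence = NA, strand = anc$strand,
    left_status = anc$left_status, right_status = anc$right_status,
    stringsAsFactors = FALSE)

  if (!is.na(anc$gap)) {
    gap <- anc$gap
    if (abs(gap - expFull) <= tolFull) {
      row$status <- "SHARED_FULL"
    } else if (abs(gap - expSolo) <= tolSolo) {
      row$status <- "SOLO_LTR"
    } else if (abs(gap - expAbs) <= tolAbs) {
      chk <- verifyEmptySite(query, anc, tsdSeq)
      row$tsd_evidence <- chk$ok
      row$status <- if (chk$ok) "PRECISE_ABSENCE" else "UNDETERMINED"
    }
    return(row)
  }

  ## immediate flanks unresolved: probe outward for a deletion signature
  sidePresent <- function(side) {
    fl <- loc[[side]]
    for (off in probeOffsets) {
      probe <- if (side == "left") {
        if (nchar(fl) < off + minAnchor) next
        substr(fl, nchar(fl) - off - minAnchor + 1L, nchar(fl) - off)
      } else {
        if (nchar(fl) < off + minAnchor) next
        substr(fl, off + 1L, off + minAnchor)
      }
      if (findUniqueMatch(probe, query)$status == "placed") return(TRUE)
    }
    FALSE
  }
  leftGone <- anc$left_status != "placed"
  rightGone <- anc$right_status != "placed"
  outerOk <- (!leftGone || sidePresent("left")) &&
             (!rightGone || sidePresent("right"))
  if ((leftGone || rightGone) && outerOk &&
      anc$left_status != "ambiguous" && anc$right_status != "ambiguous")
    row$status <- "LOCUS_DELETED"
  row
}

#' Presence/absence status matrix across assemblies
#'
#' Runs \code{\link{classifyLocus}} for every (locus, assembly) pair and
#' assembles the status matrix. A locus is insertionally polymorphic
#' when at least two distinct statuses occur among its determinable
#' cells (UNDETERMINED and LOCUS_DELETED cells are excluded from that
#' determination).
#'
#' @param genome Reference \code{DNAStringSet}.
#' @param calls FULL_PROVIRUS calls to genotype (\code{GRanges}).
#' @param assemblies Named list of query \code{DNAStringSet}s.
#' @param model The family \code{ErvFamilyModel}.
#' @param ... Passed to \code{\link{classifyLocus}}.
#' @return \code{list(status, detail, polymorphic)}: a loci-by-assembly
#'   character matrix, the per-cell evidence table, and a named logical
#'   vector.
#' @export
polymorphismMatrix <- function(genome, calls, assemblies, model, ...) {
  rows <- list()
  for (a in names(assemblies)) {
    for (i in seq_along(calls)) {
      rows[[length(rows) + 1L]] <- classifyLocus(
        genome, calls[i], assemblies[[a]], model, assemblyId = a, ...)
    }
  }
  detail <- do.call(rbind, rows)
  status <- matrix(NA_character_, length(calls), length(assemblies),
                   dimnames = list(calls$call_id, names(assemblies)))
  for (k in seq_len(nrow(detail)))
    status[detail$locus_id[k], detail$assembly_id[k]] <- detail$status[k]
  determinable <- function(x) x[!x %in% c("UNDETERMINED", "LOCUS_DELETED")]
  ## the reference assembly itself carries the insertion, so it counts as
  ## one determinable SHARED_FULL cell in the polymorphism determination
  polymorphic <- apply(status, 1, function(x)
    length(unique(c("SHARED_FULL", determinable(x)))) >= 2L)
  list(status = status, detail = detail, polymorphic = polymorphic)
}

#' Read a PAF pairwise-alignment file
#'
#' Parses the 12 mandatory PAF columns (coordinates 0-based half-open,
#' as the format specifies) and converts starts to 1-based.
#'
#' @param path Path to a PAF file.
#' @return A \code{data.frame} with columns \code{qname, qlen, qstart,
#'   qend, strand, tname, tlen, tstart, tend, nmatch, alen, mapq};
#'   \code{qstart}/\code{tstart} are converted to 1-based inclusive.
#' @export
readPaf <- function(path) {
  raw <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    fill = TRUE, header = FALSE)[, 1:12]
  names(raw) <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
                  "tlen", "tstart", "tend", "nmatch", "alen", "mapq")
  raw$qstart <- raw$qstart + 1L
  raw$tstart <- raw$tstart + 1L
  raw
}

#' Anchor a reference locus through precomputed PAF alignments
#'
#' Uses query-to-reference alignment blocks instead of in-repo anchoring:
#' the blocks covering the reference positions immediately left and right
#' of the element are located and the junction positions mapped linearly
#' within each block (block-gapless mapping; suitable for the contiguous
#' flank alignments an assembly-to-assembly aligner emits).
#'
#' @param paf \code{data.frame} from \code{\link{readPaf}} with the
#'   reference as target.
#' @param chrom,start,end Reference element coordinates (1-based
#'   closed).
#' @return A list shaped like the \code{\link{anchorFlanks}} result.
#' @export
anchorFlanksPaf <- function(paf, chrom, start, end) {
  blocks <- paf[paf$tname == chrom, , drop = FALSE]
  res <- list(chrom = NA_character_, left_end = NA_integer_,
              right_start = NA_integer_, strand = NA_character_,
              gap = NA_integer_, left_status = "unplaced",
              right_status = "unplaced", concordant = FALSE)
  lb <- blocks[blocks$tstart <= start - 1L & blocks$tend >= start - 1L, ,
               drop = FALSE]
  rb <- blocks[blocks$tstart <= end + 1L & blocks$tend >= end + 1L, ,
               drop = FALSE]
  if (nrow(lb) > 1L) res$left_status <- "ambiguous"
  if (nrow(rb) > 1L) res$right_status <- "ambiguous"
  if (nrow(lb) != 1L || nrow(rb) != 1L) return(res)
  if (lb$qname != rb$qname || lb$strand != rb$strand) return(res)
  mapPos <- function(b, t) {
    if (b$strand == "+") b$qstart + (t - b$tstart)
    else b$qend - (t - b$tstart)
  }
  le <- mapPos(lb, start - 1L)
  rs <- mapPos(rb, end + 1L)
  res$chrom <- lb$qname; res$strand <- lb$strand
  res$left_status <- res$right_status <- "placed"
  if (lb$strand == "+") {
    res$left_end <- le; res$right_start <- rs; res$gap <- rs - le - 1L
  } else {
    res$left_end <- le; res$right_start <- rs; res$gap <- le - rs - 1L
  }
  res$concordant <- !is.na(res$gap)
  res
}
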