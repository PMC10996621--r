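STOP_CODONS <- c("TAA", "TAG", "TGA")

codonsOf <- function(seq, from = 1L) {
  n <- nchar(seq)
  k <- (n - from + 1L) %/% 3L
  if (k <= 0L) return(character(0))
  at <- from + 3L * (seq_len(k) - 1L)
  substring(seq, at, at + 2L)
}

#' Find the longest open reading frame
#'
#' Scans the three frames of the sense strand for ATG-initiated,
#' stop-terminated ORFs and returns the longest (leftmost on ties).
#' Retroviral \emph{gag} is sense-encoded, so the reverse strand is not
#' searched.
#'
#' @param seq DNA sequence (character or \code{DNAString}), alphabet
#'   A/C/G/T/N.
#' @param minAa Minimum protein length in amino acids (Met included,
#'   stop excluded).
#' @return \code{list(start, end, frame, protein_len)} with 1-based
#'   nucleotide coordinates (\code{end} = last base of the stop codon;
#'   \code{frame} in 0/1/2), or \code{NULL} if no qualifying ORF.
#' @examples
#' findLongestOrf("ATGAAATAA", minAa = 1)  # encodes "MK"
#' @export
findLongestOrf <- function(seq, minAa = 50L) {
  seq <- toupper(as.character(seq))
  best <- NULL
  for (f in 0:2) {
    cod <- codonsOf(seq, from = f + 1L)
    if (!length(cod)) next
    isStop <- cod %in% STOP_CODONS
    isAtg <- cod == "ATG"
    open <- NA_integer_
    for (i in seq_along(cod)) {
      if (is.na(open) && isAtg[i]) open <- i
      if (!is.na(open) && isStop[i]) {
        plen <- i - open
        if (plen >= minAa &&
            (is.null(best) || plen > best$protein_len)) {
          best <- list(start = f + 1L + 3L * (open - 1L),
                       end = f + 3L * i, frame = f,
                       protein_len = plen)
        }
        open <- NA_integer_
      }
    }
  }
  best
}

## Map a consensus (pattern) position to a subject position through a
## pairwise alignment.
mapThroughAlignment <- function(aln, patPos) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pi <- BiocGenerics::start(Biostrings::pattern(aln)) - 1L
  si <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-" && pi == patPos) {
      if (s[k] == "-") return(NA_integer_)
      return(si)
    }
  }
  NA_integer_
}

#' Assess Gag ORF intactness of one copy
#'
#' Anchors the family's Gag ORF start on the copy by local alignment of
#' the internal consensus, then reads codons from the anchored start:
#' the copy is intact when the start codon survives and the first in-frame
#' stop does not precede \code{intactFraction} of the expected protein
#' length. A premature stop at codon k gives \code{protein_len = k - 1}.
#'
#' @param seq Copy sequence in element-sense orientation (character or
#'   \code{DNAString}): LTR + internal + LTR or a truncation thereof.
#' @param model An \code{\link{ErvFamilyModel}} with \code{expectedGagAa}
#'   and \code{gagOrfStart} set.
#' @param locusId Identifier carried into the result.
#' @param intactFraction Minimum fraction of the expected protein length
#'   (default 0.95: "full-length" with a little slack for terminal
#'   variation between copies).
#' @return A one-row \code{data.frame}: \code{locus_id},
#'   \code{orf_start}, \code{orf_end} (copy coordinates), \code{frame},
#'   \code{protein_len}, \code{intact}, \code{stop_codon_positions}
#'   (comma-separated codon indices of internal stops),
#'   \code{protein} (translated up to the first stop), \code{reason}.
#' @export
assessGag <- function(seq, model, locusId = "copy", intactFraction = 0.95) {
  seq <- toupper(as.character(seq))
  fail <- function(reason) data.frame(
    locus_id = locusId, orf_start = NA_integer_, orf_end = NA_integer_,
    frame = NA_integer_, protein_len = 0L, intact = FALSE,
    stop_codon_positions = "", protein = "", reason = reason,
    stringsAsFactors = FALSE)
  if (is.na(model@gagOrfStart) || is.na(expectedGagAa(model)))
    stop("model lacks gagOrfStart/expectedGagAa")
  aa <- expectedGagAa(model)
  aln <- Biostrings::pairwiseAlignment(
    internalSeq(model), Biostrings::DNAString(seq), type = "local",
    substitutionMatrix = scanSubstMat(), gapOpening = 5, gapExtension = 2)
  alnLen <- Biostrings::nchar(aln)
  if (alnLen < 0.1 * length(internalSeq(model)))
    return(fail("no internal sequence"))
  orfAt <- mapThroughAlignment(aln, model@gagOrfStart)
  if (is.na(orfAt)) return(fail("ORF start not covered"))
  cod <- codonsOf(seq, from = orfAt)
  if (!length(cod) || cod[1] != "ATG") return(fail("start codon lost"))
  stops <- which(cod %in% STOP_CODONS)
  internalStops <- stops[stops <= aa]
  plen <- if (length(stops)) min(stops) - 1L else length(cod)
  intact <- plen >= ceiling(intactFraction * aa)
  protein <- paste(Biostrings::GENETIC_CODE[cod[seq_len(plen)]],
                   collapse = "")
  data.frame(
    locus_id = locusId, orf_start = orfAt,
    orf_end = orfAt + 3L * plen + 2L, frame = (orfAt - 1L) %% 3L,
    protein_len = plen, intact = intact,
    stop_codon_positions = paste(internalStops, collapse = ","),
    protein = protein,
    reason = if (intact) "" else if (length(internalStops))
      sprintf("premature stop at codon %d", min(internalStops))
      else "ORF shorter than expected",
    stringsAsFactors = FALSE)
}

#' Assess Gag across a call set
#'
#' Runs \code{\link{assessGag}} on every FULL_PROVIRUS and TRUNCATED call;
#' solo LTRs carry no internal sequence and are reported not intact.
#'
#' @param genome A named \code{DNAStringSet}.
#' @param calls A call \code{GRanges}.
#' @param model An \code{ErvFamilyModel}.
#' @param intactFraction See \code{\link{assessGag}}.
#' @return A \code{data.frame}, one row per call.
#' @export
assessGagCalls <- function(genome, calls, model, intactFraction = 0.95) {
  seqs <- getCallSeqs(genome, calls)
  out <- lapply(seq_along(calls), function(i) {
    if (calls$structure_class[i] == "SOLO_LTR") {
      r <- assessGag("A", model, locusId = calls$call_id[i],
                     intactFraction = intactFraction)
      r$reason <- "no internal sequence"
      return(r)
    }
    assessGag(seqs[[i]], model, locusId = calls$call_id[i],
              intactFraction = intactFraction)
  })
  do.call(rbind, out)
}

#' Pairwise percent identity among Gag proteins
#'
#' Global alignment with a simple fixed scheme (match +1, mismatch 0,
#' gap open/extend -1); identity is matches over aligned columns with
#' terminal gaps excluded. Matrix is symmetric with a diagonal of 100.
#'
#' @param proteins Character vector or \code{AAStringSet} of proteins
#'   (\code{>= 2}; fewer returns an empty matrix with a warning).
#' @return \code{list(matrix, mean_identity)} — percent identities and
#'   the mean off-diagonal identity.
#' @export
proteinIdentityMatrix <- function(proteins) {
  nms <- names(proteins)
  proteins <- as.character(proteins)
  names(proteins) <- nms
  n <- length(proteins)
  if (n < 2L) {
    warning("need >= 2 proteins for an identity matrix")
    return(list(matrix = matrix(numeric(0), 0, 0),
                mean_identity = NA_real_))
  }
  if (is.null(names(proteins))) names(proteins) <- paste0("p", seq_len(n))
  alpha <- unique(c(Biostrings::AA_STANDARD, "X", "*",
                    unlist(strsplit(proteins, ""))))
  sm <- matrix(0, length(alpha), length(alpha),
               dimnames = list(alpha, alpha))
  diag(sm) <- 1
  m <- matrix(100, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins[i]), Biostrings::AAString(proteins[j]),
      type = "global", substitutionMatrix = sm,
      gapOpening = 1, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    gapcol <- p == "-" | s == "-"
    inner <- which(!gapcol)
    if (!length(inner)) { m[i, j] <- m[j, i] <- 0; next }
    span <- min(inner):max(inner)     # terminal gap columns excluded
    ident <- 100 * sum(p[span] == s[span]) / length(span)
    m[i, j] <- m[j, i] <- ident
  }
  list(matrix = m,
       mean_identity = mean(m[upper.tri(m)]))
}
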