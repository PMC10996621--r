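#' Sense-strand target site of an antisense oligo
#'
#' An antisense oligonucleotide (LNA or morpholino) is written 5'-3'
#' antisense to its target mRNA; the genomic/transcript site it binds is
#' therefore the reverse complement of the oligo sequence.
#'
#' @param oligo Oligo sequence 5'-3' (character), alphabet A/C/G/T,
#'   length >= 12.
#' @return The sense-strand target site as a character string.
#' @examples
#' targetSite("AAAATTTTGGGGCCC")
#' @export
targetSite <- function(oligo) {
  oligo <- toupper(as.character(oligo))
  checkDnaAlphabet(oligo, "oligo")
  if (nchar(oligo) < 12L) stop("oligo shorter than 12 nt")
  revcompChr(oligo)
}

#' Enumerate family copies targeted by an antisense oligo
#'
#' A copy is a target when the oligo's sense-strand site occurs in the
#' copy's element-sense sequence with at most \code{maxMismatches}
#' substitutions (no indels — consistent with a zero-mismatch design
#' criterion). Counts are broken down by structure class and Gag
#' intactness; copies whose annotation is too short to hold the site, or
#' where only an edge-clipped partial match exists, are listed
#' separately since their true status depends on sequence outside the
#' annotation.
#'
#' @param oligo Oligo sequence 5'-3' antisense.
#' @param seqs Named \code{DNAStringSet} of copy sequences in
#'   element-sense orientation (e.g. \code{\link{getCallSeqs}}).
#' @param structureClass Character vector parallel to \code{seqs}
#'   (FULL_PROVIRUS/SOLO_LTR/TRUNCATED), or \code{NULL}.
#' @param gagIntact Logical vector parallel to \code{seqs}, or
#'   \code{NULL}.
#' @param maxMismatches Substitutions tolerated in the site match.
#' @return A list: \code{hits} (per-copy data.frame with first match
#'   position), \code{n_total}, \code{n_copies}, \code{n_proviral},
#'   \code{n_full_gag}, \code{fraction_targeted},
#'   \code{edge_truncated} (copy names with clipped candidate sites).
#' @export
countTargets <- function(oligo, seqs, structureClass = NULL,
                         gagIntact = NULL, maxMismatches = 0L) {
  site <- targetSite(oligo)
  sitePat <- Biostrings::DNAString(site)
  w <- nchar(site)
  seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("copy", seq_along(seqs))
  m <- Biostrings::vmatchPattern(sitePat, seqs,
                                 max.mismatch = maxMismatches,
                                 with.indels = FALSE)
  nHit <- lengths(m)
  firstPos <- vapply(seq_along(m), function(i)
    if (nHit[i]) BiocGenerics::start(m[[i]])[1] else NA_integer_,
    integer(1))
  targeted <- nHit > 0L

  ## copies whose annotation clips a candidate site: a >= 8 bp piece of
  ## the site flush at a copy edge, or a copy shorter than the site
  edge <- vapply(seq_along(seqs), function(i) {
    if (targeted[i]) return(FALSE)
    s <- as.character(seqs[[i]])
    if (nchar(s) < w) return(TRUE)
    for (k in 8:(w - 1L)) {
      if (substr(s, nchar(s) - k + 1L, nchar(s)) == substr(site, 1L, k))
        return(TRUE)
      if (substr(s, 1L, k) == substr(site, w - k + 1L, w))
        return(TRUE)
    }
    FALSE
  }, logical(1))

  hits <- data.frame(copy = names(seqs), n_sites = as.integer(nHit),
                     first_pos = firstPos, targeted = targeted,
                     stringsAsFactors = FALSE)
  if (!is.null(structureClass)) hits$structure_class <- structureClass
  if (!is.null(gagIntact)) hits$gag_intact <- gagIntact
  list(
    hits = hits,
    n_total = sum(targeted),
    n_copies = length(seqs),
    n_proviral = if (is.null(structureClass)) NA_integer_ else
      sum(targeted & structureClass == "FULL_PROVIRUS"),
    n_full_gag = if (is.null(gagIntact) || is.null(structureClass))
      NA_integer_ else
      sum(targeted & structureClass == "FULL_PROVIRUS" & gagIntact %in% TRUE),
    fraction_targeted = mean(targeted),
    edge_truncated = names(seqs)[edge])
}

#' Genes within a distance of family insertions
#'
#' Reports every gene whose interval lies within \code{distance} bp of
#' any insertion call (gap counted between closest edges; overlap is
#' distance 0), optionally flagged with differential-expression
#' direction — the screen for candidate cis-regulatory effects of
#' insertions near responsive genes.
#'
#' @param genes \code{GRanges} of gene intervals with a \code{gene_id}
#'   metadata column (or names).
#' @param calls Insertion call \code{GRanges}.
#' @param distance Maximum gap in bp (default 10 kb).
#' @param deTable Optional \code{data.frame} with columns
#'   \code{gene_id}, \code{log2fc}, \code{padj}.
#' @param padjCutoff Significance cutoff applied to \code{deTable}.
#' @return A \code{data.frame}: \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{nearest_call},
#'   \code{distance}, and (when \code{deTable} is given) \code{log2fc},
#'   \code{padj}, \code{de_direction} (up/down/ns). Chromosomes present
#'   in only one of the two inputs are reported in the
#'   \code{unshared_chroms} attribute rather than silently dropped.
#' @export
genesNearInsertions <- function(genes, calls, distance = 10000L,
                                deTable = NULL, padjCutoff = 0.05) {
  if (is.null(genes$gene_id))
    genes$gene_id <- names(genes) %||% paste0("gene", seq_along(genes))
  gchr <- unique(as.character(seqnames(genes)))
  cchr <- unique(as.character(seqnames(calls)))
  unshared <- c(setdiff(gchr, cchr), setdiff(cchr, gchr))
  hits <- GenomicRanges::distanceToNearest(genes, calls,
                                           ignore.strand = TRUE)
  keep <- S4Vectors::mcols(hits)$distance <= distance
  hits <- hits[keep]
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    gene_id = genes$gene_id[qi],
    chrom = as.character(seqnames(genes))[qi],
    start = start(genes)[qi], end = end(genes)[qi],
    nearest_call = if (!is.null(calls$call_id)) calls$call_id[si]
      else as.character(si),
    distance = S4Vectors::mcols(hits)$distance,
    stringsAsFactors = FALSE)
  if (!is.null(deTable)) {
    i <- match(out$gene_id, deTable$gene_id)
    out$log2fc <- deTable$log2fc[i]
    out$padj <- deTable$padj[i]
    out$de_direction <- ifelse(
      is.na(out$padj) | out$padj > padjCutoff, "ns",
      ifelse(out$log2fc < 0, "down", "up"))
  }
  attr(out, "unshared_chroms") <- unshared
  out
}

#' Read oligos from a plain-text file
#'
#' One oligo per line: \code{name<TAB>sequence[<TAB>chemistry]}; lines
#' starting with \code{#} are ignored.
#'
#' @param path Path to the oligo file.
#' @return A \code{data.frame}: \code{name}, \code{sequence},
#'   \code{chemistry}, \code{length}.
#' @export
readOligos <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  f <- strsplit(lines, "\t")
  data.frame(
    name = vapply(f, `[`, "", 1L),
    sequence = toupper(vapply(f, `[`, "", 2L)),
    chemistry = vapply(f, function(x)
      if (length(x) >= 3L) x[3] else NA_character_, ""),
    length = nchar(vapply(f, `[`, "", 2L)),
    stringsAsFactors = FALSE)
}
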