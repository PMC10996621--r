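#' Project family copies onto the consensus (anchored pseudo-alignment)
#'
#' Each copy is aligned to the family consensus (affine-gap dynamic
#' programming, copy global / consensus local) and projected onto
#' consensus columns: positions deleted in the copy become gaps,
#' insertions relative to the consensus are dropped. The result is a
#' rectangular pseudo-alignment indexed by consensus position, suitable
#' for pairwise distance computation without a multiple aligner.
#'
#' @param copies A named \code{DNAStringSet} (or character vector) of
#'   copy sequences in element-sense orientation.
#' @param consensus The consensus \code{DNAString} (e.g.
#'   \code{\link{consensusSeq}} of the family model).
#' @param minAlignableFrac Copies with fewer than this fraction of their
#'   bases aligned are excluded with a warning.
#' @return A named character vector; each element is a string of length
#'   \code{length(consensus)} over A/C/G/T/- .
#' @export
anchorAlign <- function(copies, consensus, minAlignableFrac = 0.5) {
  copies <- Biostrings::DNAStringSet(copies)
  if (is.null(names(copies))) names(copies) <- paste0("copy", seq_along(copies))
  consLen <- length(consensus)
  out <- character(0)
  for (nm in names(copies)) {
    aln <- Biostrings::pairwiseAlignment(
      copies[[nm]], consensus, type = "global-local",
      substitutionMatrix = scanSubstMat(), gapOpening = 10, gapExtension = 1)
    if (Biostrings::nmatch(aln) < minAlignableFrac * length(copies[[nm]])) {
      warning("copy '", nm, "' has <", 100 * minAlignableFrac,
              "% alignable bases; excluded")
      next
    }
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    proj <- rep("-", consLen)
    si <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
    for (k in seq_along(s)) {
      if (s[k] != "-") {
        si <- si + 1L
        proj[si] <- p[k]           # '-' when the copy has a deletion
      }                            # insertions in the copy are dropped
    }
    out[nm] <- paste(proj, collapse = "")
  }
  out
}

#' p-distance between two projected sequences
#'
#' Fraction of differing sites over columns where both sequences have a
#' base. Pairs sharing fewer than \code{minShared} columns are reported
#' as missing (\code{NA}), not zero.
#'
#' @param a,b Projected sequences (equal-length strings, gaps as
#'   \code{-}).
#' @param minShared Minimum shared non-gap columns.
#' @return The p-distance, or \code{NA} when coverage is insufficient.
#' @export
pDistance <- function(a, b, minShared = 100L) {
  av <- strsplit(as.character(a), "")[[1]]
  bv <- strsplit(as.character(b), "")[[1]]
  stopifnot(length(av) == length(bv))
  shared <- av != "-" & bv != "-"
  if (sum(shared) < minShared) return(NA_real_)
  sum(av[shared] != bv[shared]) / sum(shared)
}

#' Jukes-Cantor distance
#'
#' \code{d = -(3/4) ln(1 - (4/3) p)}: the expected substitutions/site
#' under the one-parameter substitution model, correcting the raw
#' p-distance for multiple hits. Defined for \code{p < 3/4}.
#'
#' @param p p-distance(s) in \code{[0, 3/4)}.
#' @return Substitutions per site.
#' @export
jcDistance <- function(p) {
  if (any(!is.na(p) & (p < 0 | p >= 0.75)))
    stop("Jukes-Cantor distance undefined for p >= 3/4")
  -0.75 * log(1 - (4 / 3) * p)
}

#' Pairwise Jukes-Cantor divergence matrix from projected copies
#'
#' @param projections Output of \code{\link{anchorAlign}}.
#' @param minShared Minimum shared non-gap columns per pair.
#' @return A symmetric matrix of substitutions/site with a zero
#'   diagonal; pairs below the coverage guard are \code{NA}.
#' @export
divergenceMatrix <- function(projections, minShared = 100L) {
  n <- length(projections)
  m <- matrix(0, n, n, dimnames = list(names(projections),
                                       names(projections)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- pDistance(projections[i], projections[j], minShared)
    m[i, j] <- m[j, i] <- if (is.na(p)) NA_real_ else jcDistance(p)
  }
  m
}

#' Neighbor-joining tree from a divergence matrix
#'
#' Standard neighbor-joining agglomeration (exact on additive matrices);
#' negative branch lengths, which NJ can produce on noisy input, are
#' clamped to zero. The two-taxon case is the single edge with the
#' distance split evenly.
#'
#' @param d Symmetric numeric matrix (or \code{dist}) of distances with
#'   labels.
#' @return An \code{ape} \code{phylo} tree with branch lengths.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (anyNA(d)) stop("distance matrix contains missing pairs")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 taxa")
  labs <- rownames(d) %||% paste0("t", seq_len(n))
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    message("clamping ", sum(tr$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Terminal-branch recency statistics
#'
#' Short terminal branches mean copies nearly identical to their closest
#' relative in the tree — the signature of recent transposition. Reports
#' the terminal branch per copy, their median, and the count/fraction
#' below a threshold (default 0.01 substitutions/site).
#'
#' @param tree A \code{phylo} tree with branch lengths.
#' @param threshold Terminal-branch threshold in substitutions/site.
#' @param dist Optional divergence matrix; adds per-copy
#'   nearest-neighbor distances to the report.
#' @return A list: \code{terminal_branches} (named), \code{median_terminal},
#'   \code{n_below}, \code{fraction_below}, \code{threshold},
#'   \code{nearest_neighbor} (or \code{NULL}), \code{degenerate}
#'   (TRUE when fewer than 2 copies were available).
#' @export
recencyStats <- function(tree, threshold = 0.01, dist = NULL) {
  nn <- NULL
  if (!is.null(dist)) {
    dd <- as.matrix(dist); diag(dd) <- Inf
    nn <- apply(dd, 1, min)
  }
  if (is.null(tree) || length(tree$tip.label) < 2L) {
    return(list(terminal_branches = numeric(0),
                median_terminal = NA_real_, n_below = NA_integer_,
                fraction_below = NA_real_, threshold = threshold,
                nearest_neighbor = nn, degenerate = TRUE))
  }
  ntip <- length(tree$tip.label)
  tipEdge <- match(seq_len(ntip), tree$edge[, 2])
  tb <- setNames(tree$edge.length[tipEdge], tree$tip.label)
  list(terminal_branches = tb,
       median_terminal = median(tb),
       n_below = sum(tb < threshold),
       fraction_below = mean(tb < threshold),
       threshold = threshold,
       nearest_neighbor = nn,
       degenerate = FALSE)
}

#' LTR-LTR divergence of a provirus
#'
#' A provirus's two LTRs are identical at integration; their divergence,
#' Jukes-Cantor corrected, therefore dates the insertion. Computed from
#' the call's two LTR components by global alignment.
#'
#' @param call A single FULL_PROVIRUS call (\code{GRanges}).
#' @param genome A named \code{DNAStringSet}.
#' @return \code{list(p, jc)} — raw p-distance and corrected
#'   substitutions/site between the 5' and 3' LTR.
#' @export
ltrLtrDivergence <- function(call, genome) {
  stopifnot(length(call) == 1L)
  comp <- call$components[[1]]
  ltrs <- comp[comp$part == "LTR"]
  if (length(ltrs) < 2L) stop("missing LTR: call does not have both LTRs")
  ltrs <- ltrs[order(start(ltrs))]
  getSeq1 <- function(gr) {
    s <- as.character(Biostrings::subseq(
      genome[[as.character(seqnames(gr))]], start(gr), end(gr)))
    if (as.character(strand(gr)) == "-") revcompChr(s) else s
  }
  a <- getSeq1(ltrs[1]); b <- getSeq1(ltrs[length(ltrs)])
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = scanSubstMat(), gapOpening = 10, gapExtension = 1)
  nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
  p <- nmm / (nm + nmm)
  list(p = p, jc = jcDistance(p))
}

#' Count near-full-length copies per assembly
#'
#' Applies a length window intended to keep near-full-length elements
#' only, and reports the per-assembly counts with their range — the
#' cross-assembly copy-number comparison used to show ongoing
#' transposition.
#'
#' @param callSets Named list of call \code{GRanges} (one per assembly).
#' @param minLen,maxLen Inclusive length window, bp.
#' @return \code{list(counts, min, max)}; counts is a named integer
#'   vector.
#' @export
countNearFullLength <- function(callSets, minLen, maxLen) {
  counts <- vapply(callSets, function(calls)
    length(lengthFilter(calls, minLen, maxLen)), integer(1))
  list(counts = counts,
       min = if (length(counts)) min(counts) else NA_integer_,
       max = if (length(counts)) max(counts) else NA_integer_)
}
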