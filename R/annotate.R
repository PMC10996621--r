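## Drop near-duplicate hits (same part and strand, heavy overlap), keeping
## the best-scoring one. Seed clusters around nested insertions can yield
## redundant local alignments.
dedupHits <- function(hits) {
  if (length(hits) < 2L) return(hits)
  keep <- rep(TRUE, length(hits))
  ov <- GenomicRanges::findOverlaps(hits, hits, minoverlap = 1L)
  ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
  for (k in seq_along(ov)) {
    i <- S4Vectors::queryHits(ov)[k]; j <- S4Vectors::subjectHits(ov)[k]
    if (!keep[i] || !keep[j]) next
    if (as.character(strand(hits[i])) != as.character(strand(hits[j]))) next
    if (hits$part[i] != hits$part[j]) next
    w <- min(end(hits[i]), end(hits[j])) - max(start(hits[i]), start(hits[j])) + 1L
    if (w < 0.8 * min(width(hits[i]), width(hits[j]))) next
    if (hits$score[i] >= hits$score[j]) keep[j] <- FALSE else keep[i] <- FALSE
  }
  hits[keep]
}

#' Defragment repeat hits into insertion calls
#'
#' Merges per-fragment hits of one family into reconstructed insertion
#' calls. Hits on the same chromosome and strand are merged when they are
#' separated by at most \code{maxMergeGap} bp \emph{and} continue the
#' element in consensus order (LTR, internal, LTR along the element;
#' fragments of one part must advance in consensus coordinates). Two
#' complete LTRs are never merged without an internal region between them,
#' which keeps adjacent solo LTRs from fusing into chimeric calls.
#'
#' @param hits A hit \code{GRanges} from \code{\link{scanHits}} or
#'   \code{\link{readRepeatMaskerOut}}.
#' @param maxMergeGap Maximum genomic gap bridged by a merge, bp.
#' @return A call \code{GRanges} with metadata columns \code{call_id},
#'   \code{family}, \code{structure_class}, \code{parts} (element-order
#'   part string) and \code{components} (a \code{GRangesList} of member
#'   hits); every input hit belongs to exactly one call.
#' @export
defragment <- function(hits, maxMergeGap = 500L) {
  if (length(hits) == 0L) return(emptyCalls())
  hits <- dedupHits(BiocGenerics::sort(hits, ignore.strand = TRUE))
  calls <- list()
  for (chrom in unique(as.character(seqnames(hits)))) {
    for (str in c("+", "-")) {
      for (fam in unique(hits$family)) {
        sub <- hits[seqnames(hits) == chrom & strand(hits) == str &
                      hits$family == fam]
        if (!length(sub)) next
        ## walk in element order: genomic order for +, reversed for -
        idx <- if (str == "+") order(start(sub)) else order(-start(sub))
        sub <- sub[idx]
        cur <- 1L
        slot <- slotOf(sub$part[1], prevSlot = 0L, prevPart = NA,
                       prevConsEnd = NA, consStart = sub$cons_start[1])
        slots <- slot
        assign_ <- rep(NA_integer_, length(sub))
        assign_[1] <- cur
        for (i in seq_len(length(sub))[-1]) {
          gap <- if (str == "+")
            start(sub[i]) - end(sub[i - 1L]) - 1L
          else start(sub[i - 1L]) - end(sub[i]) - 1L
          ns <- slotOf(sub$part[i], prevSlot = slots[i - 1L],
                       prevPart = sub$part[i - 1L],
                       prevConsEnd = sub$cons_end[i - 1L],
                       consStart = sub$cons_start[i])
          if (gap >= 0 && gap <= maxMergeGap && !is.na(ns) &&
              assign_[i - 1L] == cur) {
            assign_[i] <- cur
            slots <- c(slots, ns)
          } else {
            cur <- cur + 1L
            assign_[i] <- cur
            slots <- c(slots, slotOf(sub$part[i], 0L, NA, NA,
                                     sub$cons_start[i]))
          }
        }
        for (g in unique(assign_)) {
          comp <- sub[assign_ == g]
          comp <- comp[order(start(comp))]
          calls[[length(calls) + 1L]] <- list(
            chrom = chrom, start = min(start(comp)), end = max(end(comp)),
            strand = str, family = fam, components = comp)
        }
      }
    }
  }
  buildCalls(calls)
}

## Element slot of a hit given the call state: 1 = 5' LTR, 2 = internal,
## 3 = 3' LTR; NA = cannot extend the current call.
slotOf <- function(part, prevSlot, prevPart, prevConsEnd, consStart) {
  if (prevSlot == 0L) return(if (part == "LTR") 1L else 2L)
  contig <- !is.na(prevConsEnd) && consStart >= prevConsEnd - 20L
  if (part == "INTERNAL") {
    if (prevSlot == 1L) return(2L)
    if (prevSlot == 2L && identical(prevPart, "INTERNAL") && contig) return(2L)
    return(NA_integer_)
  }
  ## part == LTR
  if (prevSlot == 2L) return(3L)
  if (prevSlot %in% c(1L, 3L) && identical(prevPart, "LTR") && contig)
    return(prevSlot)
  NA_integer_
}

emptyCalls <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(call_id = character(), family = character(),
                         structure_class = character(), parts = character(),
                         n_components = integer(),
                         components = GRangesList())
  gr
}

buildCalls <- function(callList) {
  if (!length(callList)) return(emptyCalls())
  gr <- GRanges(
    vapply(callList, `[[`, "", "chrom"),
    IRanges(vapply(callList, `[[`, 0L, "start"),
            vapply(callList, `[[`, 0L, "end")),
    strand = vapply(callList, `[[`, "", "strand"))
  comps <- GRangesList(lapply(callList, `[[`, "components"))
  parts <- vapply(callList, function(x) {
    p <- x$components$part
    if (x$strand == "-") p <- rev(p)
    paste(p, collapse = ",")
  }, "")
  mcols(gr) <- DataFrame(
    call_id = sprintf("call_%04d", seq_along(callList)),
    family = vapply(callList, `[[`, "", "family"),
    structure_class = NA_character_, parts = parts,
    n_components = lengths(comps), components = comps)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  gr$call_id <- sprintf("call_%04d", seq_along(gr))
  gr$structure_class <- vapply(seq_along(gr), function(i)
    classifyCall(gr[i]), "")
  gr
}

#' Classify an insertion call
#'
#' LTR + internal + LTR (in element order) is a full provirus; a single
#' LTR with no internal sequence is a solo LTR — the product of ectopic
#' recombination between a provirus's two LTRs; anything else is a
#' truncated copy.
#'
#' @param call A single-element call \code{GRanges}.
#' @return One of \code{"FULL_PROVIRUS"}, \code{"SOLO_LTR"},
#'   \code{"TRUNCATED"}.
#' @export
classifyCall <- function(call) {
  stopifnot(length(call) == 1L)
  comp <- call$components[[1]]
  if (length(unique(comp$family)) > 1L)
    stop("mixed families within one call")
  parts <- strsplit(call$parts, ",")[[1]]
  rle_ <- rle(parts)$values   # collapse per-part fragments
  if (identical(rle_, c("LTR", "INTERNAL", "LTR"))) return("FULL_PROVIRUS")
  if (identical(rle_, "LTR")) return("SOLO_LTR")
  "TRUNCATED"
}

#' Filter calls by reconstructed length
#'
#' Keeps calls whose genomic span lies within \code{[minLen, maxLen]} —
#' the guard used to drop highly fragmented copies and rearranged
#' full-length elements before alignment and tree building.
#'
#' @param calls A call \code{GRanges}.
#' @param minLen,maxLen Inclusive length window in bp.
#' @return The filtered calls, input order preserved.
#' @export
lengthFilter <- function(calls, minLen, maxLen) {
  if (minLen < 0 || maxLen < 0) stop("length bounds must be non-negative")
  if (minLen > maxLen) stop("minLen must be <= maxLen")
  calls[width(calls) >= minLen & width(calls) <= maxLen]
}

#' Detect a perfect target-site duplication at an occupied site
#'
#' Returns the longest k in \code{[minTsd, maxTsd]} such that the k bp
#' immediately 5' of the call equal the k bp immediately 3' of it exactly
#' (integration duplicates the target site on both flanks; only a perfect
#' duplication is accepted).
#'
#' @param genome A named \code{DNAStringSet}.
#' @param call A single-element call \code{GRanges}.
#' @param minTsd,maxTsd Search range for the TSD length, bp.
#' @return \code{list(tsd_seq, length)} or \code{NULL} when no k
#'   qualifies (with a warning if the flank is clipped at a chromosome
#'   end).
#' @export
detectTsd <- function(genome, call, minTsd = 2L, maxTsd = 20L) {
  stopifnot(length(call) == 1L)
  chrom <- as.character(seqnames(call))
  seq <- genome[[chrom]]
  s <- start(call); e <- end(call)
  maxK <- min(maxTsd, s - 1L, length(seq) - e)
  if (maxK < minTsd) {
    if (s - 1L < minTsd || length(seq) - e < minTsd)
      warning("call at chromosome edge: insufficient flank for TSD search")
    return(NULL)
  }
  for (k in seq(maxK, minTsd, by = -1L)) {
    left <- as.character(Biostrings::subseq(seq, s - k, s - 1L))
    right <- as.character(Biostrings::subseq(seq, e + 1L, e + k))
    if (left == right) return(list(tsd_seq = left, length = k))
  }
  NULL
}

#' Census of insertion calls
#'
#' @param calls A call \code{GRanges}.
#' @return A list with \code{by_class} (named counts over
#'   FULL_PROVIRUS/SOLO_LTR/TRUNCATED), \code{by_family}, \code{n_calls}
#'   and \code{n_hits} (raw fragment count, since merged-call and raw-hit
#'   censuses answer different questions).
#' @export
censusCalls <- function(calls) {
  classes <- c("FULL_PROVIRUS", "SOLO_LTR", "TRUNCATED")
  byClass <- setNames(integer(3), classes)
  tab <- table(calls$structure_class)
  byClass[names(tab)] <- as.integer(tab)
  list(by_class = byClass,
       by_family = table(calls$family),
       n_calls = length(calls),
       n_hits = sum(lengths(calls$components)))
}

#' Extract call sequences in element-sense orientation
#'
#' @param genome A named \code{DNAStringSet}.
#' @param calls A call \code{GRanges}; minus-strand calls are
#'   reverse-complemented so every returned sequence reads 5' LTR first.
#' @return A named \code{DNAStringSet} (names = \code{call_id}).
#' @export
getCallSeqs <- function(genome, calls) {
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(calls), function(i) {
    s <- as.character(Biostrings::subseq(
      genome[[as.character(seqnames(calls[i]))]],
      start(calls[i]), end(calls[i])))
    if (as.character(strand(calls[i])) == "-") revcompChr(s) else s
  }, ""))
  names(seqs) <- calls$call_id
  seqs
}

#' Write calls as BED6 plus a detailed table
#'
#' BED uses 0-based half-open coordinates; the score column is 0.
#'
#' @param calls A call \code{GRanges}.
#' @param bedPath,tablePath Output paths (either may be \code{NULL}).
#' @return Invisibly, the call table \code{data.frame}.
#' @export
writeCalls <- function(calls, bedPath = NULL, tablePath = NULL) {
  df <- data.frame(
    call_id = calls$call_id, chrom = as.character(seqnames(calls)),
    start = start(calls), end = end(calls),
    strand = as.character(strand(calls)), family = calls$family,
    structure_class = calls$structure_class, parts = calls$parts,
    n_components = calls$n_components, length = width(calls),
    stringsAsFactors = FALSE)
  if (!is.null(bedPath)) {
    bed <- data.frame(df$chrom, df$start - 1L, df$end, df$call_id, 0L,
                      df$strand)
    write.table(bed, bedPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tablePath))
    write.table(df, tablePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a RepeatMasker-style .out hit table
#'
#' Parses the whitespace-delimited \code{.out} format (three header lines,
#' then one row per hit): 1-based inclusive query coordinates, \code{C}
#' for minus strand with reversed consensus columns, and an optional
#' trailing \code{*} marking a hit overlapped by a higher-scoring one.
#' Asterisked rows are deduplicated by keeping the highest score among
#' overlapping same-part hits. Repeat names ending in \code{-LTR}/
#' \code{_LTR} map to part LTR, \code{-I}/\code{_I}/\code{-int} to
#' INTERNAL.
#'
#' @param path Path to the \code{.out} file.
#' @return A hit \code{GRanges} as produced by \code{\link{scanHits}}.
#' @export
readRepeatMaskerOut <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(newHits())
  rows <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  parse1 <- function(f) {
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    nm <- f[10]
    part <- if (grepl("([-_]LTR)$", nm)) "LTR"
            else if (grepl("([-_](I|int))$", nm, ignore.case = TRUE)) "INTERNAL"
            else "INTERNAL"
    fam <- sub("[-_](LTR|I|int)$", "", nm, ignore.case = TRUE)
    depar <- function(x) as.integer(gsub("[()]", "", x))
    if (strand == "+") { cs <- depar(f[12]); ce <- depar(f[13]) }
    else { cs <- depar(f[14]); ce <- depar(f[13]) }
    list(score = as.numeric(f[1]), div = as.numeric(f[2]),
         chrom = f[5], start = as.integer(f[6]), end = as.integer(f[7]),
         strand = strand, family = fam, part = part, cs = cs, ce = ce,
         star = length(f) >= 16L && f[16] == "*")
  }
  p <- lapply(rows, parse1)
  hits <- newHits(
    vapply(p, `[[`, "", "chrom"),
    vapply(p, `[[`, 0L, "start"), vapply(p, `[[`, 0L, "end"),
    vapply(p, `[[`, "", "strand"), vapply(p, `[[`, "", "family"),
    vapply(p, `[[`, "", "part"),
    vapply(p, `[[`, 0L, "cs"), vapply(p, `[[`, 0L, "ce"),
    vapply(p, `[[`, 0, "div"), vapply(p, `[[`, 0, "score"))
  dedupHits(BiocGenerics::sort(hits, ignore.strand = TRUE))
}
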