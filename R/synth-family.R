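#' Random protein-coding DNA
#'
#' ATG + (\code{nAa} - 1) random non-stop codons + TAA: a clean open
#' reading frame with no internal stop in its own frame. Individual codons
#' can be pinned (e.g. to place a specific residue at a known position).
#'
#' @param nAa Protein length in amino acids, initiator Met included.
#' @param seed Integer seed.
#' @param fixed Optional named list, codon index (1 = ATG) to codon string.
#' @return A character scalar of length \code{3 * (nAa + 1)}.
#' @export
randomCodingSeq <- function(nAa, seed = 1L, fixed = NULL) {
  stopifnot(nAa >= 1)
  stops <- c("TAA", "TAG", "TGA")
  all64 <- as.vector(outer(
    as.vector(outer(DNA_BASES4, DNA_BASES4, paste0)), DNA_BASES4, paste0))
  sense <- setdiff(all64, stops)
  codons <- withSeed(seed,
    c("ATG", sample(sense, nAa - 1L, replace = TRUE), "TAA"))
  if (!is.null(fixed)) {
    for (k in names(fixed)) {
      i <- as.integer(k)
      stopifnot(i >= 1, i <= nAa)
      codons[i] <- fixed[[k]]
    }
  }
  paste(codons, collapse = "")
}

#' Construct a synthetic ERV family model
#'
#' Builds a family with a random consensus LTR and an internal region
#' carrying a Gag open reading frame of the requested length, flanked by
#' untranslated padding. The defaults model a compact lokiretrovirus-like
#' nonautonomous family: ~400 bp LTRs, a single Gag ORF of 617 aa (the only
#' long ORF; no pol/env), a full element a few kb long, and a 5-bp
#' target-site duplication.
#'
#' @param seed Integer seed.
#' @param ltrLen LTR length in bp.
#' @param gagAa Gag protein length in amino acids.
#' @param padUp,padDown Untranslated padding around the ORF within the
#'   internal region, bp.
#' @param tsdLen Target-site duplication length in bp.
#' @param gc GC fraction of the non-coding parts.
#' @param familyName Family identifier.
#' @return An \code{\link{ErvFamilyModel}} with \code{gagOrfStart} set.
#' @examples
#' fam <- synthFamilyModel(seed = 42)
#' elementLength(fam)
#' @export
synthFamilyModel <- function(seed = 1L, ltrLen = 400L, gagAa = 617L,
                             padUp = 300L, padDown = 300L, tsdLen = 5L,
                             gc = 0.45, familyName = "ERVSim-1") {
  ltr <- withSeed(deriveSeed(seed, "ltr"), randomDna(ltrLen, gc))
  orf <- randomCodingSeq(gagAa, seed = deriveSeed(seed, "orf"))
  up <- withSeed(deriveSeed(seed, "padU"), randomDna(padUp, gc))
  down <- withSeed(deriveSeed(seed, "padD"), randomDna(padDown, gc))
  ErvFamilyModel(familyName, ltr, paste0(up, orf, down),
                 tsdLen = tsdLen, expectedGagAa = gagAa,
                 gagOrfStart = padUp + 1L)
}

#' Simulate a complete ERV study: reference plus strains, with truth
#'
#' Generates a random reference genome, plants a family of insertions
#' (full proviruses, solo LTRs, truncated fragments, optionally nested
#' copies), then derives strain genomes that differ from the reference by
#' precise absences, solo-LTR conversions and locus deletions. This is the
#' planted-truth benchmark every downstream stage is tested against.
#'
#' Default scale: a 2-Mb reference (4 x 500 kb), 60 insertions
#' (40 full / 15 solo / 5 truncated) at divergences drawn uniformly in
#' [0, 0.02] substitutions/site with 5-bp TSDs, and 3 strains carrying 20
#' presence/absence events — the copy numbers, divergence ceiling and
#' strain count of a young, transpositionally active family studied across
#' a handful of assemblies.
#'
#' @param seed Integer seed governing every draw.
#' @param nFull,nSolo,nTrunc Planted copies per structure class.
#' @param nNested Additional full copies planted inside the internal region
#'   of earlier full copies (one level of nesting).
#' @param nChroms,chromLen Reference genome shape.
#' @param maxDivergence Upper bound of the per-copy divergence draw.
#' @param nStrains Number of derived strains.
#' @param nEvents Total presence/absence events across strains.
#' @param model Optional pre-built \code{ErvFamilyModel}.
#' @return A list: \code{model}, \code{reference} (DNAStringSet),
#'   \code{truth} (reference rows), \code{strains} (named list of
#'   DNAStringSet), \code{strainTruth} (rows per strain),
#'   \code{strainEvents} (the planted events).
#' @export
simulateErvStudy <- function(seed = 1L, nFull = 40L, nSolo = 15L,
                             nTrunc = 5L, nNested = 0L, nChroms = 4L,
                             chromLen = 500000L, maxDivergence = 0.02,
                             nStrains = 3L, nEvents = 20L, model = NULL) {
  if (is.null(model)) model <- synthFamilyModel(seed = deriveSeed(seed, "fam"))
  L <- length(ltrSeq(model)); I <- length(internalSeq(model))
  genome <- makeRandomGenome(nChroms, chromLen, gc = 0.41,
                             seed = deriveSeed(seed, "genome"))

  n <- nFull + nSolo + nTrunc
  perChrom <- ceiling(n / nChroms)
  ev <- withSeed(deriveSeed(seed, "events"), {
    pos <- integer(0); chrom <- character(0)
    for (c in seq_len(nChroms)) {
      k <- min(perChrom, n - length(pos))
      if (k <= 0) break
      grid <- round(seq(chromLen / (k + 1), chromLen * k / (k + 1),
                        length.out = k))
      jit <- round(runif(k, -0.2, 0.2) * chromLen / (k + 1))
      pos <- c(pos, pmin(chromLen - 100L, pmax(100L, grid + jit)))
      chrom <- c(chrom, rep(paste0("chr", c), k))
    }
    cls <- sample(rep(c("FULL", "SOLO", "TRUNC"), c(nFull, nSolo, nTrunc)))
    data.frame(
      chrom = chrom, pos = pos,
      divergence = round(runif(n, 0, maxDivergence), 4),
      strand = sample(c("+", "-"), n, replace = TRUE),
      trunc_start = ifelse(cls == "FULL", NA_integer_,
        ifelse(cls == "SOLO", L + 1L,
          ifelse(runif(n) < 0.5, 1L, L + I + 1L))),
      trunc_end = ifelse(cls == "FULL", NA_integer_,
        ifelse(cls == "SOLO", 2L * L + I,
          NA_integer_)),  # filled below per flavour
      stringsAsFactors = FALSE
    )
  })
  tr <- !is.na(ev$trunc_start) & is.na(ev$trunc_end)
  ev$trunc_end[tr] <- ifelse(ev$trunc_start[tr] == 1L, L, 2L * L + I)
  ev$locus_id <- sprintf("locus_%04d", seq_len(n))

  res <- plantInsertions(genome, model, ev, genomeId = "ref",
                         seed = deriveSeed(seed, "plant"))
  reference <- res$genome; truth <- res$truth

  if (nNested > 0L) {
    hosts <- withSeed(deriveSeed(seed, "nestpick"), {
      full <- truth[truth$structure_class == "FULL_PROVIRUS", ]
      full[sample(nrow(full), min(nNested, nrow(full))), ]
    })
    for (i in seq_len(nrow(hosts))) {
      h <- hosts[i, ]
      at <- h$start + L + round((h$end - h$start - 2L * L) / 2)
      res <- plantInsertion(reference, model, h$chrom, at,
                            divergence = 0.005,
                            locusId = sprintf("nested_%02d", i),
                            genomeId = "ref", truth = truth,
                            seed = deriveSeed(seed, paste0("nest", i)))
      reference <- res$genome; truth <- res$truth
    }
  }

  ## Presence/absence events: drawn over non-nested full proviruses, at
  ## most one event per locus per strain.
  kinds <- c("ABSENT_PRECISE", "SOLO_LTR_CONVERSION", "LOCUS_DELETION")
  full <- truth$locus_id[truth$structure_class == "FULL_PROVIRUS" &
                           !truth$nested]
  strainEvents <- withSeed(deriveSeed(seed, "strainev"), {
    per <- diff(round(seq(0, nEvents, length.out = nStrains + 1L)))
    out <- list()
    for (s in seq_len(nStrains)) {
      loci <- sample(full, per[s])
      out[[s]] <- data.frame(
        strain = paste0("strain", s), locus_id = loci,
        kind = sample(kinds, per[s], replace = TRUE),
        deletion_span = 2000L, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  strains <- list(); strainTruth <- list()
  for (s in unique(strainEvents$strain)) {
    se <- strainEvents[strainEvents$strain == s, ]
    ds <- deriveStrain(reference, truth, se, model, s,
                       seed = deriveSeed(seed, s))
    strains[[s]] <- ds$genome
    strainTruth[[s]] <- ds$truth
  }

  list(model = model, reference = reference, truth = truth,
       strains = strains, strainTruth = do.call(rbind, strainTruth),
       strainEvents = strainEvents)
}
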