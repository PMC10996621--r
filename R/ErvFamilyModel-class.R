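#' ErvFamilyModel: consensus model of an LTR retroelement family
#'
#' The family model is the template against which every downstream stage is
#' measured: a consensus long terminal repeat (LTR), a consensus internal
#' region, the length of the target-site duplication (TSD) created at
#' integration, and the expected length of the Gag protein encoded by the
#' internal region. A full-length provirus is LTR + internal + LTR.
#'
#' @slot familyName Family identifier, e.g. \code{"BikSim-1"}.
#' @slot ltr \code{\link[Biostrings]{DNAString}} consensus LTR.
#' @slot internal \code{DNAString} consensus internal region.
#' @slot tsdLen Integer TSD length in bp created at integration (0 allowed).
#' @slot expectedGagAa Expected Gag protein length in amino acids
#'   (initiator Met included, stop excluded).
#' @slot gagOrfStart 1-based start of the Gag ORF within the internal
#'   region, or \code{NA_integer_} if unknown.
#'
#' @examples
#' fam <- synthFamilyModel(seed = 1)
#' fam
#' elementLength(fam)
#' @name ErvFamilyModel-class
#' @aliases ErvFamilyModel-class
#' @exportClass ErvFamilyModel
setClass("ErvFamilyModel",
  representation(
    familyName = "character",
    ltr = "DNAString",
    internal = "DNAString",
    tsdLen = "integer",
    expectedGagAa = "integer",
    gagOrfStart = "integer"
  )
)

setValidity("ErvFamilyModel", function(object) {
  msg <- character()
  if (length(object@ltr) == 0L) msg <- c(msg, "ltr sequence is empty")
  if (length(object@internal) == 0L) msg <- c(msg, "internal sequence is empty")
  for (s in c(ltr = as.character(object@ltr), internal = as.character(object@internal))) {
    if (grepl("[^ACGT]", s)) msg <- c(msg, "model sequences must be over {A,C,G,T}")
  }
  if (is.na(object@tsdLen) || object@tsdLen < 0L)
    msg <- c(msg, "tsdLen must be >= 0")
  if (!is.na(object@expectedGagAa) && object@expectedGagAa <= 0L)
    msg <- c(msg, "expectedGagAa must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an ErvFamilyModel
#'
#' @param familyName Family identifier.
#' @param ltr,internal Consensus LTR / internal sequences (character or
#'   \code{DNAString}).
#' @param tsdLen Target-site duplication length in bp.
#' @param expectedGagAa Expected Gag length in amino acids (NA if unknown).
#' @param gagOrfStart 1-based Gag ORF start within the internal region
#'   (NA if unknown; located on demand by ORF search).
#' @return An \code{ErvFamilyModel} object.
#' @export
ErvFamilyModel <- function(familyName, ltr, internal, tsdLen = 5L,
                           expectedGagAa = NA_integer_,
                           gagOrfStart = NA_integer_) {
  new("ErvFamilyModel",
    familyName = as.character(familyName),
    ltr = Biostrings::DNAString(as.character(ltr)),
    internal = Biostrings::DNAString(as.character(internal)),
    tsdLen = as.integer(tsdLen),
    expectedGagAa = as.integer(expectedGagAa),
    gagOrfStart = as.integer(gagOrfStart)
  )
}

#' @describeIn ErvFamilyModel-class family name accessor
#' @param x,object An \code{ErvFamilyModel}.
#' @export
familyName <- function(x) x@familyName

#' @describeIn ErvFamilyModel-class consensus LTR accessor
#' @export
ltrSeq <- function(x) x@ltr

#' @describeIn ErvFamilyModel-class consensus internal-region accessor
#' @export
internalSeq <- function(x) x@internal

#' @describeIn ErvFamilyModel-class TSD length accessor
#' @export
tsdLen <- function(x) x@tsdLen

#' @describeIn ErvFamilyModel-class expected Gag length accessor
#' @export
expectedGagAa <- function(x) x@expectedGagAa

#' @describeIn ErvFamilyModel-class full element length:
#'   \code{2 * length(ltr) + length(internal)}
#' @export
elementLength <- function(x) 2L * length(x@ltr) + length(x@internal)

#' @describeIn ErvFamilyModel-class consensus of the full element
#'   (LTR + internal + LTR) as a \code{DNAString}
#' @export
consensusSeq <- function(x) {
  Biostrings::xscat(x@ltr, x@internal, x@ltr)
}

setMethod("show", "ErvFamilyModel", function(object) {
  cat("ErvFamilyModel '", object@familyName, "'\n", sep = "")
  cat("  LTR: ", length(object@ltr), " bp; internal: ",
      length(object@internal), " bp; element: ",
      elementLength(object), " bp\n", sep = "")
  cat("  TSD length: ", object@tsdLen, " bp; expected Gag: ",
      object@expectedGagAa, " aa\n", sep = "")
})

#' Write/read an ErvFamilyModel as FASTA
#'
#' The model is serialised as a two-record FASTA: \code{<family>_LTR} and
#' \code{<family>_I}; TSD length and expected Gag length travel in the
#' description line as \code{tsd=<n> gag_aa=<n> orf_start=<n>}.
#'
#' @param model An \code{ErvFamilyModel}.
#' @param path Output / input FASTA path.
#' @return \code{writeFamilyModel} returns \code{path} invisibly;
#'   \code{readFamilyModel} returns an \code{ErvFamilyModel}.
#' @export
writeFamilyModel <- function(model, path) {
  seqs <- Biostrings::DNAStringSet(c(as.character(model@ltr),
                                     as.character(model@internal)))
  names(seqs) <- c(
    sprintf("%s_LTR tsd=%d gag_aa=%d orf_start=%d", model@familyName,
            model@tsdLen, model@expectedGagAa, model@gagOrfStart),
    sprintf("%s_I", model@familyName))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeFamilyModel
#' @export
readFamilyModel <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2L)
    stop("family model FASTA must contain exactly two records (LTR, internal)")
  hdr <- names(seqs)[1]
  fam <- sub("_LTR.*", "", hdr)
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=-?[0-9]+"), hdr))
    if (length(m)) as.integer(sub(paste0(key, "="), "", m)) else NA_integer_
  }
  tsd <- grab("tsd")
  ErvFamilyModel(fam, seqs[[1]], seqs[[2]],
                 tsdLen = if (is.na(tsd)) 5L else tsd,
                 expectedGagAa = grab("gag_aa"),
                 gagOrfStart = grab("orf_start"))
}
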