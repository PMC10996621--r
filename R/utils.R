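#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats setNames runif
#' @importFrom utils read.table write.table
#' @importClassesFrom Biostrings DNAString
#' @import BiocGenerics
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES4 <- c("A", "C", "G", "T")

## Deterministic per-stage seed derivation: all randomness in a run flows
## from one top-level seed. Kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(as.character(stage)))
  as.integer((as.numeric(seed) * 10007 + offs * 131) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a random DNA sequence
#'
#' @param n Length in bp.
#' @param gc GC fraction in (0, 1).
#' @return A character scalar over A/C/G/T.
#' @keywords internal
randomDna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

## Independent uniform substitutions at rate `divergence`; each hit site is
## replaced by one of the three other bases. Returns the mutated string and
## the number of substitutions actually drawn (truth bookkeeping).
mutateSeq <- function(seq, divergence) {
  if (divergence <= 0) return(list(seq = seq, n_sub = 0L))
  stopifnot(divergence < 0.5)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < divergence)
  for (i in hit) {
    ch[i] <- sample(setdiff(DNA_BASES4, ch[i]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_sub = length(hit))
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

checkDnaAlphabet <- function(x, what = "sequence") {
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  invisible(TRUE)
}
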