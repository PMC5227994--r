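#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a master seed and a stage label
#'
#' Keeps independent pipeline stages on independent, reproducible streams.
#' The result always fits in a 32-bit integer.
#' @noRd
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string
#'
#' Uppercases, maps U to T (RNA input), and collapses every other symbol to N.
#' @param x character vector of sequences
#' @return normalized character vector over {A,C,G,T,N}
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "T", chartr("U", "T", toupper(x)))
  gsub("[^ACGT]", "N", x)
}

#' Reverse-complement nucleotide strings (N maps to N)
#' @param x character vector over {A,C,G,T,N}
#' @return reverse complements
#' @export
revcomp <- function(x) {
  vapply(chartr("ACGT", "TGCA", x), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Integer coding used by the C++ kernels: A=0 C=1 G=2 T=3 N=4.
encode_seq <- function(s) {
  code <- match(strsplit(s, "", fixed = TRUE)[[1]], c(DNA_BASES, "N")) - 1L
  code[is.na(code)] <- 4L
  code
}

decode_seq <- function(code) {
  paste(c(DNA_BASES, "N")[code + 1L], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
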