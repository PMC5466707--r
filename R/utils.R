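#' Convert internal genotype codes to display symbols
#'
#' Codes 0/1/2/3 (missing, parent-1, parent-2, heterozygous) map to
#' `"-"`, `"a"`, `"b"`, `"h"` respectively, matching the symbols used in
#' genotype-track and bin-matrix TSV output.
#'
#' @param code integer vector/matrix of codes in 0:3.
#' @return character vector/matrix of symbols, same shape as `code`.
#' @export
code_to_symbol <- function(code) {
  out <- GT_SYMBOLS[as.integer(code) + 1L]
  if (is.matrix(code)) {
    out <- matrix(out, nrow = nrow(code), dimnames = dimnames(code))
  }
  out
}

#' Convert display symbols back to internal genotype codes
#'
#' @param symbol character vector/matrix over `"-"`, `"a"`, `"b"`, `"h"`.
#' @return integer vector/matrix of codes 0:3.
#' @export
symbol_to_code <- function(symbol) {
  out <- match(symbol, GT_SYMBOLS) - 1L
  if (anyNA(out)) stop("unknown genotype symbol: ",
                       paste(unique(symbol[is.na(out)]), collapse = ", "))
  if (is.matrix(symbol)) {
    out <- matrix(out, nrow = nrow(symbol), dimnames = dimnames(symbol))
  }
  out
}

#' Reverse-complement DNA strings
#'
#' Case-preserving (a <-> t, G <-> C, ...); non-ACGT characters such as N are
#' left as their complement-table image (N -> N).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
    chartr("ACGTacgtNn", "TGCAtgcaNn", paste(chars, collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

#' Generate a random DNA sequence
#'
#' @param n sequence length in bases.
#' @return a single uppercase DNA string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## stop() with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## rolling sum of width w over x; returns length(x) - w + 1 values
roll_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}

## fill NA entries with the nearest non-NA neighbour (ties -> left)
fill_nearest <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0L || length(ok) == length(x)) return(x)
  idx <- seq_along(x)
  fi <- findInterval(idx, ok)
  left <- ifelse(fi == 0L, NA_integer_, ok[pmax(fi, 1L)])
  right <- ifelse(fi >= length(ok), NA_integer_, ok[pmin(fi + 1L, length(ok))])
  pick <- ifelse(is.na(left), right,
                 ifelse(is.na(right), left,
                        ifelse(idx - left <= right - idx, left, right)))
  x[pick]
}
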