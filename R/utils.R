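#' @useDynLib intronevo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx density dist median phyper quantile rbinom
#'   rnbinom rnorm runif sd setNames cor
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# encode a DNA string to the integer alphabet used by the alignment kernels
# (1..4 = ACGT, 0 = anything else)
encode_dna <- function(x) {
  v <- utf8ToInt(x)
  out <- integer(length(v))
  out[v == 65L] <- 1L  # A
  out[v == 67L] <- 2L  # C
  out[v == 71L] <- 3L  # G
  out[v == 84L] <- 4L  # T
  out
}

decode_dna <- function(v) {
  codes <- c(65L, 67L, 71L, 84L)
  v[v < 1L | v > 4L] <- NA_integer_
  chars <- ifelse(is.na(v), 78L, codes[v])  # N for anything unknown
  intToUtf8(chars)
}

# fast random DNA string of length n (uses the current RNG stream)
random_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

revcomp <- function(x) {
  v <- rev(utf8ToInt(x))
  comp <- v
  comp[v == 65L] <- 84L; comp[v == 84L] <- 65L
  comp[v == 67L] <- 71L; comp[v == 71L] <- 67L
  intToUtf8(comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
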