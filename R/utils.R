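#' @useDynLib affipair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats phyper pchisq fisher.test quantile rbinom runif setNames
#' @importFrom utils read.table write.table head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector of log-scale values.
#' @return log of the summed probabilities.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Canonical unordered pair ordering (lexicographic)
#' @keywords internal
canonical_pair <- function(a, b) {
  swap <- a > b
  out <- cbind(ifelse(swap, b, a), ifelse(swap, a, b))
  colnames(out) <- c("tf_a", "tf_b")
  out
}

pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p[, 1L], p[, 2L], sep = "\r")
}

#' Encode a DNA string as integers (A=1, C=2, G=3, T=4, other=0)
#' @keywords internal
encode_dna <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], DNA_BASES)
  m[is.na(m)] <- 0L
  as.integer(m)
}

decode_dna <- function(code) {
  paste(ifelse(code >= 1L & code <= 4L, DNA_BASES[pmax(code, 1L)], "N"),
        collapse = "")
}

#' Reverse complement of an integer-encoded sequence
#' @keywords internal
revcomp_code <- function(code) {
  out <- rev(code)
  comp <- out
  comp[out >= 1L] <- 5L - out[out >= 1L]
  comp
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
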