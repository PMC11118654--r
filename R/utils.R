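.BASES <- c("A", "C", "G", "T")
.PYRIMIDINES <- c("C", "T")

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' Cosine similarity between two nonnegative vectors
#'
#' Standard cosine similarity; returns 0 when either vector has zero norm.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A number in `[-1, 1]` (in `[0, 1]` for nonnegative input).
#' @export
cosineSimilarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

## column-wise cosine similarity matrix between columns of A and columns of B
.cosineCross <- function(A, B) {
  An <- sweep(A, 2, pmax(sqrt(colSums(A^2)), .Machine$double.eps), "/")
  Bn <- sweep(B, 2, pmax(sqrt(colSums(B^2)), .Machine$double.eps), "/")
  crossprod(An, Bn)
}

## deterministic derived seeds, kept below 2^31 - 1
.childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 94906249 + 104729 * as.numeric(i)) %% 2147483629L + 1)
}

.normalizeColumns <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

## nonnegative least squares; returns the coefficient vector
.nnls <- function(A, b) {
  A <- as.matrix(A)
  fit <- pracma::lsqnonneg(A, as.numeric(b))
  x <- fit$x
  names(x) <- colnames(A)
  x
}
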