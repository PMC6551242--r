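#' @keywords internal
"_PACKAGE"

## Symbol order is fixed package-wide; it is also the documented tie-break
## order for consensus calls (A < C < G < T < DEL).
MT_SYMBOLS <- c("A", "C", "G", "T", "DEL")

#' Length of the revised Cambridge Reference Sequence (rCRS)
#'
#' The mitochondrial coordinate axis used throughout the package: 1-based,
#' inclusive positions on a 16,569 bp circular genome. Only the length is
#' needed; all computations operate on nucleotide counts, never on the
#' reference base itself.
#'
#' @return Integer scalar, 16569.
#' @export
rcrs_length <- function() 16569L

## Deterministic per-sample seed derivation so that cohort results do not
## depend on the order in which samples are processed. Kept below 2^31 - 1.
derive_seed <- function(base_seed, sample_id) {
  codes <- utf8ToInt(as.character(sample_id))
  h <- as.numeric(base_seed) %% 2147483647
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

## x * log2(x) with the 0 log 0 = 0 convention.
xlog2x <- function(x) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log2(x[nz])
  out
}

## Shannon entropy (bits) of rows of a counts matrix; rows with zero depth
## return 0 (callers decide how to treat them).
row_entropy <- function(counts) {
  depth <- rowSums(counts)
  H <- numeric(nrow(counts))
  nz <- depth > 0
  if (any(nz)) {
    p <- counts[nz, , drop = FALSE] / depth[nz]
    H[nz] <- -rowSums(matrix(xlog2x(p), nrow = sum(nz)))
  }
  H
}

## Column means / variances without matrixStats.
col_vars <- function(M) {
  n <- nrow(M)
  if (n < 2) return(rep(NA_real_, ncol(M)))
  mu <- colMeans(M)
  colSums((M - rep(mu, each = n))^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
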