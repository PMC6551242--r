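#' Sequencing-error model for minor-variant filtering
#'
#' Minor variants are separated from sequencing errors with an exact
#' one-sided binomial tail test. Errors are modeled as symmetric
#' substitutions: a read is miscalled with probability `error_rate` and
#' lands on any specific alternative base with rate `error_rate / 3`.
#' A non-majority symbol observed `k` times at depth `n` is removed when
#' `P(X >= k)` for `X ~ Binomial(n, error_rate / 3)` exceeds
#' `removal_threshold`, i.e. when the observation is compatible with error
#' alone at the fixed 1e-5 probability bar.
#'
#' @param error_rate Per-read miscall probability `q`, in (0, 1).
#'   Default 0.01, a conservative Illumina substitution-error figure.
#' @param removal_threshold Tail-probability bar above which a minor
#'   variant is treated as error (default 1e-5).
#' @return An object of class `error_model`.
#' @export
error_model <- function(error_rate = 0.01, removal_threshold = 1e-5) {
  stopifnot(error_rate > 0, error_rate < 1,
            removal_threshold > 0, removal_threshold < 1)
  structure(list(error_rate = error_rate,
                 removal_threshold = removal_threshold),
            class = "error_model")
}

#' Upper-tail error probability of a minor-variant count
#'
#' `P(X >= k)` for `X ~ Binomial(n, q/3)`: the probability that sequencing
#' error alone produces at least `k` reads of one specific alternative
#' base at depth `n`. Monotonically non-increasing in `k`; `k = 0` gives 1.
#'
#' @param k Observed minor-variant count(s), `0 <= k <= n`.
#' @param n Site depth(s), `n >= 1`.
#' @param model An [error_model()].
#' @return Numeric vector of tail probabilities in \[0, 1\].
#' @export
error_probability <- function(k, n, model = error_model()) {
  if (any(n < 1)) stop("depth must be >= 1")
  if (any(k > n)) stop("minor count exceeds depth")
  if (any(k < 0)) stop("negative count")
  stats::pbinom(k - 1, n, model$error_rate / 3, lower.tail = FALSE)
}

#' Minimal retained minor-variant count at a given depth
#'
#' The smallest count `k*` whose error probability is at or below the
#' removal threshold; filtering a site is equivalent to zeroing every
#' non-majority symbol with count below `k*(depth)`.
#'
#' @param n Depth(s).
#' @inheritParams error_probability
#' @return Integer vector of thresholds.
#' @export
min_retained_count <- function(n, model = error_model()) {
  ## qbinom(.., lower.tail = FALSE) returns the smallest x with
  ## P(X > x) <= threshold; k* = x + 1 then satisfies P(X >= k*) <= threshold.
  as.integer(stats::qbinom(model$removal_threshold, n, model$error_rate / 3,
                           lower.tail = FALSE) + 1L)
}

#' Filter one site's counts
#'
#' Removes (zeroes) every non-majority symbol whose count is compatible
#' with sequencing error; the majority symbol is never removed, and on an
#' exact tie for the majority all tied symbols are exempt. Depth is
#' recomputed from the surviving counts. An all-zero site is returned
#' unchanged.
#'
#' @param counts Named numeric vector of counts over a subset of
#'   `A, C, G, T, DEL`.
#' @param model An [error_model()].
#' @return Filtered counts vector (same names).
#' @export
filter_site <- function(counts, model = error_model()) {
  n <- sum(counts)
  if (n == 0) return(counts)
  kstar <- min_retained_count(n, model)
  mx <- max(counts)
  drop <- counts > 0 & counts < mx & counts < kstar
  counts[drop] <- 0
  counts
}

#' Filter every site of a profile
#'
#' Applies [filter_site()] independently at all positions (vectorized via
#' the per-depth count threshold); metadata is preserved.
#'
#' @param profile A `sample_profile`.
#' @param model An [error_model()].
#' @return A filtered `sample_profile`.
#' @export
filter_profile <- function(profile, model = error_model()) {
  m <- profile$counts
  depth <- rowSums(m)
  nz <- depth > 0
  if (any(nz)) {
    kstar <- rep(NA_integer_, length(depth))
    kstar[nz] <- min_retained_count(depth[nz], model)
    rowmax <- do.call(pmax, as.data.frame(m))
    drop <- m > 0 & m < rowmax & m < kstar
    m[drop] <- 0L
  }
  out <- profile
  out$counts <- m
  out
}
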