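# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities with naive code (explicit loops,
# closed forms, exhaustive enumeration) so they share nothing with the
# package's vectorized implementations.

# Counts matrix (L x 5) with a single polymorphic site, everything else
# monomorphic on base A at the given depth.
fixture_counts <- function(L, depth = 50, poly_pos = integer(0),
                           poly_counts = NULL) {
  m <- matrix(0L, nrow = L, ncol = 5,
              dimnames = list(NULL, c("A", "C", "G", "T", "DEL")))
  m[, "A"] <- depth
  for (i in seq_along(poly_pos)) {
    m[poly_pos[[i]], ] <- 0L
    m[poly_pos[[i]], names(poly_counts[[i]])] <- poly_counts[[i]]
  }
  m
}

fixture_profile <- function(L = 200, depth = 50, poly_pos = integer(0),
                            poly_counts = NULL, sample_id = "fx",
                            group = "unknown", patient_id = sample_id,
                            tissue = "blood") {
  sample_profile(fixture_counts(L, depth, poly_pos, poly_counts),
                 sample_id, patient_id, tissue, group, L = L)
}

# Plain-formula Shannon entropy (bits) of a counts vector.
naive_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p) / log(2))
}

# Exact expectation of the plug-in entropy of an m-read subsample drawn
# without replacement from a two-symbol site, by enumerating all draw
# compositions under the hypergeometric distribution. Also returns the
# exact variance of a single draw's entropy (for Monte-Carlo SEs).
exact_subsample_entropy_2sym <- function(c1, c2, m) {
  ks <- 0:m
  pr <- dhyper(ks, c1, c2, m)
  H <- vapply(ks, function(k) naive_entropy(c(k, m - k)), numeric(1))
  list(mean = sum(pr * H), var = sum(pr * H^2) - sum(pr * H)^2)
}

# Brute-force upper-tail binomial error probability by direct summation.
naive_error_probability <- function(k, n, q) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * (q / 3)^j * (1 - q / 3)^(n - j),
             numeric(1)))
}

# Brute-force single-pass ReliefF with uniform distance weights and
# range-normalized feature differences; explicit O(n^2 p) loops.
brute_relief <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  Xn <- X
  for (j in seq_len(p)) Xn[, j] <- if (rng[j] > 0) X[, j] / rng[j] else 0
  W <- numeric(p)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j) sum((Xn[i, ] - Xn[j, ])^2 / p),
                numeric(1))
    hits <- setdiff(which(y == y[i]), i)
    miss <- which(y != y[i])
    hits <- hits[order(d[hits])][seq_len(k)]
    miss <- miss[order(d[miss])][seq_len(k)]
    for (j in seq_len(p)) {
      W[j] <- W[j] + sum(abs(Xn[miss, j] - Xn[i, j])) -
        sum(abs(Xn[hits, j] - Xn[i, j]))
    }
  }
  W / (n * k)
}

# Quick entropy-profile list for a simulated cohort.
profile_cohort <- function(cohort, model = error_model(),
                           params = resample_params(seed = 1L)) {
  lapply(cohort, entropy_profile, model = model, params = params)
}
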