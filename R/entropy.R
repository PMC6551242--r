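#' Subsampling parameters for depth normalization
#'
#' To keep per-site heterogeneity comparable across samples sequenced at
#' different depths, entropy is computed as the mean plug-in Shannon
#' entropy over repeated fixed-size draws of reads taken without
#' replacement at each position. The draw size of 50 reads matches the
#' mean depth of the case group (~49.6x) and 100 draws are averaged.
#'
#' @param n_resamples Number of random draws per site (default 100).
#' @param reads_per_draw Reads per draw (default 50). Sites at or below
#'   this depth use all their reads, so the result is exact there.
#' @param seed Optional integer base seed. Each sample derives its own
#'   stream from `(seed, sample_id)`, so cohort results do not depend on
#'   processing order.
#' @return An object of class `resample_params`.
#' @export
resample_params <- function(n_resamples = 100, reads_per_draw = 50, seed = NULL) {
  stopifnot(n_resamples >= 1, reads_per_draw >= 1)
  structure(list(n_resamples = as.integer(n_resamples),
                 reads_per_draw = as.integer(reads_per_draw),
                 seed = seed),
            class = "resample_params")
}

#' Shannon entropy of one site (bits)
#'
#' `H = -sum_i x_i log2 x_i` over the symbols with nonzero count, where
#' `x_i` is the fraction of reads carrying variant `i`. Zero for
#' monomorphic sites; at most `log2(#symbols)` bits.
#'
#' @param counts Named or unnamed numeric vector of per-symbol read
#'   counts; total must be >= 1 (zero-depth sites are the caller's
#'   responsibility).
#' @return Entropy in bits.
#' @export
site_entropy <- function(counts) {
  depth <- sum(counts)
  if (depth < 1) stop("site has zero depth; handle uncovered sites upstream")
  p <- counts[counts > 0] / depth
  -sum(xlog2x(p))
}

## Multivariate hypergeometric draws: n_draws subsamples of size m from a
## composition `cnts` (without replacement), via a chain of univariate
## rhyper calls. Returns an n_draws x length(cnts) matrix.
rmvhyper <- function(n_draws, cnts, m) {
  k <- matrix(0, nrow = n_draws, ncol = length(cnts))
  remaining <- rep(m, n_draws)
  pool_other <- sum(cnts)
  for (s in seq_along(cnts)) {
    pool_other <- pool_other - cnts[[s]]
    if (cnts[[s]] == 0) next
    ks <- stats::rhyper(n_draws, cnts[[s]], pool_other, remaining)
    k[, s] <- ks
    remaining <- remaining - ks
  }
  k
}

#' Depth-normalized (subsampled) entropy of one site
#'
#' Mean plug-in entropy over `n_resamples` draws of `reads_per_draw`
#' reads taken without replacement (multivariate hypergeometric on the
#' site's counts). When the depth does not exceed the draw size, every
#' draw is the full site and the result equals [site_entropy()] exactly.
#'
#' @param counts Per-symbol read counts; total depth >= 1.
#' @param params A [resample_params()].
#' @return Mean entropy in bits.
#' @export
resampled_site_entropy <- function(counts, params = resample_params()) {
  depth <- sum(counts)
  if (depth < 1) stop("site has zero depth")
  if (sum(counts > 0) <= 1) return(0)
  if (depth <= params$reads_per_draw) return(site_entropy(counts))
  run <- function() {
    k <- rmvhyper(params$n_resamples, counts, params$reads_per_draw)
    mean(row_entropy(k))
  }
  if (!is.null(params$seed)) withr::with_seed(params$seed, run()) else run()
}

#' Per-sample entropy profile
#'
#' Composes the per-site pipeline: error-filter the counts, then compute
#' the depth-normalized entropy at every position. Zero-depth positions
#' carry entropy 0 and are flagged. Deterministic given the base seed.
#'
#' @param profile A `sample_profile` (QC-passed).
#' @param model An [error_model()].
#' @param params A [resample_params()].
#' @return An object of class `entropy_profile`: list with `sample_id`,
#'   `patient_id`, `tissue`, `group`, `grade`, `L`, numeric `entropy`
#'   (length `L`, bits), logical `zero_depth`, and the parameters used.
#' @export
entropy_profile <- function(profile, model = error_model(),
                            params = resample_params()) {
  filt <- filter_profile(profile, model)
  m <- filt$counts
  depth <- rowSums(m)
  H <- numeric(profile$L)
  poly <- rowSums(m > 0) >= 2
  ## Plug-in entropy is exact wherever depth <= draw size (every draw is
  ## the whole site) and trivially 0 at monomorphic sites.
  exact <- poly & depth >= 1 & depth <= params$reads_per_draw
  if (any(exact)) H[exact] <- row_entropy(m[exact, , drop = FALSE])
  mc <- which(poly & depth > params$reads_per_draw)
  if (length(mc)) {
    run <- function() {
      for (p in mc) {
        k <- rmvhyper(params$n_resamples, m[p, ], params$reads_per_draw)
        H[p] <<- mean(row_entropy(k))
      }
    }
    if (!is.null(params$seed)) {
      withr::with_seed(derive_seed(params$seed, profile$sample_id), run())
    } else run()
  }
  structure(list(
    sample_id = profile$sample_id, patient_id = profile$patient_id,
    tissue = profile$tissue, group = profile$group, grade = profile$grade,
    L = profile$L, entropy = H, zero_depth = depth == 0,
    model = model, params = params
  ), class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf(
    "<entropy_profile> %s (%s, %s): L = %d, total entropy %.3g bits/site, %d nonzero sites\n",
    x$sample_id, x$tissue, x$group, x$L, total_entropy(x), sum(x$entropy > 0)))
  invisible(x)
}

#' Total (mean per-site) entropy of a sample
#'
#' The mean of the per-site entropies over all `L` positions, zero-depth
#' positions contributing 0. On real blood mtDNA this is of order 1e-3
#' bits/site.
#'
#' @param ep An `entropy_profile`.
#' @return Numeric scalar (bits per site).
#' @export
total_entropy <- function(ep) mean(ep$entropy)

#' Standardize an entropy profile to Z-scores (SMEP)
#'
#' Transforms a sample's per-site entropies into the signed number of
#' standard deviations above or below that sample's own mean, using the
#' population (divide-by-N) standard deviation for bit-reproducibility.
#' Standardization is per sample, never per cohort, which is what makes
#' the profiles comparable across sequencing runs.
#'
#' @param ep An `entropy_profile`.
#' @return Numeric vector of length `L` with class `smep` and attribute
#'   `sample_id`. A constant profile yields all zeros with a warning.
#' @export
standardize <- function(ep) {
  H <- ep$entropy
  mu <- mean(H)
  sdev <- sqrt(mean((H - mu)^2))
  if (sdev == 0) {
    warning("constant entropy profile; SMEP set to all zeros")
    z <- numeric(length(H))
  } else {
    z <- (H - mu) / sdev
  }
  structure(z, class = "smep", sample_id = ep$sample_id)
}

#' Sliding-window mean entropy on the circular mtDNA axis
#'
#' Mean entropy in an odd-width window around each center position;
#' windows wrap around the origin (position L adjoins position 1),
#' consistent with the circular mitochondrial genome.
#'
#' @param ep An `entropy_profile`, or a plain numeric vector of per-site
#'   values.
#' @param window Odd window width in bp (default 201).
#' @param step Step between window centers (default 1).
#' @return `data.frame(position, mean_entropy)`.
#' @export
sliding_window_entropy <- function(ep, window = 201, step = 1) {
  H <- if (inherits(ep, "entropy_profile")) ep$entropy else as.numeric(ep)
  L <- length(H)
  if (window %% 2 == 0) stop("window width must be odd")
  if (window > L) stop("window wider than the genome")
  h <- (window - 1) / 2
  ext <- c(H[(L - h + 1):L], H, H[1:h])        # pad both ends circularly
  cs <- c(0, cumsum(ext))
  centers <- seq(1, L, by = step)
  idx <- centers + h                            # center position in `ext`
  means <- (cs[idx + h + 1] - cs[idx - h]) / window
  data.frame(position = centers, mean_entropy = means)
}

#' Assemble a cohort SMEP matrix
#'
#' Standardizes each entropy profile and stacks them into a samples x
#' positions matrix with group and patient labels; row order equals input
#' order.
#'
#' @param eps List of `entropy_profile` objects sharing the same `L`.
#' @return An object of class `cohort_matrix`: list with numeric matrix
#'   `X` (rows named by sample), character `group`, `patient_id`,
#'   `sample_id`, integer `grade`, and `positions` (column coordinates).
#' @export
cohort_matrix <- function(eps) {
  stopifnot(length(eps) >= 1)
  Ls <- vapply(eps, function(e) e$L, integer(1))
  if (length(unique(Ls)) != 1) stop("profiles have mixed genome lengths")
  X <- t(vapply(eps, function(e) as.numeric(suppressWarnings(standardize(e))),
                numeric(Ls[[1]])))
  rownames(X) <- vapply(eps, function(e) e$sample_id, character(1))
  structure(list(
    X = X,
    positions = seq_len(Ls[[1]]),
    group = vapply(eps, function(e) e$group, character(1)),
    patient_id = vapply(eps, function(e) e$patient_id, character(1)),
    sample_id = rownames(X),
    grade = vapply(eps, function(e) e$grade %||% NA_integer_, integer(1))
  ), class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d samples x %d positions (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s: %d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a per-sample entropy table
#'
#' TSV with columns `position, depth, mean_entropy, zero_depth`.
#'
#' @param ep An `entropy_profile`.
#' @param profile The originating `sample_profile` (for depths).
#' @param path Output path.
#' @export
write_entropy_table <- function(ep, profile, path) {
  utils::write.table(
    data.frame(position = seq_len(ep$L), depth = site_depths(profile),
               mean_entropy = ep$entropy, zero_depth = ep$zero_depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
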