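#' Consensus sequence of a profile
#'
#' Per position the highest-count symbol; ties are broken by the fixed
#' symbol order A < C < G < T < DEL; zero-depth positions are called `N`.
#'
#' @param profile A `sample_profile`.
#' @return Character vector of length `L` over `{A,C,G,T,DEL,N}`.
#' @export
consensus <- function(profile) {
  m <- profile$counts
  depth <- rowSums(m)
  ## max.col with ties.method = "first" honors the A<C<G<T<DEL order
  ## because the columns are stored in that order.
  idx <- max.col(m, ties.method = "first")
  out <- MT_SYMBOLS[idx]
  out[depth == 0] <- "N"
  out
}

#' Positions where two consensus sequences differ
#'
#' @param a,b Consensus vectors of equal length.
#' @param ignore_n Skip positions where either call is `N` (default).
#' @return Integer vector of differing positions (1-based).
#' @export
consensus_diff <- function(a, b, ignore_n = TRUE) {
  if (length(a) != length(b)) stop("consensus sequences differ in length")
  d <- a != b
  if (ignore_n) d <- d & a != "N" & b != "N"
  which(d)
}

## Entropy matrices (samples x L) from lists of entropy_profiles.
entropy_matrix <- function(eps) {
  t(vapply(eps, function(e) e$entropy, numeric(eps[[1]]$L)))
}

## Vectorized one-sample t on columns of a difference matrix.
paired_t_cols <- function(D) {
  n <- nrow(D)
  mu <- colMeans(D)
  v <- col_vars(D)
  tstat <- rep(NA_real_, ncol(D))
  p <- rep(1, ncol(D))
  ok <- v > 0
  tstat[ok] <- mu[ok] / sqrt(v[ok] / n)
  p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df = n - 1)
  list(t = tstat, p = p, mean_diff = mu)
}

## Vectorized Welch t on columns of two matrices.
welch_t_cols <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- col_vars(A); v2 <- col_vars(B)
  se2 <- v1 / n1 + v2 / n2
  tstat <- rep(NA_real_, ncol(A))
  p <- rep(1, ncol(A))
  ok <- se2 > 0
  tstat[ok] <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df = df)
  list(t = tstat, p = p, mean_a = m1, mean_b = m2, testable = ok)
}

site_comparison_frame <- function(positions, mean_a, mean_b, tstat, p, alpha) {
  direction <- rep("none", length(positions))
  sig <- !is.na(tstat) & p < alpha
  direction[sig & mean_a > mean_b] <- "higher_in_a"
  direction[sig & mean_a < mean_b] <- "lower_in_a"
  data.frame(position = positions, mean_a = mean_a, mean_b = mean_b,
             t_statistic = tstat, p_value = p, direction = direction,
             stringsAsFactors = FALSE)
}

#' Per-site paired t-tests between two matched cohorts
#'
#' For tissue contrasts within the same patients: a two-sided paired
#' t-test on the per-patient entropy differences at every position.
#' Positions with zero variance of the differences get p = 1 and
#' direction `none`.
#'
#' @param eps_a,eps_b Lists of `entropy_profile` objects covering the same
#'   patients (matched by `patient_id`).
#' @param alpha Significance level for the direction call (default 0.05,
#'   uncorrected; a Benjamini-Hochberg column is appended as
#'   supplementary output).
#' @return `data.frame` with one row per position: `position, mean_a,
#'   mean_b, t_statistic, p_value, direction, p_bh`.
#' @export
paired_site_tests <- function(eps_a, eps_b, alpha = 0.05) {
  pa <- vapply(eps_a, function(e) e$patient_id, character(1))
  pb <- vapply(eps_b, function(e) e$patient_id, character(1))
  um <- c(setdiff(pa, pb), setdiff(pb, pa))
  if (length(um))
    stop("unmatched patients: ", paste(unique(um), collapse = ", "))
  if (length(pa) < 2) stop("paired tests need at least 2 patients")
  eps_b <- eps_b[match(pa, pb)]
  A <- entropy_matrix(eps_a); B <- entropy_matrix(eps_b)
  res <- paired_t_cols(A - B)
  out <- site_comparison_frame(seq_len(ncol(A)), colMeans(A), colMeans(B),
                               res$t, res$p, alpha)
  out$p_bh <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Per-site Welch t-tests between two independent cohorts
#'
#' Case/control contrast: a two-sided Welch (unequal-variance) t-test on
#' per-sample entropies at every position, plus the headline fractions of
#' significantly different sites at the (uncorrected) `alpha` level. The
#' fractions are reported both over polymorphic positions (entropy > 0 in
#' at least one sample; the denominator used for the headline numbers)
#' and over all `L` positions.
#'
#' @param eps_a,eps_b Lists of `entropy_profile` objects (groups a and b).
#' @param alpha Significance level (default 0.05, uncorrected).
#' @return List with `sites` (per-position data.frame as in
#'   [paired_site_tests()]), `fractions` (pct_diff, pct_higher_in_a,
#'   pct_lower_in_a over polymorphic sites), `fractions_all_sites`,
#'   `n_polymorphic`, and `n_testable`.
#' @export
unpaired_site_tests <- function(eps_a, eps_b, alpha = 0.05) {
  if (length(eps_a) < 2 || length(eps_b) < 2)
    stop("each group needs at least 2 samples")
  A <- entropy_matrix(eps_a); B <- entropy_matrix(eps_b)
  res <- welch_t_cols(A, B)
  out <- site_comparison_frame(seq_len(ncol(A)), res$mean_a, res$mean_b,
                               res$t, res$p, alpha)
  out$p_bh <- stats::p.adjust(out$p_value, "BH")
  poly <- colSums(rbind(A, B) > 0) >= 1
  frac <- function(denom) {
    n <- sum(denom)
    if (n == 0) return(c(pct_diff = 0, pct_higher_in_a = 0, pct_lower_in_a = 0))
    c(pct_diff = 100 * sum(out$direction != "none" & denom) / n,
      pct_higher_in_a = 100 * sum(out$direction == "higher_in_a" & denom) / n,
      pct_lower_in_a = 100 * sum(out$direction == "lower_in_a" & denom) / n)
  }
  list(sites = out,
       fractions = frac(poly),
       fractions_all_sites = frac(rep(TRUE, ncol(A))),
       n_polymorphic = sum(poly),
       n_testable = sum(res$testable))
}

#' Group summary table (means, ratios, p-values)
#'
#' Per-metric group means, ratio of the averages (a / b), and the paired
#' or Welch t-test p-value, for the standard summary metrics: mean mtDNA
#' depth, total entropy, percentage of the genome covered, and number of
#' polymorphic sites. Mirrors the layout of the cohort comparison tables
#' used in blood-vs-liver and case-vs-control analyses.
#'
#' @param profiles_a,profiles_b Lists of `sample_profile` objects.
#' @param eps_a,eps_b Optional matching lists of `entropy_profile`
#'   objects; the total-entropy row is skipped with a warning if absent.
#' @param paired Use a paired test matched by `patient_id` (default
#'   FALSE = Welch).
#' @param model Error model used to count polymorphic sites.
#' @return `data.frame(metric, mean_a, mean_b, ratio, p_value)`.
#' @export
summarize_groups <- function(profiles_a, profiles_b, eps_a = NULL, eps_b = NULL,
                             paired = FALSE, model = error_model()) {
  per_sample <- function(ps) {
    t(vapply(ps, function(p) {
      cs <- coverage_summary(p, model)
      c(mean_depth = cs$mean_depth,
        pct_covered = 100 * cs$fraction_covered,
        n_polymorphic = cs$n_polymorphic_sites)
    }, numeric(3)))
  }
  Ma <- per_sample(profiles_a); Mb <- per_sample(profiles_b)
  if (!is.null(eps_a) && !is.null(eps_b)) {
    Ma <- cbind(Ma, total_entropy = vapply(eps_a, total_entropy, numeric(1)))
    Mb <- cbind(Mb, total_entropy = vapply(eps_b, total_entropy, numeric(1)))
  } else {
    warning("entropy profiles not supplied; total-entropy row skipped")
  }
  if (paired) {
    pa <- vapply(profiles_a, function(p) p$patient_id, character(1))
    pb <- vapply(profiles_b, function(p) p$patient_id, character(1))
    if (!setequal(pa, pb)) stop("paired = TRUE but patient sets differ")
    Mb <- Mb[match(pa, pb), , drop = FALSE]
  }
  rows <- lapply(colnames(Ma), function(met) {
    a <- Ma[, met]; b <- Mb[, met]
    p <- if (paired) {
      d <- a - b
      if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
    } else {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) 1
      else stats::t.test(a, b)$p.value
    }
    data.frame(metric = met, mean_a = mean(a), mean_b = mean(b),
               ratio = if (mean(b) == 0) NA_real_ else mean(a) / mean(b),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tumor-specific consensus sites across matched patients
#'
#' For each patient, positions where the tumor and blood consensus
#' sequences differ; the union over patients is the tumor-specific site
#' set. For every such site the prevalence (fraction of patients whose
#' tumor/blood consensus differs there) is reported, together with
#' whether the patient's tumor consensus variant is still detectable at
#' sub-consensus (low) frequency in that patient's blood after error
#' filtering.
#'
#' @param tumor,blood Lists of `sample_profile` objects matched by
#'   `patient_id`.
#' @param model An [error_model()] applied before low-frequency presence
#'   is assessed.
#' @return List with `sites` (sorted positions), `prevalence`
#'   (`data.frame(position, n_patients, prevalence)`) and
#'   `low_freq_presence` (`data.frame(patient_id, position,
#'   tumor_variant, present_in_blood)`).
#' @export
tumor_specific_sites <- function(tumor, blood, model = error_model()) {
  pt <- vapply(tumor, function(p) p$patient_id, character(1))
  pb <- vapply(blood, function(p) p$patient_id, character(1))
  if (!setequal(pt, pb)) stop("tumor and blood cohorts cover different patients")
  blood <- blood[match(pt, pb)]
  per_pat <- lapply(seq_along(tumor), function(i) {
    ct <- consensus(tumor[[i]]); cb <- consensus(blood[[i]])
    d <- consensus_diff(ct, cb)
    if (length(d) == 0) return(NULL)
    bf <- filter_profile(blood[[i]], model)
    data.frame(patient_id = pt[[i]], position = d,
               tumor_variant = ct[d],
               present_in_blood = vapply(seq_along(d), function(j) {
                 bf$counts[d[[j]], ct[d[[j]]]] > 0
               }, logical(1)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_pat)
  if (is.null(tab)) {
    return(list(sites = integer(0),
                prevalence = data.frame(position = integer(0),
                                        n_patients = integer(0),
                                        prevalence = numeric(0)),
                low_freq_presence = data.frame()))
  }
  counts <- table(tab$position)
  prevalence <- data.frame(
    position = as.integer(names(counts)),
    n_patients = as.integer(counts),
    prevalence = as.numeric(counts) / length(tumor))
  prevalence <- prevalence[order(prevalence$position), ]
  rownames(prevalence) <- NULL
  list(sites = sort(unique(tab$position)),
       prevalence = prevalence,
       low_freq_presence = tab)
}
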