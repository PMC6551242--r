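#' Synthetic cohort configuration
#'
#' Describes the statistical structure of a simulated case/control blood
#' mtDNA cohort: group-specific sequencing depth (case mean ~50x, control
#' mean ~120x, with negative-binomial dispersion), a pool of polymorphic
#' (heteroplasmic) positions covering ~0.5% of the genome with long-tailed
#' minor-allele fractions, haplogroup-like consensus backbones assigned
#' independently of case status, per-read sequencing error, a global
#' entropy reduction in cases, and a small set of planted differential
#' sites (mostly lower entropy in cases: 1.77% of the polymorphic pool
#' lower, 0.32% higher). The recorded ground truth makes the planted
#' structure recoverable by downstream selection and classification.
#'
#' @param n_cases,n_controls Group sizes (defaults 232 / 232, the
#'   optimization-set sizes).
#' @param L Genome length (default 16,569).
#' @param depth_case,depth_control Group mean depths (defaults 50 / 120).
#' @param depth_dispersion Negative-binomial size parameter (default 8).
#' @param covered_fraction Fraction of positions with depth >= 1 per
#'   sample (default 0.995); the remainder get depth 0 to exercise
#'   coverage QC.
#' @param f_polymorphic Fraction of positions in the heteroplasmic pool
#'   (default 0.005, ~83 sites).
#' @param mf_shape1,mf_shape2 Beta shape parameters of the minor-allele
#'   fraction distribution, scaled to (0, 0.5] (defaults 0.8, 4:
#'   long-tailed toward low fractions).
#' @param mf_min,mf_max Clamp bounds on the site minor fraction
#'   (defaults 0.01 and 0.40; near-balanced heteroplasmies are excluded
#'   because they destabilize per-tissue majority calls).
#' @param sample_mf_concentration Beta concentration of per-sample minor
#'   fractions around the site-level fraction (default 100).
#' @param frac_lower,frac_higher Fractions of the polymorphic pool
#'   planted with lower / higher case entropy (defaults 0.0177, 0.0032).
#' @param mf_planted_min Minimum site minor fraction for a planted
#'   differential site (default 0.10): a between-group entropy effect can
#'   only exist at a site whose baseline heteroplasmy is detectable at
#'   the study depths, so planted sites are drawn from that part of the
#'   pool.
#' @param effect_scale Multiplicative minor-fraction scaling at planted
#'   sites (default 0.15; applied to cases at "lower" sites and to
#'   controls at "higher" sites).
#' @param case_mf_scale Global multiplicative minor-fraction scaling in
#'   cases (default 1.0). At the default group depths no global scaling
#'   is needed to emulate the ~1.28-fold lower case total entropy: the
#'   error filter detects fewer low-frequency heteroplasmies at 50x than
#'   at 120x, and that interaction alone reproduces the ratio's
#'   magnitude; the knob exists to add genuine global diversity loss on
#'   top.
#' @param q_sim Per-read sequencing error rate (default 0.003).
#' @param n_haplogroups,n_backbone_diffs Number of haplogroup backbones
#'   and consensus differences per backbone (defaults 5, 25).
#' @param depth_blood,depth_tumor,depth_normal Tissue mean depths for
#'   trio mode (defaults 50, 100, 350, mirroring the blood < tumor <
#'   normal mtDNA representation).
#' @param tumor_flip_rate Poisson mean of tumor consensus flips per
#'   patient in trio mode (default 0.92).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 232, n_controls = 232, L = rcrs_length(),
                       depth_case = 50, depth_control = 120,
                       depth_dispersion = 8, covered_fraction = 0.995,
                       f_polymorphic = 0.005,
                       mf_shape1 = 0.8, mf_shape2 = 4,
                       mf_min = 0.01, mf_max = 0.40,
                       sample_mf_concentration = 100,
                       frac_lower = 0.0177, frac_higher = 0.0032,
                       mf_planted_min = 0.10,
                       effect_scale = 0.15, case_mf_scale = 1.0,
                       q_sim = 0.003,
                       n_haplogroups = 5, n_backbone_diffs = 25,
                       depth_blood = 50, depth_tumor = 100,
                       depth_normal = 350, tumor_flip_rate = 0.92) {
  stopifnot(n_cases >= 1, n_controls >= 1, L >= 10,
            covered_fraction > 0, covered_fraction <= 1,
            f_polymorphic >= 0, f_polymorphic <= 1,
            frac_lower >= 0, frac_higher >= 0,
            effect_scale > 0, case_mf_scale > 0,
            q_sim >= 0, q_sim < 1, mf_min > 0, mf_max <= 0.5)
  n_poly <- round(f_polymorphic * L)
  if (round(frac_lower * n_poly) + round(frac_higher * n_poly) > n_poly)
    stop("planted sites exceed the polymorphic pool")
  structure(as.list(environment()), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

## Shared cohort-level structure: reference consensus, haplogroup
## backbones, the polymorphic pool with site minor fractions, and the
## planted differential sites.
sim_truth_setup <- function(cfg, seed) {
  withr::with_seed(seed, {
    ref <- sample(BASES, cfg$L, replace = TRUE)
    n_poly <- round(cfg$f_polymorphic * cfg$L)
    poly <- sort(sample.int(cfg$L, n_poly))
    site_mf <- pmin(pmax(0.5 * stats::rbeta(n_poly, cfg$mf_shape1, cfg$mf_shape2),
                         cfg$mf_min), cfg$mf_max)
    minor <- vapply(poly, function(p) sample(setdiff(BASES, ref[[p]]), 1),
                    character(1))
    m_lower <- round(cfg$frac_lower * n_poly)
    m_higher <- round(cfg$frac_higher * n_poly)
    eligible <- which(site_mf >= cfg$mf_planted_min)
    if (length(eligible) < m_lower + m_higher)
      stop("too few pool sites with detectable heteroplasmy to plant effects")
    planted <- sample(eligible, m_lower + m_higher)
    lower_idx <- planted[seq_len(m_lower)]
    higher_idx <- if (m_higher > 0) planted[m_lower + seq_len(m_higher)] else integer(0)
    non_pool <- setdiff(seq_len(cfg$L), poly)
    backbones <- lapply(seq_len(cfg$n_haplogroups), function(h) {
      n_bb <- min(cfg$n_backbone_diffs, length(non_pool))
      pos <- non_pool[sample.int(length(non_pool), n_bb)]
      list(position = pos,
           base = vapply(pos, function(p) sample(setdiff(BASES, ref[[p]]), 1),
                         character(1)))
    })
    list(ref = ref, poly_positions = poly, site_mf = site_mf,
         minor_base = minor,
         planted_lower = poly[lower_idx], planted_higher = poly[higher_idx],
         lower_idx = lower_idx, higher_idx = higher_idx,
         backbones = backbones)
  })
}

## Draw one sample's counts matrix given its consensus, per-site minor
## fractions (length L, 0 outside the pool), mean depth and error rate.
draw_sample_counts <- function(cfg, cons_idx, minor_idx, mf, mean_depth) {
  L <- cfg$L
  depth <- stats::rnbinom(L, size = cfg$depth_dispersion, mu = mean_depth)
  depth <- pmax(depth, 1L)
  n_uncov <- round((1 - cfg$covered_fraction) * L)
  if (n_uncov > 0) depth[sample.int(L, n_uncov)] <- 0L
  ## True composition, then the closed-form observed composition under
  ## uniform substitution error: p_obs = p(1 - q) + (1 - p) q/3.
  P <- matrix(0, nrow = L, ncol = 4)
  P[cbind(seq_len(L), cons_idx)] <- 1 - mf
  P[cbind(seq_len(L), minor_idx)] <- P[cbind(seq_len(L), minor_idx)] + mf
  P <- P * (1 - cfg$q_sim) + (1 - P) * cfg$q_sim / 3
  ## Multinomial draw as a chain of binomials, vectorized over positions.
  counts <- matrix(0L, nrow = L, ncol = length(MT_SYMBOLS),
                   dimnames = list(NULL, MT_SYMBOLS))
  remaining <- depth
  ptot <- rowSums(P)
  pleft <- ptot
  for (b in 1:3) {
    pr <- ifelse(pleft > 0, pmin(pmax(P[, b] / pleft, 0), 1), 0)
    k <- stats::rbinom(L, remaining, pr)
    counts[, b] <- k
    remaining <- remaining - k
    pleft <- pleft - P[, b]
  }
  counts[, 4] <- remaining
  counts
}

## Per-sample minor fractions: site-level mf with Beta-distributed
## sample-to-sample variation, then group scaling and planted effects.
sample_minor_fractions <- function(cfg, truth, is_case) {
  kappa <- cfg$sample_mf_concentration
  mf <- stats::rbeta(length(truth$site_mf),
                     truth$site_mf * kappa, (1 - truth$site_mf) * kappa)
  mf <- pmin(pmax(mf, cfg$mf_min / 2), cfg$mf_max)
  if (is_case) {
    mf <- mf * cfg$case_mf_scale
    mf[truth$lower_idx] <- mf[truth$lower_idx] * cfg$effect_scale
  } else {
    mf[truth$higher_idx] <- mf[truth$higher_idx] * cfg$effect_scale
  }
  mf
}

make_sim_profile <- function(cfg, truth, sample_id, patient_id, tissue,
                             group, hap, mf_poly, mean_depth,
                             extra_flips = NULL) {
  cons <- truth$ref
  bb <- truth$backbones[[hap]]
  cons[bb$position] <- bb$base
  if (!is.null(extra_flips)) cons[extra_flips$position] <- extra_flips$base
  cons_idx <- match(cons, BASES)
  minor_idx <- cons_idx                 # self => adds 0 where not polymorphic
  minor_idx[truth$poly_positions] <- match(truth$minor_base, BASES)
  mf <- numeric(cfg$L)
  mf[truth$poly_positions] <- mf_poly
  ## A planted tumor flip at a pool position would make minor == consensus;
  ## zero the minor fraction there (clonal fixation).
  clash <- minor_idx == cons_idx
  mf[clash] <- 0
  counts <- draw_sample_counts(cfg, cons_idx, minor_idx, mf, mean_depth)
  sample_profile(counts, sample_id, patient_id, tissue, group,
                 NA_integer_, cfg$L)
}

#' Simulate a case/control blood cohort with ground truth
#'
#' Generates `n_cases + n_controls` read-count profiles per
#' [sim_config()]: each sample gets a haplogroup backbone (independent of
#' case status), per-sample minor-allele fractions at the polymorphic
#' pool (globally scaled down in cases, strongly scaled at the planted
#' differential sites), negative-binomial depths, and multinomial reads
#' corrupted by uniform substitution error. Fully deterministic given
#' the seed; each sample draws from its own derived stream so results do
#' not depend on processing order.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param id_prefix Prefix of the generated sample ids (default `"S"`).
#'   Cohorts simulated with the same seed share the cohort-level truth
#'   (pool, planted sites, backbones); a different prefix yields new
#'   samples from that shared truth, e.g. a held-out validation set.
#' @return List with `cohort` (list of `sample_profile`; cases first,
#'   group `"HCC"`, then controls, group `"NC"`) and `truth` (list with
#'   the polymorphic pool, site minor fractions, planted lower/higher
#'   site positions, haplogroup assignments and the per-sample expected
#'   minor fractions).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L, id_prefix = "S") {
  truth <- sim_truth_setup(cfg, seed)
  n <- cfg$n_cases + cfg$n_controls
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  groups <- rep(c("HCC", "NC"), c(cfg$n_cases, cfg$n_controls))
  haps <- withr::with_seed(derive_seed(seed, paste0(id_prefix, "-haplogroups")),
                           sample.int(cfg$n_haplogroups, n, replace = TRUE))
  cohort <- vector("list", n)
  sample_mf <- matrix(0, nrow = n, ncol = length(truth$poly_positions))
  for (i in seq_len(n)) {
    is_case <- groups[[i]] == "HCC"
    cohort[[i]] <- withr::with_seed(derive_seed(seed, ids[[i]]), {
      mf_poly <- sample_minor_fractions(cfg, truth, is_case)
      sample_mf[i, ] <- mf_poly
      make_sim_profile(cfg, truth, ids[[i]], ids[[i]], "blood", groups[[i]],
                       haps[[i]], mf_poly,
                       if (is_case) cfg$depth_case else cfg$depth_control)
    })
  }
  truth$haplogroup <- haps
  truth$group <- groups
  truth$sample_mf <- sample_mf
  truth$effect_scale <- cfg$effect_scale
  list(cohort = cohort, truth = truth)
}

#' Simulate matched blood/tumor/normal-liver trios
#'
#' Each synthetic patient shares one haplogroup backbone and one set of
#' per-site minor fractions across the three tissues; the tumor receives
#' a Poisson(`tumor_flip_rate`)-distributed number of clonal consensus
#' flips at random non-pool positions, and tissue mean depths follow the
#' blood < tumor < normal ordering of mtDNA representation.
#'
#' @param cfg A [sim_config()].
#' @param n_patients Number of patients (default 25).
#' @param seed Integer seed.
#' @return List with `blood`, `tumor`, `normal` (lists of
#'   `sample_profile` in patient order) and `truth` (includes
#'   `tumor_flips`, the per-patient flip positions).
#' @export
simulate_tissue_trios <- function(cfg = sim_config(), n_patients = 25,
                                  seed = 1L) {
  truth <- sim_truth_setup(cfg, seed)
  non_pool <- setdiff(seq_len(cfg$L), truth$poly_positions)
  blood <- tumor <- normal <- vector("list", n_patients)
  flips <- vector("list", n_patients)
  haps <- withr::with_seed(derive_seed(seed, "trio-haplogroups"),
                           sample.int(cfg$n_haplogroups, n_patients,
                                      replace = TRUE))
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%04d", i)
    withr::with_seed(derive_seed(seed, pid), {
      mf_poly <- sample_minor_fractions(cfg, truth, is_case = TRUE)
      n_flip <- min(stats::rpois(1, cfg$tumor_flip_rate), length(non_pool))
      fp <- if (n_flip > 0) non_pool[sample.int(length(non_pool), n_flip)]
            else integer(0)
      cons_here <- truth$ref
      bb <- truth$backbones[[haps[[i]]]]
      cons_here[bb$position] <- bb$base
      fb <- vapply(fp, function(p) sample(setdiff(BASES, cons_here[[p]]), 1),
                   character(1))
      flips[[i]] <- fp
      blood[[i]] <- make_sim_profile(cfg, truth, paste0(pid, "_B"), pid,
                                     "blood", "HCC", haps[[i]], mf_poly,
                                     cfg$depth_blood)
      tumor[[i]] <- make_sim_profile(cfg, truth, paste0(pid, "_T"), pid,
                                     "tumor", "HCC", haps[[i]], mf_poly,
                                     cfg$depth_tumor,
                                     extra_flips = list(position = fp, base = fb))
      normal[[i]] <- make_sim_profile(cfg, truth, paste0(pid, "_N"), pid,
                                      "normal_liver", "HCC", haps[[i]], mf_poly,
                                      cfg$depth_normal)
    })
  }
  truth$haplogroup <- haps
  truth$tumor_flips <- flips
  list(blood = blood, tumor = tumor, normal = normal, truth = truth)
}

#' Write the simulation truth table
#'
#' TSV with one row per polymorphic-pool position: `position,
#' minor_base, site_mf, planted` (`lower`, `higher` or `none`).
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param path Output path.
#' @export
write_truth_table <- function(truth, path) {
  planted <- rep("none", length(truth$poly_positions))
  planted[match(truth$planted_lower, truth$poly_positions)] <- "lower"
  planted[match(truth$planted_higher, truth$poly_positions)] <- "higher"
  utils::write.table(
    data.frame(position = truth$poly_positions,
               minor_base = truth$minor_base,
               site_mf = truth$site_mf, planted = planted),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
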