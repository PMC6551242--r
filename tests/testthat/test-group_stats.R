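test_that("consensus calls majority symbols with documented tie-breaking", {
  prof <- fixture_profile(L = 6, depth = 50,
                          poly_pos = 1:5,
                          poly_counts = list(c(A = 49, C = 1),
                                             c(A = 25, C = 25),
                                             c(G = 30, T = 20),
                                             c(T = 50),
                                             c(C = 10, DEL = 40)))
  prof$counts[6, ] <- 0L
  expect_equal(consensus(prof), c("A", "A", "G", "T", "DEL", "N"))
})

test_that("consensus_diff is symmetric and skips N positions", {
  a <- rep("A", 100); b <- a
  expect_length(consensus_diff(a, b), 0)
  b[c(31, 89)] <- "C"
  expect_equal(consensus_diff(a, b), c(31, 89))
  expect_equal(consensus_diff(a, b), consensus_diff(b, a))
  a[31] <- "N"
  expect_equal(consensus_diff(a, b), 89)
  expect_equal(consensus_diff(a, b, ignore_n = FALSE), c(31, 89))
  expect_error(consensus_diff(a, b[1:50]), "length")
})

make_eps <- function(M, ids, group = "unknown") {
  lapply(seq_len(nrow(M)), function(i) {
    structure(list(sample_id = ids[[i]], patient_id = ids[[i]],
                   tissue = "blood", group = group, grade = NA_integer_,
                   L = ncol(M), entropy = M[i, ],
                   zero_depth = rep(FALSE, ncol(M))),
              class = "entropy_profile")
  })
}

test_that("paired_site_tests equal the one-sample t of differences", {
  set.seed(31)
  n <- 10; L <- 40
  A <- matrix(runif(n * L, 0, 0.5), n)
  B <- A + matrix(rnorm(n * L, 0, 0.02), n)
  ids <- sprintf("pt%02d", seq_len(n))
  res <- paired_site_tests(make_eps(A, ids), make_eps(B, ids))
  for (j in sample(L, 8)) {
    tt <- t.test(A[, j] - B[, j])
    expect_equal(res$t_statistic[[j]], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[[j]], tt$p.value, tolerance = 1e-10)
  }
  # identical cohorts: all p = 1, no direction
  res0 <- paired_site_tests(make_eps(A, ids), make_eps(A, ids))
  expect_true(all(res0$p_value == 1))
  expect_true(all(res0$direction == "none"))
  # a constant +0.1 shift (tiny jitter) has the smallest p
  B2 <- A; B2[, 17] <- A[, 17] + 0.1 + rnorm(n, 0, 1e-4)
  res2 <- paired_site_tests(make_eps(B2, ids), make_eps(A, ids))
  expect_equal(which.min(res2$p_value), 17)
  expect_equal(res2$direction[[17]], "higher_in_a")
  # pairing is by patient id, not order
  resf <- paired_site_tests(make_eps(B2, ids), make_eps(A, ids)[n:1])
  expect_equal(resf$p_value, res2$p_value)
  expect_error(paired_site_tests(make_eps(A, ids), make_eps(A, toupper(ids))),
               "unmatched")
})

test_that("unpaired_site_tests match Welch's t.test and report coherent fractions", {
  set.seed(32)
  A <- matrix(rgamma(12 * 30, 2, 10), 12)
  B <- matrix(rgamma(15 * 30, 2, 8), 15)
  res <- unpaired_site_tests(make_eps(A, sprintf("a%d", 1:12)),
                             make_eps(B, sprintf("b%d", 1:15)))
  for (j in sample(30, 8)) {
    tt <- t.test(A[, j], B[, j])
    expect_equal(res$sites$t_statistic[[j]], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(res$sites$p_value[[j]], tt$p.value, tolerance = 1e-10)
  }
  f <- res$fractions
  expect_equal(unname(f["pct_diff"]),
               unname(f["pct_higher_in_a"] + f["pct_lower_in_a"]))
  # equal constant groups: nothing significant
  C <- matrix(0.2, 6, 30)
  res0 <- unpaired_site_tests(make_eps(C, sprintf("c%d", 1:6)),
                              make_eps(C, sprintf("d%d", 1:6)))
  expect_equal(unname(res0$fractions["pct_diff"]), 0)
  expect_true(all(res0$sites$p_value == 1))
})

test_that("planted shifts are recovered in the expected direction", {
  set.seed(33)
  n <- 40; L <- 200
  A <- matrix(abs(rnorm(n * L, 0.2, 0.05)), n)
  B <- A + matrix(rnorm(n * L, 0, 0.05), n)
  shifted <- sample(L, 4)
  B[, shifted] <- B[, shifted] + 0.5
  res <- unpaired_site_tests(make_eps(A, sprintf("a%d", 1:n)),
                             make_eps(B, sprintf("b%d", 1:n)))
  expect_true(all(res$sites$direction[shifted] == "lower_in_a"))
  expect_true(all(res$sites$p_value[shifted] < 1e-6))
})

test_that("summarize_groups reports means, reciprocal ratios and scaling effects", {
  sim <- simulate_cohort(sim_config(n_cases = 5, n_controls = 5, L = 500,
                                    f_polymorphic = 0.04,
                                    frac_lower = 0, frac_higher = 0,
                                    case_mf_scale = 1), seed = 44)
  profs <- sim$cohort
  eps <- profile_cohort(profs)
  a <- 1:5; b <- 6:10
  gs <- suppressWarnings(summarize_groups(profs[a], profs[b], eps[a], eps[b]))
  expect_setequal(gs$metric, c("mean_depth", "pct_covered", "n_polymorphic",
                               "total_entropy"))
  gs_rev <- suppressWarnings(summarize_groups(profs[b], profs[a], eps[b], eps[a]))
  expect_equal(gs$ratio * gs_rev$ratio[match(gs$metric, gs_rev$metric)],
               rep(1, 4))
  # identical groups: all ratios exactly 1
  gs_id <- suppressWarnings(summarize_groups(profs[a], profs[a], eps[a], eps[a]))
  expect_equal(gs_id$ratio, rep(1, 4))
  # constructed x1.28 entropy scaling shows up as a 1/1.28 ratio
  eps_scaled <- lapply(eps[b], function(e) { e$entropy <- e$entropy * 1.28; e })
  gs_sc <- suppressWarnings(summarize_groups(profs[a], profs[b], eps[a], eps_scaled))
  r_ent <- gs_sc$ratio[gs_sc$metric == "total_entropy"]
  r_base <- gs$ratio[gs$metric == "total_entropy"]
  expect_equal(r_ent, r_base / 1.28, tolerance = 1e-12)
})

test_that("tumor-specific sites recover planted consensus flips and their prevalence", {
  L <- 300
  blood <- lapply(1:4, function(i)
    fixture_profile(L = L, depth = 60, sample_id = sprintf("p%d_b", i),
                    patient_id = sprintf("p%d", i), tissue = "blood"))
  tumor <- lapply(1:4, function(i)
    fixture_profile(L = L, depth = 60, sample_id = sprintf("p%d_t", i),
                    patient_id = sprintf("p%d", i), tissue = "tumor"))
  # identical tissues: empty set
  ts0 <- tumor_specific_sites(tumor, blood)
  expect_length(ts0$sites, 0)
  # shared flip at 150 in patients 1-3, private flip at 42 in patient 1
  for (i in 1:3) {
    tumor[[i]]$counts[150, ] <- 0L
    tumor[[i]]$counts[150, "G"] <- 60L
  }
  tumor[[1]]$counts[42, ] <- 0L
  tumor[[1]]$counts[42, "T"] <- 60L
  # patient 2 blood carries the tumor variant at low (sub-consensus) frequency
  blood[[2]]$counts[150, "G"] <- 10L
  ts <- tumor_specific_sites(tumor, blood)
  expect_equal(ts$sites, c(42, 150))
  expect_equal(ts$prevalence$prevalence[ts$prevalence$position == 150], 3 / 4)
  expect_equal(ts$prevalence$prevalence[ts$prevalence$position == 42], 1 / 4)
  lf <- ts$low_freq_presence
  expect_true(lf$present_in_blood[lf$patient_id == "p2" & lf$position == 150])
  expect_false(lf$present_in_blood[lf$patient_id == "p1" & lf$position == 150])
})

test_that("type-I error of per-site Welch tests is near nominal under the null", {
  set.seed(35)
  n <- 30; L <- 800
  A <- matrix(rnorm(n * L, 0.3, 0.1), n)
  B <- matrix(rnorm(n * L, 0.3, 0.1), n)
  res <- unpaired_site_tests(make_eps(abs(A), sprintf("a%d", 1:n)),
                             make_eps(abs(B), sprintf("b%d", 1:n)))
  rate <- mean(res$sites$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / L)
  expect_lt(abs(rate - 0.05), 3 * se)
})
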