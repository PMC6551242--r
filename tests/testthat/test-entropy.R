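test_that("site_entropy matches the analytic formula", {
  expect_equal(site_entropy(c(A = 50)), 0)
  expect_equal(site_entropy(c(A = 25, C = 25)), 1)
  expect_equal(site_entropy(c(A = 10, C = 10, G = 10, T = 10)), 2)
  expect_equal(site_entropy(c(A = 49, C = 1)),
               -(0.98 * log2(0.98) + 0.02 * log2(0.02)))
  # against naive formula on random compositions
  set.seed(3)
  for (i in 1:20) {
    cnts <- rmultinom(1, 200, c(0.5, 0.3, 0.15, 0.05))[, 1]
    expect_equal(site_entropy(cnts), naive_entropy(cnts), tolerance = 1e-12)
  }
  expect_error(site_entropy(c(A = 0)), "zero depth")
})

test_that("resampled entropy is exact at or below the draw size and zero when monomorphic", {
  pr <- resample_params(n_resamples = 10, reads_per_draw = 50, seed = 4)
  expect_equal(resampled_site_entropy(c(A = 30, C = 20), pr),
               site_entropy(c(A = 30, C = 20)))
  expect_equal(resampled_site_entropy(c(A = 10000), pr), 0)
  expect_error(resampled_site_entropy(c(A = 0), pr), "zero depth")
})

test_that("subsampled entropy matches the exact hypergeometric expectation and is negatively biased", {
  compositions <- list(c(A = 5000, C = 5000), c(A = 900, C = 100),
                       c(A = 150, C = 60))
  for (cnts in compositions) {
    ex <- exact_subsample_entropy_2sym(cnts[[1]], cnts[[2]], 50)
    pr <- resample_params(n_resamples = 400, reads_per_draw = 50, seed = 99)
    mc <- resampled_site_entropy(cnts, pr)
    se <- sqrt(ex$var / 400)
    expect_lt(abs(mc - ex$mean), 3 * se + 1e-12)
    # Jensen: the expected plug-in entropy of a subsample never exceeds
    # the entropy of the source composition
    expect_lte(ex$mean, site_entropy(cnts) + 1e-12)
  }
})

test_that("entropy_profile composes filter + resampling, flags zero depth, and is seed-deterministic", {
  prof <- fixture_profile(L = 120, depth = 50,
                          poly_pos = c(10, 60, 90),
                          poly_counts = list(c(A = 25, C = 25),
                                             c(A = 400, G = 100),
                                             c(A = 49, C = 1)))
  prof$counts[101:120, ] <- 0L
  ep <- entropy_profile(prof, params = resample_params(seed = 8))
  expect_length(ep$entropy, 120)
  expect_equal(ep$entropy[[10]], 1.0)               # depth 50: exact draw
  expect_gt(ep$entropy[[60]], 0)                    # resampled deep site
  expect_equal(ep$entropy[[90]], 0)                 # 1-read minor filtered
  expect_true(all(ep$zero_depth[101:120]))
  expect_equal(ep$entropy[101:120], rep(0, 20))
  expect_true(all(ep$entropy >= 0 & ep$entropy <= 2))
  # determinism
  ep2 <- entropy_profile(prof, params = resample_params(seed = 8))
  expect_identical(ep$entropy, ep2$entropy)
  # different seed changes the MC site but not the exact ones
  ep3 <- entropy_profile(prof, params = resample_params(seed = 9))
  expect_equal(ep3$entropy[[10]], 1.0)
})

test_that("total_entropy is the mean over all positions", {
  prof <- fixture_profile(L = 100, depth = 50)
  ep <- entropy_profile(prof)
  expect_equal(total_entropy(ep), 0)
  ep$entropy[[5]] <- 1.0
  expect_equal(total_entropy(ep), 1 / 100)
})

test_that("standardize yields per-sample Z-scores with population sd", {
  ep <- structure(list(sample_id = "z", L = 3, entropy = c(0, 0, 2)),
                  class = "entropy_profile")
  z <- standardize(ep)
  expect_equal(as.numeric(z), c(-1, -1, 2) / sqrt(2), tolerance = 1e-12)
  # any profile: mean 0, sd 1
  set.seed(5)
  ep$entropy <- runif(3)
  z <- as.numeric(standardize(ep))
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  # constant profile: zeros + warning
  ep$entropy <- rep(0.4, 3)
  expect_warning(zc <- standardize(ep), "constant")
  expect_equal(as.numeric(zc), c(0, 0, 0))
})

test_that("sliding windows are circular means matching brute force", {
  L <- 500
  ep <- structure(list(sample_id = "w", L = L, entropy = rep(0.3, L)),
                  class = "entropy_profile")
  sw <- sliding_window_entropy(ep, window = 201)
  expect_equal(sw$mean_entropy, rep(0.3, L))

  # single spike: exactly `window` windows carry h / window
  ep$entropy <- numeric(L); ep$entropy[[250]] <- 2
  sw <- sliding_window_entropy(ep, window = 201)
  expect_equal(sum(sw$mean_entropy > 0), 201)
  expect_equal(max(sw$mean_entropy), 2 / 201)

  # random profile vs brute-force circular means at random centers
  set.seed(6)
  ep$entropy <- runif(L)
  sw <- sliding_window_entropy(ep, window = 31)
  idx_circ <- function(i) ((i - 1) %% L) + 1
  for (c in sample(L, 50)) {
    expect_equal(sw$mean_entropy[[c]],
                 mean(ep$entropy[idx_circ((c - 15):(c + 15))]),
                 tolerance = 1e-12)
  }
  # spike at the origin wraps around
  ep$entropy <- numeric(L); ep$entropy[[1]] <- 1
  sw <- sliding_window_entropy(ep, window = 5)
  expect_equal(which(sw$mean_entropy > 0), c(1, 2, 3, L - 1, L))
  expect_error(sliding_window_entropy(ep, window = 10), "odd")
})

test_that("cohort_matrix stacks per-sample SMEPs in input order", {
  sim <- simulate_cohort(sim_config(n_cases = 3, n_controls = 3, L = 400,
                                    f_polymorphic = 0.05,
                                    frac_lower = 0, frac_higher = 0), seed = 7)
  eps <- profile_cohort(sim$cohort)
  cm <- cohort_matrix(eps)
  expect_equal(dim(cm$X), c(6, 400))
  expect_equal(cm$group, c(rep("HCC", 3), rep("NC", 3)))
  # each row is that sample's SMEP: mean 0, sd 1
  expect_true(all(abs(rowMeans(cm$X)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(cm$X^2)) - 1) < 1e-9))
  # permuting input order permutes rows identically
  perm <- c(4, 1, 6, 2, 3, 5)
  cm2 <- cohort_matrix(eps[perm])
  expect_equal(cm2$X, cm$X[perm, ])
  # mixed lengths rejected
  eps_bad <- c(eps[1:2], profile_cohort(simulate_cohort(
    sim_config(n_cases = 1, n_controls = 1, L = 300,
               frac_lower = 0, frac_higher = 0), seed = 1)$cohort))
  expect_error(cohort_matrix(eps_bad), "mixed")
})
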