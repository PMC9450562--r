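test_that("spike_count_matrix aggregates windows correctly", {
  r <- spike_raster(matrix(c(1, 0, 2, 1, 0, 3, 1, 0, 0, 2, 1, 1), nrow = 2,
                           byrow = TRUE), dt = 1)
  scm <- spike_count_matrix(r, 2)
  expect_equal(scm$n_subsets, 3L)
  expect_identical(unname(scm$counts),
                   matrix(c(1, 3, 3, 1, 2, 2), nrow = 2, byrow = TRUE))
  expect_equal(scm$window_width, 2)

  # window spanning the full recording leaves a single subset: error
  expect_error(spike_count_matrix(r, 6), "2 windows")
  expect_error(spike_count_matrix(r, 0.5), "bin width")

  # tau-multiple mode floors to whole bins: 0.333 s / 0.066 s -> 5 bins
  r2 <- spike_raster(matrix(rpois(40, 1), nrow = 2), dt = 0.066)
  scm2 <- spike_count_matrix(r2, 1, mode = "tau_multiple", tau = 0.333)
  expect_equal(scm2$window_width / r2$dt, 5)
  expect_error(spike_count_matrix(r2, 1, mode = "tau_multiple"), "tau")
})

test_that("covariance estimator matches the explicit unbiased formula", {
  # exact linear dependence
  scm <- make_scm(matrix(c(1, 2, 3, 2, 4, 6), nrow = 2, byrow = TRUE))
  cs <- count_covariance_stats(scm)
  expect_equal(cs$cov[1, 2], 2)
  expect_equal(unname(cs$var), c(1, 4))
  expect_equal(cs$corr_offdiag, 1)

  # brute-force oracle on random small matrices
  for (seed in 1:5) {
    set.seed(seed)
    counts <- matrix(rpois(5 * 8, 3), nrow = 5)
    cs2 <- count_covariance_stats(make_scm(counts))
    N <- 8
    brute <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      ni <- counts[i, ]; nj <- counts[j, ]
      brute[i, j] <- sum((ni - mean(ni)) * (nj - mean(nj))) / (N - 1)
    }
    expect_equal(unname(cs2$cov), brute, tolerance = 1e-12)
    expect_equal(cs2$Delta, sd(brute[upper.tri(brute)]) / mean(diag(brute)),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance neurons are excluded from correlations, kept in covariances", {
  counts <- rbind(c(1, 2, 3, 4), c(2, 2, 2, 2), c(4, 3, 2, 1))
  cs <- count_covariance_stats(make_scm(counts))
  expect_identical(cs$zero_variance_neurons, 2L)
  expect_equal(dim(cs$cov), c(3L, 3L))
  expect_true(all(cs$cov[2, ] == 0))
  expect_length(cs$corr_offdiag, 1L)   # only the (1,3) pair survives
  expect_equal(cs$corr_offdiag, -1)
})

test_that("independent Poisson neurons give |mu| much smaller than sigma", {
  set.seed(71)
  r <- spike_raster(matrix(rpois(50 * 2000, 0.3), nrow = 50), dt = 1)
  cs <- count_covariance_stats(spike_count_matrix(r, 10))  # 200 subsets
  expect_lt(abs(cs$mean_cov), cs$width_cov / 3)
  expect_lt(abs(mean(cs$corr_offdiag)), 0.01)
  # under the null the naive Delta is mostly estimation bias, so the
  # jackknife correction pulls it down substantially
  expect_lt(cs$Delta_jackknife, cs$Delta)
})

test_that("participation ratio reproduces closed-form spectra", {
  # one dominant mode: two perfectly anticorrelated neurons
  scm1 <- make_scm(rbind(c(1, 3, 1, 3), c(3, 1, 3, 1)))
  expect_equal(participation_ratio(scm1)$N_eff, 1, tolerance = 1e-12)

  # two equal independent modes
  scm2 <- make_scm(rbind(c(1, 3, 1, 3), c(1, 1, 3, 3)))
  expect_equal(participation_ratio(scm2)$N_eff, 2, tolerance = 1e-12)

  # four orthogonal modes with variance ratios 4:3:2:1 -> evr (.4,.3,.2,.1)
  # built from disjoint-support +/-1 contrasts over 20 subsets
  blocks <- list(c(1, 8), c(9, 14), c(15, 18), c(19, 20))
  counts <- t(sapply(seq_along(blocks), function(i) {
    supp <- blocks[[i]][1]:blocks[[i]][2]
    x <- rep(0, 20)
    x[supp] <- rep(c(1, -1), length(supp) / 2)
    x + 1
  }))
  pr <- participation_ratio(make_scm(counts))
  expect_equal(sort(pr$evr, decreasing = TRUE), c(0.4, 0.3, 0.2, 0.1),
               tolerance = 1e-12)
  expect_equal(pr$N_eff, 10 / 3, tolerance = 1e-12)
})

test_that("rank-one population activity has dimensionality ~1 with uniform loadings", {
  set.seed(72)
  latent <- rpois(300, 50)
  counts <- t(sapply(1:30, function(i) latent + rpois(300, 1)))
  pr <- participation_ratio(make_scm(counts))
  expect_lt(pr$N_eff, 1.2)
  l1 <- abs(pr$loadings[, 1])
  expect_lt(sd(l1) / mean(l1), 0.1)   # near-uniform first component
})

test_that("N_eff is scale-invariant and properly bounded", {
  set.seed(73)
  counts <- matrix(rpois(12 * 30, 4), nrow = 12)
  pr1 <- participation_ratio(make_scm(counts))
  pr2 <- participation_ratio(make_scm(counts * 7L))
  expect_equal(pr1$N_eff, pr2$N_eff, tolerance = 1e-12)
  expect_gte(pr1$N_eff, 1)
  expect_lte(pr1$N_eff, min(12, 30 - 1))
  expect_equal(sum(pr1$evr), 1, tolerance = 1e-12)
  expect_error(participation_ratio(make_scm(matrix(2L, 4, 6))), "degenerate")
})

test_that("lambda_max follows the covariance-width formula", {
  expect_identical(lambda_max(0), 0)
  expect_equal(lambda_max(1 / sqrt(1500), 1500), 0.5, tolerance = 1e-12)
  expect_equal(lambda_max(0.05, 1500), 1 - 1 / 4.75, tolerance = 1e-12)
  # strictly increasing in Delta and network size, saturating below 1
  d <- seq(0, 2, by = 0.1)
  expect_true(all(diff(lambda_max(d)) > 0))
  expect_true(all(lambda_max(d) < 1))
  expect_gt(lambda_max(0.1, 3000), lambda_max(0.1, 1500))
  expect_error(lambda_max(-0.1), "Delta")
})

test_that("the mu << sigma signature survives 50% neuron subsampling", {
  set.seed(74)
  r <- spike_raster(matrix(rpois(60 * 1500, 0.4), nrow = 60), dt = 1)
  full <- count_covariance_stats(spike_count_matrix(r, 10))
  half <- count_covariance_stats(
    spike_count_matrix(subsample_neurons(r, 0.5, seed = 75), 10))
  expect_lt(abs(full$mean_cov), full$width_cov)
  expect_lt(abs(half$mean_cov), half$width_cov)
})
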