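test_that("regression slopes are exact on a noiseless geometric series", {
  # A_t = 2^20 * 0.5^t: integers throughout, slopes r_k = 0.5^k exactly
  a <- activity_series(2^(20:0), 1)
  r <- regression_slopes(a, 10)
  expect_equal(r[1:3], 0.5^(1:3), tolerance = 1e-12)

  expect_error(regression_slopes(activity_series(rep(3, 100), 1), 10),
               "constant")
  expect_error(regression_slopes(a, 9), "k_max")
  expect_error(regression_slopes(a, 11), "too short")
})

test_that("slopes on an i.i.d. series stay inside the null band", {
  set.seed(62)
  x <- activity_series(rpois(1e5, 4), 1)
  r <- regression_slopes(x, 20)
  expect_lt(max(abs(r)), 3 / sqrt(1e5))
})

test_that("slopes on a branching simulation track m^k", {
  s <- simulate_branching(0.9, 1, 1e5, seed = 61)
  r <- regression_slopes(s, 20)
  expect_lt(max(abs(r - 0.9^(1:20))), 0.02)
  # data-driven k_max: at least the floor, at most n/10
  r2 <- regression_slopes(s)
  expect_gte(length(r2), 20L)
  expect_lte(length(r2), 1e4L)
})

test_that("branching-parameter fit is exact on model input", {
  fit <- fit_branching_parameter(0.5 * 0.9^(1:40), dt = 1)
  expect_equal(fit$m_hat, 0.9, tolerance = 1e-7)
  expect_equal(fit$b_hat, 0.5, tolerance = 1e-6)
  expect_lt(fit$fit_residual, 1e-10)
  expect_equal(fit$tau, -1 / log(0.9), tolerance = 1e-6)
  expect_equal(round(fit$tau, 4), 9.4912)

  # recording-scale autocorrelation time: m = 0.986 at dt = 4 ms
  fit2 <- fit_branching_parameter(0.986^(1:40), dt = 0.004)
  expect_equal(fit2$tau, -0.004 / log(0.986), tolerance = 1e-6)
  expect_equal(round(fit2$tau, 4), 0.2837)
  expect_true(fit2$tau > 0.104 && fit2$tau < 0.433)

  # spike-at-lag-1 slopes drive m to the lower boundary
  fit0 <- fit_branching_parameter(c(0.4, rep(0, 39)), dt = 1)
  expect_true(fit0$m_hat < 0.1)
  expect_error(fit_branching_parameter(0.9^(1:5), 1), "k_max")
})

test_that("stationarity battery classifies the canonical slope shapes", {
  # exact exponential: everything clear
  b1 <- stationarity_battery(0.9^(1:40), 1)
  expect_false(any(b1$H_offset, b1$H_tau, b1$H_lin, b1$H_MR_invalid))
  expect_identical(b1$verdict, "accepted_clear")

  # all-zero slopes: the Poisson definition (m = 0, r_k = 0)
  b2 <- stationarity_battery(rep(0, 40), 1)
  expect_true(b2$H_MR_invalid)
  expect_true(b2$H_poisson)
  expect_identical(b2$verdict, "accepted_poisson")

  # pure linear ramp: the line fits perfectly, the exponential cannot
  b3 <- stationarity_battery(0.005 * (1:40) + 0.1, 1)
  expect_true(b3$H_lin)
  expect_identical(b3$verdict, "rejected_nonstationary")

  # exponential plus a large offset: H_offset fires
  set.seed(4)
  b4 <- stationarity_battery(0.5 * 0.8^(1:40) + 0.2 +
                               rnorm(40, sd = 1e-4), 1)
  expect_true(b4$H_offset)
  expect_identical(b4$verdict, "rejected_nonstationary")
})

test_that("acceptance policy distinguishes strict from lenient", {
  clear <- stationarity_battery(0.9^(1:40), 1)
  expect_true(accept_dataset(clear, "strict")$accepted)
  expect_true(accept_dataset(clear, "lenient")$accepted)

  pois <- stationarity_battery(rep(0, 40), 1)
  expect_true(accept_dataset(pois, "strict")$accepted)

  # only H_MR_invalid positive: rejected under strict, accepted under lenient
  flagged <- clear
  flagged$H_MR_invalid <- TRUE
  flagged$H_poisson <- FALSE
  flagged$verdict <- "invalid"
  expect_false(accept_dataset(flagged, "strict")$accepted)
  acc <- accept_dataset(flagged, "lenient")
  expect_true(acc$accepted)
  expect_identical(acc$reason, "accepted_flagged")

  # any nonstationarity flag rejects under both policies
  bad <- stationarity_battery(0.005 * (1:40) + 0.1, 1)
  expect_false(accept_dataset(bad, "strict")$accepted)
  expect_false(accept_dataset(bad, "lenient")$accepted)
})

test_that("MR estimate is invariant under binomial spike subsampling", {
  for (m in c(0.8, 0.95)) {
    s <- simulate_branching(m, (1 - m) * 10, 1e5, seed = round(100 * m))
    fits <- sapply(c(0.05, 0.2, 1), function(q) {
      x <- if (q < 1) subsample_spikes_binomial(s, q, seed = round(1000 * q)) else s
      mr <- mr_estimate(x)
      c(mr$m_hat, mr$b_hat)
    })
    expect_lt(max(fits[1, ]) - min(fits[1, ]), 0.03)   # m_hat stable
    expect_true(all(diff(fits[2, ]) > 0))              # b_hat grows with q
    # the naive one-step slope underestimates under subsampling
    r1 <- regression_slopes(subsample_spikes_binomial(s, 0.1, seed = 9), 10)[1]
    expect_lt(r1, m - 0.03)
  }
})

test_that("MR estimate is consistent across temporal coarsening", {
  s <- simulate_branching(0.9, 1, 1e5, seed = 63)
  m1 <- mr_estimate(s)$m_hat
  for (mode in c("sum", "skip")) {
    m2 <- mr_estimate(temporal_coarsen(s, 2, mode))$m_hat
    expect_lt(abs(m2 - m1^2), 0.02)
  }
})

test_that("timescale conversion reproduces the printed effective values", {
  expect_equal(round(timescale_convert(0.985, 15), 4), 0.7972)
  expect_equal(round(timescale_convert(0.9999, 15), 4), 0.9985)
  expect_identical(timescale_convert(1, 15), 1)
  expect_identical(timescale_convert(1, 0.25), 1)
  expect_error(timescale_convert(0, 15), "m must be")
})

test_that("phi fit recovers an exact conversion law and converts timescales", {
  dts <- c(0.066, 0.132, 0.264)
  fit <- fit_phi(data.frame(dt = dts, m_hat = 0.0326^dts))
  expect_equal(fit$phi, 0.0326, tolerance = 1e-10)
  expect_equal(round(predict(fit, 0.004), 3), 0.986)
  expect_lt(fit$fit_residual, 1e-20)

  expect_error(fit_phi(data.frame(dt = dts[1:2], m_hat = c(0.5, 0.4))),
               "insufficient")
  expect_error(fit_phi(data.frame(dt = dts, m_hat = c(0.5, -0.1, 0.2))),
               "m_hat")
  # outlier exclusion drops the right rows
  pairs <- data.frame(dt = c(dts, 0.5), m_hat = c(0.0326^dts, 0.9))
  fit2 <- fit_phi(pairs, exclude = 4L)
  expect_equal(fit2$phi, 0.0326, tolerance = 1e-10)
})
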