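test_that("constructors enforce strict positivity", {
  expect_error(learning_params(0, 1, 1), "N")
  expect_error(learning_params(5, -1, 1), "D")
  expect_error(learning_params(5, 1, 0), "delta")
  expect_error(learning_params(NA, 1, 1), "N")
  expect_error(logistic_params(0, 5), "slope")
  expect_s3_class(learning_params(1e-3, 1e3, 2), "learning_params")
})

test_that("model family is recoverable from parameters", {
  expect_identical(kind_of(learning_params(5, 1, 2)), "gamma")
  expect_identical(kind_of(learning_params(1, 3, 2)), "weibull")
  expect_identical(kind_of(learning_params(8, 0.5, 2)), "weibull_gamma")
  expect_identical(kind_of(logistic_params(1, 5)), "logistic")
})

test_that("cumulative intensity is a power law in age", {
  expect_equal(cumulative_intensity(learning_params(1, 1, 2), 3), 6)
  expect_equal(cumulative_intensity(learning_params(1, 2, 0.01), 10), 1.0)
  # delta * sqrt(5), hand-check
  expect_equal(cumulative_intensity(learning_params(1, 0.5, 3.7947), 5),
               3.7947 * sqrt(5), tolerance = 1e-12)
  expect_equal(cumulative_intensity(learning_params(2, 1.3, 0.7), 0), 0)
  ts <- seq(0.1, 40, length.out = 50)
  expect_true(all(diff(cumulative_intensity(learning_params(3, 0.4, 1.2), ts)) > 0))
  expect_error(cumulative_intensity(learning_params(1, 1, 1), -1), "t")
})

test_that("accumulator CDF matches independent oracles", {
  # Poisson-tail oracle: P(5th event by t=5) = 1 - e^-5 sum_{k<5} 5^k/k!
  poisson_tail <- 1 - exp(-5) * sum(5^(0:4) / factorial(0:4))
  expect_equal(aoa_cdf(learning_params(5, 1, 1), 5), poisson_tail,
               tolerance = 1e-12)
  # Weibull closed form
  expect_equal(aoa_cdf(learning_params(1, 2, 0.01), 10), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(aoa_cdf(learning_params(8, 0.5, 2), 0), 0)
  expect_error(aoa_cdf(learning_params(1, 1, 1), -0.5), "t")
  # monotone, bounded
  ts <- seq(0, 60, length.out = 200)
  for (i in 1:5) {
    set.seed(i)
    pr <- random_learning_params()
    Fv <- aoa_cdf(pr, ts)
    expect_true(all(diff(Fv) >= 0))
    expect_true(all(Fv >= 0 & Fv <= 1))
  }
})

test_that("logistic CDF and mean follow the slope/intercept parameterization", {
  lp <- logistic_params(1, 5)
  expect_equal(aoa_cdf(lp, 5), 0.5)
  expect_equal(aoa_mean(lp), 5)
  expect_equal(aoa_quantile(lp, 0.5), 5)
  expect_true(aoa_cdf(lp, -10) > 0)  # logistic support is the whole line
})

test_that("pdf matches closed forms and is consistent with the CDF", {
  expect_equal(aoa_pdf(learning_params(2, 1, 1), 1), exp(-1), tolerance = 1e-12)
  expect_equal(aoa_pdf(learning_params(1, 1, 2), 0.5), 2 * exp(-1),
               tolerance = 1e-12)
  expect_error(aoa_pdf(learning_params(2, 1, 1), 0), "t")
  for (i in 1:5) {
    set.seed(100 + i)
    pr <- random_learning_params()
    # integrates to 1
    total <- stats::integrate(function(t) aoa_pdf(pr, t), 0, Inf,
                              rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
    # f = dF/dt by central difference
    ts <- aoa_quantile(pr, c(0.1, 0.3, 0.5, 0.7, 0.9))
    h <- 1e-5 * ts
    dF <- (aoa_cdf(pr, ts + h) - aoa_cdf(pr, ts - h)) / (2 * h)
    expect_equal(aoa_pdf(pr, ts), dF, tolerance = 1e-6)
  }
})

test_that("hazard equals f/(1-F) and shows the documented shapes", {
  expect_equal(aoa_hazard(learning_params(1, 1, 0.3), c(1, 5, 20)),
               rep(0.3, 3), tolerance = 1e-12)
  wb <- learning_params(1, 3, 0.01)
  tw <- seq(0.5, aoa_quantile(wb, 0.999), length.out = 100)
  expect_true(all(diff(aoa_hazard(wb, tw)) > 0))
  ts <- seq(0.5, 50, length.out = 300)
  # peaked: unique interior maximum on (0, 50] (mean 5 puts the peak inside)
  h <- aoa_hazard(learning_params(8, 0.5, rate_for_mean(8, 0.5, 5)), ts)
  peak <- which.max(h)
  expect_gt(peak, 1)
  expect_lt(peak, length(ts))
  expect_true(all(diff(h[1:peak]) > 0))
  expect_true(all(diff(h[peak:length(h)]) < 0))
  # mutual consistency: hazard * (1 - F) = f
  for (i in 1:5) {
    set.seed(200 + i)
    pr <- random_learning_params()
    tg <- aoa_quantile(pr, seq(0.05, 0.95, by = 0.1))
    expect_equal(aoa_hazard(pr, tg) * (1 - aoa_cdf(pr, tg)), aoa_pdf(pr, tg),
                 tolerance = 1e-8)
  }
  # saturated CDF yields the documented +Inf sentinel
  expect_identical(aoa_hazard(learning_params(1, 1, 5), 1e4), Inf)
})

test_that("closed-form mean agrees with numeric integration", {
  expect_equal(aoa_mean(learning_params(5, 1, 1)), 5)
  expect_equal(aoa_mean(learning_params(1, 1, 2)), 0.5)
  for (i in 1:20) {
    set.seed(300 + i)
    pr <- random_learning_params()
    upper <- aoa_quantile(pr, 1 - 1e-12)  # truncation error ~1e-10 relative
    mi <- stats::integrate(function(t) t * aoa_pdf(pr, t), 0, upper,
                           rel.tol = 1e-9)$value
    expect_equal(aoa_mean(pr), mi, tolerance = 1e-6)
  }
})

test_that("quantile inverts the CDF", {
  expect_equal(aoa_quantile(learning_params(1, 1, 1), 0.5), log(2),
               tolerance = 1e-12)
  expect_error(aoa_quantile(learning_params(1, 1, 1), 0), "q")
  expect_error(aoa_quantile(learning_params(1, 1, 1), 1), "q")
  qs <- seq(0.01, 0.99, by = 0.07)
  for (i in 1:10) {
    set.seed(400 + i)
    pr <- random_learning_params()
    ts <- aoa_quantile(pr, qs)
    expect_true(all(diff(ts) > 0))
    expect_equal(aoa_cdf(pr, ts), qs, tolerance = 1e-8)
  }
})

test_that("reduction identities hold against stats distributions", {
  ts <- seq(0.2, 30, length.out = 40)
  # N = 1: Weibull with shape D, scale delta^(-1/D)
  pr <- learning_params(1, 2.5, 0.004)
  expect_equal(aoa_cdf(pr, ts),
               stats::pweibull(ts, shape = 2.5, scale = 0.004^(-1 / 2.5)),
               tolerance = 1e-10)
  # D = 1: gamma with shape N, rate delta
  pr <- learning_params(4.5, 1, 0.3)
  expect_equal(aoa_cdf(pr, ts), stats::pgamma(ts, shape = 4.5, rate = 0.3),
               tolerance = 1e-10)
  expect_equal(aoa_pdf(pr, ts), stats::dgamma(ts, shape = 4.5, rate = 0.3),
               tolerance = 1e-10)
  # N = D = 1: exponential
  pr <- learning_params(1, 1, 0.7)
  expect_equal(aoa_cdf(pr, ts), stats::pexp(ts, 0.7), tolerance = 1e-10)
})

test_that("rescaling delta by c^-D rescales ages by c", {
  for (i in 1:5) {
    set.seed(500 + i)
    pr <- random_learning_params()
    cc <- 10^stats::runif(1, -0.5, 0.5)
    pr2 <- learning_params(pr$N, pr$D, pr$delta * cc^(-pr$D))
    ts <- seq(0.5, 25, length.out = 30)
    expect_equal(aoa_cdf(pr2, cc * ts), aoa_cdf(pr, ts), tolerance = 1e-10)
    expect_equal(aoa_mean(pr2), cc * aoa_mean(pr), tolerance = 1e-10)
  }
})

test_that("hazard-shape classification agrees with a numeric scan", {
  expect_identical(classify_hazard_shape(learning_params(8, 0.5, 1)), "peaked")
  expect_identical(classify_hazard_shape(learning_params(1, 1, 0.4)), "constant")
  expect_identical(classify_hazard_shape(learning_params(5, 1, 1)),
                   "monotone_increasing")
  expect_identical(classify_hazard_shape(learning_params(1, 0.6, 1)),
                   "monotone_decreasing")
  expect_identical(classify_hazard_shape(learning_params(0.2, 3, 0.05)),
                   "bathtub")
  cases <- list(
    learning_params(1, 2.4, 0.01), learning_params(3, 1, 0.3),
    learning_params(12, 0.4, 2), learning_params(0.5, 1.1, 0.2),
    learning_params(0.7, 0.9, 0.4), learning_params(2, 2, 0.01),
    learning_params(6, 0.25, 2.5), learning_params(1, 0.5, 1)
  )
  for (pr in cases) {
    # scale to a mean of ~10 so the scan grid sees the whole shape
    pr_s <- learning_params(pr$N, pr$D,
                            rate_for_mean(pr$N, pr$D, 10))
    expect_identical(classify_hazard_shape(pr_s), scan_hazard_shape(pr_s),
                     info = sprintf("N=%g D=%g", pr$N, pr$D))
  }
})
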