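# Frozen oracle values computed independently with mpmath (30-digit
# polylogarithm series) and closed forms.

test_that("pmf matches closed forms and the series oracle", {
  ztp <- degree_model("ztp", lambda = 2)
  expect_equal(degree_pmf(ztp, 1), 2 * exp(-2) / (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(degree_pmf(ztp, 1), 0.313035285499331, tolerance = 1e-12)
  expect_identical(degree_pmf(ztp, 0), 0)

  p012 <- degree_model("polylog", lambda = 0.1, theta = 2)
  expect_equal(degree_pmf(p012, 1), 0.420884035030508, tolerance = 1e-10)
  expect_identical(degree_pmf(p012, 0), 0)

  p23 <- degree_model("polylog", lambda = 2, theta = 3)
  expect_equal(degree_pmf(p23, 4), 0.0179438289855687, tolerance = 1e-10)
  expect_equal(degree_pmf(p23, 5), 0.00822868179183456, tolerance = 1e-10)
})

test_that("model means match closed forms; polylog(0.1, 2) has mean 2.42", {
  expect_equal(model_mean(degree_model("ztp", lambda = 2)), 2 / (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(model_mean(degree_model("polylog", lambda = 0.1, theta = 2)),
               2.42248291431644, tolerance = 1e-9)
  expect_equal(round(model_mean(degree_model("polylog", lambda = 0.1, theta = 2)), 2), 2.42)
  expect_equal(model_mean(degree_model("polylog", lambda = 2, theta = 3)),
               1.37306211181224, tolerance = 1e-9)
})

test_that("pmf normalises and the mean equals its series for all three laws", {
  models <- list(
    degree_model("ztp", lambda = 2),
    degree_model("polylog", lambda = 0.1, theta = 2),
    degree_model("polylog", lambda = 2, theta = 3)
  )
  for (m in models) {
    k <- 0:400
    p <- degree_pmf(m, k)
    expect_gte(sum(p), 1 - 1e-9)
    expect_true(all(p >= 0))
    expect_equal(sum(k * p), model_mean(m), tolerance = 1e-6)
  }
})

test_that("tail ordering: polylog(0.1,2) heaviest, then ztp(2), then polylog(2,3)", {
  p012 <- degree_model("polylog", lambda = 0.1, theta = 2)
  ztp <- degree_model("ztp", lambda = 2)
  p23 <- degree_model("polylog", lambda = 2, theta = 3)
  # full ordering holds in the moderate tail (the Poisson tail eventually
  # drops below the geometric polylog(2,3) tail past k ~ 8)
  expect_gt(degree_pmf(p012, 7), degree_pmf(ztp, 7))
  expect_gt(degree_pmf(ztp, 7), degree_pmf(p23, 7))
  expect_gt(degree_pmf(p012, 10), degree_pmf(ztp, 10))
  expect_gt(degree_pmf(p012, 10), degree_pmf(p23, 10))
})

test_that("degree sampling is even-summed, deterministic, and unbiased", {
  ztp <- degree_model("ztp", lambda = 2)
  for (i in 1:20) {
    expect_identical(sum(sample_degrees(ztp, 2)) %% 2, 0)
  }
  set.seed(7)
  a <- sample_degrees(ztp, 100)
  set.seed(7)
  b <- sample_degrees(ztp, 100)
  expect_identical(a, b)

  set.seed(11)
  d <- sample_degrees(ztp, 1e5)
  mu <- model_mean(ztp)
  v <- sum((0:50)^2 * degree_pmf(ztp, 0:50)) - mu^2
  expect_lt(abs(mean(d) - mu), 3 * sqrt(v / 1e5))
})

test_that("inadmissible parameters and supports are rejected", {
  expect_error(degree_model("ztp", lambda = -1), "lambda")
  expect_error(degree_model("ztp"), "lambda")
  expect_error(degree_model("polylog", lambda = -0.5, theta = 2), "exponent")
  expect_error(degree_model("polylog", lambda = 1, theta = 0), "theta")
  expect_error(degree_pmf(degree_model("ztp", lambda = 2), -1), "non-negative")
  expect_error(degree_model("empirical", k = 1:2, prob = c(-1, 2)), "non-negative")
})

test_that("empirical family reproduces its table", {
  m <- degree_model("empirical", k = c(1, 3, 4), prob = c(0.5, 0.25, 0.25))
  expect_equal(degree_pmf(m, c(0, 1, 2, 3, 4)), c(0, 0.5, 0, 0.25, 0.25))
  expect_equal(model_mean(m), 0.5 + 0.75 + 1)
  set.seed(3)
  d <- sample_degrees(m, 1000)
  expect_true(all(d %in% c(1, 3, 4)))
})
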