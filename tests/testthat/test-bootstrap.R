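test_that("f_star and mu_star reproduce the worked multiset fixture exactly", {
  fs <- f_star(c(2, 0, 3), c(2, 2, 3))
  expect_equal(fs$prob[fs$k == 0], 1 / 3, tolerance = 1e-15)
  expect_equal(fs$prob[fs$k == 2], 7 / 18, tolerance = 1e-15)
  expect_equal(fs$prob[fs$k == 3], 5 / 18, tolerance = 1e-15)
  expect_equal(mu_star(c(2, 0, 3), c(2, 2, 3)), 29 / 18, tolerance = 1e-15)
})

test_that("degenerate multisets: seeds-only, all-zero seeds, symmetry", {
  fs <- f_star(c(2, 0, 3))
  expect_equal(fs$prob[fs$k %in% c(0, 2, 3)], rep(1 / 3, 3))
  expect_equal(mu_star(c(2, 0, 3)), 5 / 3)

  fs0 <- f_star(c(0, 0, 0))
  expect_equal(fs0$prob[fs0$k == 0], 1)
  expect_equal(sum(fs0$prob), 1)

  expect_equal(
    mu_star(c(3, 0, 2), c(3, 2, 2)),
    mu_star(c(2, 0, 3), c(2, 2, 3))
  )
  expect_error(f_star(integer(), c(1, 2)), "non-empty")
  expect_error(f_star(c(1, 2), c(0, 2)), "degree >= 1")
})

test_that("estimator identities hold on random multisets", {
  set.seed(17)
  for (i in 1:500) {
    s <- sample(0:8, sample(1:30, 1), replace = TRUE)
    ns <- sample(1:8, sample(0:60, 1), replace = TRUE)
    fs <- f_star(s, ns)
    expect_lt(abs(sum(fs$prob) - 1), 1e-12)
    expect_lt(abs(sum(fs$prob[fs$k >= 1]) - (1 - mean(s == 0))), 1e-12)
    expect_lt(abs(sum(fs$k * fs$prob) - mu_star(s, ns)), 1e-12)
  }
})

make_patchset <- function(seed_degrees, nonseed_degrees) {
  # a minimal handmade patch set: all non-seed records hang off one seed
  patches <- lapply(seq_along(seed_degrees), function(i) {
    waves <- if (i == 1) {
      list(list(
        vertex = seq_along(nonseed_degrees) + 100L,
        degree = as.integer(nonseed_degrees)
      ))
    } else {
      list(list(vertex = integer(), degree = integer()))
    }
    list(seed = i, seed_degree = as.integer(seed_degrees[i]), waves = waves)
  })
  structure(
    list(patches = patches, d_max = 1L, seeds = seq_along(seed_degrees)),
    class = "patch_set"
  )
}

test_that("resampling is deterministic under a seed and yields proper pmfs", {
  ps <- make_patchset(c(2, 3, 1, 2), c(1, 2, 2, 3, 4, 1))
  set.seed(5)
  a <- resample_patches(ps, 50)
  set.seed(5)
  b <- resample_patches(ps, 50)
  expect_identical(a, b)
  expect_true(all(abs(colSums(a$values) - 1) < 1e-12))
  expect_true(all(a$values >= 0))

  const <- make_patchset(c(3, 3, 3), c(3, 3, 3, 3))
  mu <- resample_patches(const, 20, statistic = "mean_degree")
  expect_equal(as.numeric(mu$values), rep(3, 20))
})

test_that("seeds-only views reduce to plain seed resampling", {
  ps <- make_patchset(c(2, 4, 6), integer())
  ps0 <- subpatch(ps, 3, 0)
  set.seed(9)
  bs <- resample_patches(ps0, 200, statistic = "mean_degree")
  # every replicate is a mean of three values drawn from {2, 4, 6}
  sums <- as.numeric(bs$values) * 3
  expect_true(all(abs(sums - round(sums)) < 1e-9))
  expect_true(all(round(sums) %in% seq(6, 18, by = 2)))
})

test_that("inverse-degree weights equalise non-seed representation", {
  # pool: one degree-10 record, nine degree-1 records; with 1/k weights the
  # degree-10 record should be drawn with probability (1/10)/(9 + 1/10)
  ps <- make_patchset(c(1, 1), c(10, rep(1, 9)))
  set.seed(23)
  bs <- resample_patches(ps, 2000)
  prop10 <- mean(bs$values[11, ] * 12) / 10 # mean count of 10s per replicate / 10
  expect_equal(prop10, (1 / 10) / (9 + 1 / 10), tolerance = 0.25)
  set.seed(23)
  bu <- resample_patches(ps, 2000, weights = "uniform")
  prop10_u <- mean(bu$values[11, ] * 12) / 10
  expect_gt(prop10_u, 3 * prop10) # uniform resampling over-represents hubs
})

test_that("Efron interval follows the 1-based ceiling rank rule", {
  mk <- function(values) {
    structure(
      list(statistic = "mean_degree", values = values, B = length(values),
           combo = c(m = 1L, w = 0L), k_max = 1L),
      class = "boot_sample"
    )
  }
  expect_warning(ci <- efron_ci(mk(c(4, 2, 1, 5, 3)), alpha = 0.05), "coarse")
  expect_equal(c(ci$lower, ci$upper), c(1, 5))
  ci99 <- efron_ci(mk(sample(1:500)), alpha = 0.99)
  expect_equal(c(ci99$lower, ci99$upper), c(248, 253)) # ranks ceil(247.5), ceil(252.5)
  expect_lte(ci99$lower, stats::median(1:500))
  expect_gte(ci99$upper, stats::median(1:500))
  ci_const <- efron_ci(mk(rep(7, 100)), alpha = 0.05)
  expect_equal(c(ci_const$lower, ci_const$upper), c(7, 7))
})

test_that("intervals for degrees beyond the observed grid collapse to zero", {
  ps <- make_patchset(c(2, 2, 2), c(1, 2, 2))
  set.seed(2)
  bs <- resample_patches(ps, 100)
  ci <- efron_ci(bs, k = 40)
  expect_equal(c(ci$lower, ci$upper), c(0, 0))
})

test_that("tidy views of bootstrap samples are well-formed", {
  ps <- make_patchset(c(2, 3, 1), c(1, 2, 3))
  set.seed(3)
  bs <- resample_patches(ps, 10)
  td <- tidy(bs)
  expect_identical(nrow(td), 10L * nrow(bs$values))
  expect_true(all(c("replicate", "k", "prob") %in% names(td)))
  mu <- resample_patches(ps, 10, statistic = "mean_degree")
  expect_identical(names(tidy(mu)), c("replicate", "mu"))
})
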