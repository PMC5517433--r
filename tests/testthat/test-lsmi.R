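test_that("hand-traced patches: path, triangle, square, zero waves", {
  path <- simple_net(rbind(c(0, 1), c(1, 2), c(2, 3)))
  ps <- lsmi(path, seeds = 2L, d = 1) # vertex labelled 1
  p <- ps$patches[[1]]
  expect_identical(p$seed_degree, 2L)
  expect_identical(sort(p$waves[[1]]$degree), c(1L, 2L))

  ps0 <- lsmi(path, seeds = 2L, d = 0)
  expect_length(ps0$patches[[1]]$waves, 0)

  tri <- simple_net(rbind(c(0, 1), c(0, 2), c(1, 2)))
  ps <- lsmi(tri, seeds = 1L, d = 2)
  p <- ps$patches[[1]]
  expect_identical(sort(p$waves[[1]]$degree), c(2L, 2L))
  # edge 1-2 is traced at wave 2 but both endpoints are already recorded
  expect_length(p$waves[[2]]$degree, 0)

  sq <- simple_net(rbind(c(0, 1), c(0, 2), c(1, 3), c(2, 3)))
  ps <- lsmi(sq, seeds = 1L, d = 2)
  p <- ps$patches[[1]]
  expect_identical(sort(p$waves[[1]]$degree), c(2L, 2L))
  # opposite corner is reached along two distinct untraced edges: two records
  expect_identical(p$waves[[2]]$degree, c(2L, 2L))
  expect_identical(unique(p$waves[[2]]$vertex), 4L)
})

test_that("seed sampling is uniform without replacement", {
  g <- random_connected_graph(23)
  expect_setequal(sample_seeds(g, 23), 1:23)
  expect_error(sample_seeds(g, 24), "between")
  set.seed(13)
  draws <- replicate(1e4, sample_seeds(g, 1))
  expect_gt(stats::chisq.test(table(factor(draws, levels = 1:23)))$p.value, 0.01)
})

test_that("subpatch is a pure prefix view, monotone in seeds and waves", {
  set.seed(21)
  g <- random_connected_graph(23)
  ps <- lsmi(g, sample_seeds(g, 8), d = 3)
  expect_identical(subpatch(ps, 8, 3), ps)
  expect_length(subpatch(ps, 8, 0)$patches[[1]]$waves, 0)
  expect_error(subpatch(ps, 9, 3), "out of range")
  expect_error(subpatch(ps, 8, 4), "out of range")
  count_ns <- function(p) length(patchboot:::patch_pools(p)$nonseed)
  for (m in 1:8) {
    for (w in 0:3) {
      expect_gte(count_ns(subpatch(ps, min(m + 1, 8), w)), count_ns(subpatch(ps, m, w)))
      if (w < 3) expect_gte(count_ns(subpatch(ps, m, w + 1)), count_ns(subpatch(ps, m, w)))
    }
  }
})

test_that("lsmi agrees with the brute-force enumerator on all small graphs", {
  res <- oracle_check()
  expect_gt(res$graphs, 700)
  expect_identical(res$mismatches, 0L)
  expect_identical(res$ledger_violations, 0L)
})

test_that("seeds-only mean-degree estimator is unbiased", {
  g <- fixed_ztp_graph()
  truth <- mean(g$deg)
  set.seed(31)
  means <- replicate(1e4, mean(g$deg[sample.int(g$n, 10)]))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - truth), 3 * se)
})

test_that("adding waves shrinks the bootstrap spread of the mean degree", {
  set.seed(41)
  g <- sample_network(degree_model("polylog", lambda = 0.1, theta = 2), 1e4)
  wd <- wave_diagnostic(g, m = 30, wave_list = c(0, 2), B = 500)
  sd0 <- wd$summary$sd[wd$summary$w == 0]
  sd2 <- wd$summary$sd[wd$summary$w == 2]
  expect_lt(sd2, sd0)
})

test_that("patch sets round-trip through JSON", {
  set.seed(51)
  g <- random_connected_graph(15)
  ps <- lsmi(g, sample_seeds(g, 4), d = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_patches(ps, f)
  ps2 <- read_patches(f)
  expect_identical(ps2$seeds, ps$seeds)
  expect_identical(ps2$d_max, ps$d_max)
  for (i in seq_along(ps$patches)) {
    expect_identical(ps2$patches[[i]]$seed_degree, ps$patches[[i]]$seed_degree)
    for (w in seq_len(ps$d_max)) {
      expect_identical(ps2$patches[[i]]$waves[[w]]$degree, ps$patches[[i]]$waves[[w]]$degree)
    }
  }
})

test_that("patch tibble view carries one row per inclusion record", {
  g <- simple_net(rbind(c(0, 1), c(0, 2), c(1, 3), c(2, 3)))
  tb <- as_tibble(lsmi(g, seeds = 1L, d = 2))
  expect_identical(nrow(tb), 5L) # seed + two wave-1 + two wave-2 records
  expect_identical(sum(tb$wave == 0), 1L)
})
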