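# Data-driven choice of the seed-wave combination.
#
# One maximal snowball sample serves every combination of the grid: smaller
# seed counts are prefixes of the ordered seed draw and shallower waves are
# truncations (see subpatch()). Each combination j yields a bootstrap
# percentile interval BCI_j; cheap proxy point estimates of the target,
# computed seeds-only from fresh uniform vertex samples, are then used to
# score each interval by how close the fraction of proxies it contains is to
# the nominal level. The combination with proxy coverage closest to 1-alpha
# wins; ties prefer the narrower interval, then fewer waves, then fewer
# seeds.

#' Seed-wave grid
#'
#' @param seed_counts Strictly increasing positive seed counts.
#' @param wave_depths Wave depths (positive; 0 allowed for diagnostics).
#' @return A `seed_wave_grid`: tibble of all `J = l * d` combinations with
#'   columns `m` and `w`.
#' @export
seed_wave_grid <- function(seed_counts = c(20, 30, 40, 50), wave_depths = 1:5) {
  if (any(seed_counts <= 0) || any(diff(seed_counts) <= 0)) {
    stop("seed_counts must be positive and strictly increasing", call. = FALSE)
  }
  if (any(wave_depths < 0)) stop("wave_depths must be >= 0", call. = FALSE)
  g <- tidyr::expand_grid(m = as.integer(seed_counts), w = as.integer(sort(wave_depths)))
  class(g) <- c("seed_wave_grid", class(g))
  g
}

# normalise a target argument: "mean" or a non-negative integer k (meaning f(k))
normalize_target <- function(target) {
  if (identical(target, "mean") || identical(target, "mean_degree")) {
    return(list(type = "mean", k = NA_integer_, label = "mean_degree"))
  }
  if (is.numeric(target) && length(target) == 1 && target >= 0 && target == floor(target)) {
    return(list(type = "fk", k = as.integer(target), label = sprintf("f(%d)", as.integer(target))))
  }
  stop("target must be \"mean\" or a non-negative integer k", call. = FALSE)
}

# replicate values of one target from an fk_vector boot_sample
boot_component <- function(sample, tgt) {
  stopifnot(identical(sample$statistic, "fk_vector"))
  if (tgt$type == "mean") {
    colSums(sample$values * (0:(nrow(sample$values) - 1L)))
  } else if (tgt$k >= nrow(sample$values)) {
    rep(0, sample$B)
  } else {
    sample$values[tgt$k + 1L, ]
  }
}

# degrees of proxy_reps independent uniform without-replacement vertex
# samples of proxy_size: a proxy_size x proxy_reps matrix
proxy_degree_draws <- function(graph, proxy_size, proxy_reps) {
  if (proxy_size > graph$n) stop("proxy_size exceeds graph order", call. = FALSE)
  vapply(
    seq_len(proxy_reps),
    function(i) graph$deg[sample.int(graph$n, proxy_size)],
    integer(proxy_size)
  )
}

#' Seeds-only proxy point estimates
#'
#' Each repetition draws `proxy_size` vertices uniformly without replacement
#' and computes the target seeds-only: the sample mean degree, or the sample
#' proportion of degree-`k` vertices. These unbiased, cheap estimates are the
#' yardstick the cross-validation scores candidate intervals against.
#'
#' @param graph A [simple_net()].
#' @param proxy_size Vertices per repetition.
#' @param proxy_reps Number of repetitions.
#' @param target `"mean"` or an integer degree `k` (targets `f(k)`).
#' @return Numeric vector of `proxy_reps` point estimates.
#' @export
proxy_estimates <- function(graph, proxy_size, proxy_reps, target = "mean") {
  stopifnot(inherits(graph, "simple_net"), proxy_reps >= 1)
  tgt <- normalize_target(target)
  draws <- proxy_degree_draws(graph, proxy_size, proxy_reps)
  if (tgt$type == "mean") colMeans(draws) else colMeans(draws == tgt$k)
}

# combo selection rule, isolated so alternative policies are a one-function
# swap: proxy coverage closest to nominal, ties to the narrower interval,
# then fewer waves, then fewer seeds
select_combo <- function(table, alpha) {
  order(abs(table$coverage - (1 - alpha)), table$width, table$w, table$m)[1]
}

# shared FPB engine: one maximal LSMI, per-combo bootstrap of the full f(k)
# vector, proxy scoring of the cv_target statistic, one combo choice, and
# interval read-off for every requested target at the chosen combo.
# targets/cv_target: normalised target lists (see normalize_target()).
fpb_engine <- function(graph, grid, B, alpha, targets, cv_target,
                       proxy_size, proxy_reps, weights = "inverse_degree") {
  m_max <- max(grid$m)
  d_max <- max(grid$w)
  if (m_max > graph$n) stop("largest seed count exceeds graph order", call. = FALSE)
  seeds <- sample_seeds(graph, m_max)
  ps <- lsmi(graph, seeds, d_max)
  samples <- vector("list", nrow(grid))
  for (j in seq_len(nrow(grid))) {
    samples[[j]] <- resample_patches(
      subpatch(ps, grid$m[j], grid$w[j]), B,
      statistic = "fk_vector", weights = weights
    )
  }
  proxy_draws <- proxy_degree_draws(graph, proxy_size, proxy_reps)
  eta <- if (cv_target$type == "mean") {
    colMeans(proxy_draws)
  } else {
    colMeans(proxy_draws == cv_target$k)
  }
  tab <- purrr::map_dfr(seq_len(nrow(grid)), function(j) {
    vals <- boot_component(samples[[j]], cv_target)
    b <- efron_bounds(vals, alpha)
    tibble::tibble(
      m = grid$m[j], w = grid$w[j],
      lower = b[1], upper = b[2], width = b[2] - b[1],
      coverage = mean(eta >= b[1] & eta <= b[2])
    )
  })
  pick <- select_combo(tab, alpha)
  target_cis <- purrr::map_dfr(targets, function(tgt) {
    b <- efron_bounds(boot_component(samples[[pick]], tgt), alpha)
    tibble::tibble(
      target = tgt$label, m = grid$m[pick], w = grid$w[pick],
      lower = b[1], upper = b[2]
    )
  })
  list(
    patchset = ps, samples = samples, table = tab, chosen = pick,
    proxy = eta, target_cis = target_cis, grid = grid
  )
}

#' Cross-validated seed-wave selection
#'
#' Runs the full selection procedure for one target statistic: grows one
#' maximal snowball sample (the only [lsmi()] call), bootstraps every
#' combination of the grid from views of it, scores each combination's
#' percentile interval by the fraction of seeds-only proxy estimates it
#' contains, and picks the combination whose proxy coverage is closest to
#' `1 - alpha` (ties: narrower interval, fewer waves, fewer seeds).
#'
#' @param graph A [simple_net()].
#' @param grid A [seed_wave_grid()].
#' @param B Bootstrap replicates per combination.
#' @param proxy_size,proxy_reps Proxy sampling design (see
#'   [proxy_estimates()]).
#' @param alpha Significance level.
#' @param target `"mean"` or an integer degree `k`.
#' @param weights Non-seed resampling weights (see [resample_patches()]).
#' @return A `cv_report`: list with `table` (per-combo tibble: `m`, `w`,
#'   `lower`, `upper`, `width`, `coverage`), `chosen` (row index), `target`,
#'   `alpha`, `B`. [generics::tidy()] returns the table with a `chosen`
#'   flag; [generics::glance()] the selected row.
#' @export
cross_validate <- function(graph, grid = seed_wave_grid(), B = 500,
                           proxy_size = 100, proxy_reps = 13,
                           alpha = 0.05, target = "mean",
                           weights = c("inverse_degree", "uniform")) {
  weights <- match.arg(weights)
  stopifnot(inherits(graph, "simple_net"), proxy_reps >= 2)
  tgt <- normalize_target(target)
  eng <- fpb_engine(
    graph, grid, B, alpha, list(tgt), cv_target = tgt,
    proxy_size = proxy_size, proxy_reps = proxy_reps, weights = weights
  )
  structure(
    list(
      table = eng$table, chosen = eng$chosen, target = tgt$label,
      alpha = alpha, B = as.integer(B), proxy = eng$proxy
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  ch <- x$table[x$chosen, ]
  cat(sprintf(
    "<cv_report> target %s, %d combos, chosen m = %d seeds, w = %d waves\n",
    x$target, nrow(x$table), ch$m, ch$w
  ))
  cat(sprintf(
    "  %d%% CI (%.4g, %.4g), proxy coverage %.3f\n",
    round(100 * (1 - x$alpha)), ch$lower, ch$upper, ch$coverage
  ))
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::mutate(x$table, chosen = dplyr::row_number() == x$chosen)
}

#' @export
glance.cv_report <- function(x, ...) {
  dplyr::mutate(
    x$table[x$chosen, ],
    target = x$target, level = 1 - x$alpha, B = x$B,
    .before = 1
  )
}
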