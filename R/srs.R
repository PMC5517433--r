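# Competitor intervals from simple random sampling of vertex degrees.
# Both assume the graph order n is known — an information advantage over the
# patchwork bootstrap, which uses no such knowledge.

#' Simple random sample of vertex degrees
#'
#' @param graph A [simple_net()].
#' @param M Sample size (without replacement).
#' @return Integer vector of `M` degrees.
#' @export
srs_degrees <- function(graph, M) {
  stopifnot(inherits(graph, "simple_net"))
  if (M < 1 || M > graph$n) stop("M must be between 1 and the graph order", call. = FALSE)
  graph$deg[sample.int(graph$n, M)]
}

#' Normality-based interval for a degree proportion (NCI)
#'
#' `f_hat(k) +/- z * sigma_hat` with the finite-population-corrected
#' variance `sigma^2 = ((n - M)/n) * f_hat (1 - f_hat) / (M - 1)` and `z`
#' the upper `alpha/2` standard-normal point. The interval is reported as
#' the formula gives it, without truncation to `[0, 1]`.
#'
#' @param degrees Integer vector of `M` sampled degrees.
#' @param n Known graph order.
#' @param k Target degree.
#' @param alpha Significance level.
#' @return One-row tibble: `method`, `target`, `level`, `lower`, `upper`,
#'   `M`, `n`.
#' @examples
#' # f_hat = 0.2, M = 50, n = 2000 -> (0.0894, 0.3106)
#' nci(c(rep(2, 10), rep(1, 40)), n = 2000, k = 2)
#' @export
nci <- function(degrees, n, k, alpha = 0.05) {
  M <- length(degrees)
  if (M < 2) stop("NCI variance needs M >= 2", call. = FALSE)
  if (M > n) stop("M cannot exceed n", call. = FALSE)
  f_hat <- mean(degrees == k)
  sigma2 <- ((n - M) / n) * f_hat * (1 - f_hat) / (M - 1)
  z <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(
    method = "NCI", target = sprintf("f(%d)", as.integer(k)), level = 1 - alpha,
    lower = f_hat - z * sqrt(sigma2), upper = f_hat + z * sqrt(sigma2),
    M = M, n = as.integer(n)
  )
}

#' SRS quantile bootstrap interval for a degree proportion (QCI)
#'
#' Resamples the `M` sampled degrees with replacement `B` times, computes
#' the proportion at degree `k` per resample, and reads off the Efron
#' rank-rule percentile interval.
#'
#' @inheritParams nci
#' @param B Bootstrap resamples.
#' @return One-row tibble: `method`, `target`, `level`, `lower`, `upper`,
#'   `M`, `B`.
#' @export
qci <- function(degrees, k, B = 500, alpha = 0.05) {
  M <- length(degrees)
  if (M < 1 || B < 1) stop("need M >= 1 and B >= 1", call. = FALSE)
  hits <- degrees == k
  props <- colMeans(matrix(hits[sample.int(M, M * B, replace = TRUE)], nrow = M))
  b <- efron_bounds(props, alpha)
  tibble::tibble(
    method = "QCI", target = sprintf("f(%d)", as.integer(k)), level = 1 - alpha,
    lower = b[1], upper = b[2], M = M, B = as.integer(B)
  )
}
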