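# Within-patch resampling and the bootstrap degree-distribution estimators.
#
# One bootstrap replicate draws m seeds with replacement (uniform) from the
# observed seed degrees and the same number of non-seeds as observed, with
# replacement, from the pooled non-seed inclusion records with probability
# proportional to 1/degree. A non-seed is reached along an edge, so its
# inclusion probability grows with its degree; the inverse-degree weight is
# the Horvitz--Thompson correction for that unequal inclusion.
#
# The combined estimator, with p0* the proportion of zeros among the
# resampled seeds, ns(k) the resampled non-seed count at degree k, and
# s(k) the resampled seed count at degree k:
#
#   f*(k) = (s(k) + (1 - p0*) ns(k)) / (#seeds + #nonseeds),  k >= 1
#   f*(0) = p0*
#   mu*   = sum_k k f*(k)
#         = (sum seed degrees + (1 - p0*) sum non-seed degrees) / (#s + #ns)
#
# Summing the k >= 1 numerators gives (1 - p0*)(#s + #ns): the estimator is
# a proper pmf by construction.

#' Bootstrap degree-distribution estimate from one pair of multisets
#'
#' @param seed_degrees Integer multiset of resampled seed degrees (non-empty).
#' @param nonseed_degrees Integer multiset of resampled non-seed degrees
#'   (possibly empty; all entries must be `>= 1`).
#' @param k_max Highest degree of the returned grid (default: max observed).
#' @return A tibble with columns `k` (0..k_max) and `prob`, summing to 1.
#' @examples
#' f_star(c(2, 0, 3), c(2, 2, 3)) # f*(2) = 7/18, f*(3) = 5/18, f*(0) = 1/3
#' @export
f_star <- function(seed_degrees, nonseed_degrees = integer(), k_max = NULL) {
  if (!length(seed_degrees)) stop("seed multiset must be non-empty", call. = FALSE)
  if (length(nonseed_degrees) && any(nonseed_degrees < 1)) {
    stop("non-seed records must have degree >= 1", call. = FALSE)
  }
  if (is.null(k_max)) k_max <- max(seed_degrees, nonseed_degrees, 0L)
  ns_tot <- length(nonseed_degrees)
  s_tot <- length(seed_degrees)
  p0 <- sum(seed_degrees == 0) / s_tot
  k <- 0:k_max
  s_k <- tabulate(seed_degrees, nbins = k_max)          # counts at k = 1..k_max
  ns_k <- tabulate(nonseed_degrees, nbins = k_max)
  # with no non-seeds this reduces to the empirical seed pmf
  prob <- c(p0, (s_k + (1 - p0) * ns_k) / (s_tot + ns_tot))
  tibble::tibble(k = k, prob = prob)
}

#' Bootstrap mean-degree estimate from one pair of multisets
#'
#' Equals `sum(k * f_star(...)$prob)` exactly.
#'
#' @inheritParams f_star
#' @return A single numeric value.
#' @examples
#' mu_star(c(2, 0, 3), c(2, 2, 3)) # 29/18
#' @export
mu_star <- function(seed_degrees, nonseed_degrees = integer()) {
  if (!length(seed_degrees)) stop("seed multiset must be non-empty", call. = FALSE)
  if (length(nonseed_degrees) && any(nonseed_degrees < 1)) {
    stop("non-seed records must have degree >= 1", call. = FALSE)
  }
  if (!length(nonseed_degrees)) return(mean(seed_degrees))
  p0 <- mean(seed_degrees == 0)
  (sum(seed_degrees) + (1 - p0) * sum(nonseed_degrees)) /
    (length(seed_degrees) + length(nonseed_degrees))
}

#' Resample within patches
#'
#' Produces `B` bootstrap replicates of either the full degree-probability
#' vector or the mean degree, from a patch-set view. Per replicate, seeds are
#' resampled uniformly with replacement; non-seeds are resampled with
#' replacement from the pooled inclusion records with weight proportional to
#' `1/degree` (`weights = "inverse_degree"`, the default) or uniformly
#' (`weights = "uniform"`, for ablation). The number of resampled non-seeds
#' equals the observed non-seed record count, keeping the information volume
#' of each replicate fixed.
#'
#' @param patchset A `patch_set` view (see [subpatch()]).
#' @param B Number of bootstrap replicates.
#' @param statistic `"fk_vector"` or `"mean_degree"`.
#' @param weights Non-seed resampling weights.
#' @param k_max Degree grid cap for `"fk_vector"` (default: max degree
#'   observed in the view).
#' @return A `boot_sample`: list with `statistic`, `values` (a `(k_max+1) x B`
#'   matrix for `"fk_vector"`, rows indexed by degree 0..k_max; a length-`B`
#'   vector for `"mean_degree"`), `B`, and `combo = c(m, w)`.
#' @export
resample_patches <- function(patchset, B,
                             statistic = c("fk_vector", "mean_degree"),
                             weights = c("inverse_degree", "uniform"),
                             k_max = NULL) {
  statistic <- match.arg(statistic)
  weights <- match.arg(weights)
  stopifnot(inherits(patchset, "patch_set"), B >= 1)
  pools <- patch_pools(patchset)
  m <- length(pools$seed)
  if (!m) stop("patch set has no seeds", call. = FALSE)
  nns <- length(pools$nonseed)
  if (patchset$d_max > 0 && nns == 0) {
    warning("no non-seed records in view; falling back to seeds-only resampling")
  }
  if (is.null(k_max)) k_max <- max(pools$seed, pools$nonseed, 1L)

  S <- matrix(pools$seed[sample.int(m, m * B, replace = TRUE)], nrow = m)
  if (nns) {
    w <- if (weights == "inverse_degree") 1 / pools$nonseed else rep(1, nns)
    NS <- matrix(
      pools$nonseed[sample.int(nns, nns * B, replace = TRUE, prob = w)],
      nrow = nns
    )
  } else {
    NS <- matrix(integer(), nrow = 0, ncol = B)
  }

  p0 <- colSums(S == 0) / m
  if (statistic == "mean_degree") {
    ns_sum <- if (nns) colSums(NS) else rep(0, B)
    values <- (colSums(S) + (1 - p0) * ns_sum) / (m + nns)
  } else {
    # per-column tabulation in one pass: offset degrees by column
    bins <- k_max + 1L
    s_counts <- matrix(
      tabulate(as.vector(S) + 1L + bins * rep(0:(B - 1L), each = m), nbins = bins * B),
      nrow = bins
    )
    if (nns) {
      ns_counts <- matrix(
        tabulate(as.vector(NS) + 1L + bins * rep(0:(B - 1L), each = nns), nbins = bins * B),
        nrow = bins
      )
    } else {
      ns_counts <- matrix(0, nrow = bins, ncol = B)
    }
    values <- (s_counts[-1L, , drop = FALSE] +
                 sweep(ns_counts[-1L, , drop = FALSE], 2, 1 - p0, "*")) / (m + nns)
    values <- rbind(p0, values)
    rownames(values) <- NULL
  }
  structure(
    list(
      statistic = statistic, values = values, B = as.integer(B),
      combo = c(m = m, w = patchset$d_max), k_max = as.integer(k_max)
    ),
    class = "boot_sample"
  )
}

#' @export
print.boot_sample <- function(x, ...) {
  cat(sprintf(
    "<boot_sample> %s, B = %d, combo (m = %d seeds, w = %d waves)\n",
    x$statistic, x$B, x$combo["m"], x$combo["w"]
  ))
  invisible(x)
}

#' @export
tidy.boot_sample <- function(x, ...) {
  if (x$statistic == "mean_degree") {
    tibble::tibble(replicate = seq_len(x$B), mu = as.numeric(x$values))
  } else {
    tibble::tibble(
      replicate = rep(seq_len(x$B), each = nrow(x$values)),
      k = rep(0:(nrow(x$values) - 1L), x$B),
      prob = as.numeric(x$values)
    )
  }
}

# rank-rule percentile bounds: 1-based ceiling order statistics
efron_bounds <- function(values, alpha) {
  v <- sort(values)
  B <- length(v)
  lo <- v[max(1L, ceiling(B * alpha / 2))]
  hi <- v[max(1L, ceiling(B * (1 - alpha / 2)))]
  c(lo, hi)
}

#' Efron percentile confidence interval
#'
#' Endpoints are the empirical `alpha/2` and `1 - alpha/2` quantiles of the
#' bootstrap replicates, taken as 1-based ceiling order statistics: the
#' values at ranks `ceiling(B * alpha/2)` and `ceiling(B * (1 - alpha/2))`.
#'
#' @param sample A `boot_sample` from [resample_patches()].
#' @param alpha Significance level (interval level is `1 - alpha`).
#' @param k For an `"fk_vector"` sample, the degree whose probability the
#'   interval targets; ignored for `"mean_degree"`.
#' @return A one-row tibble: `target`, `m`, `w`, `level`, `lower`, `upper`,
#'   `B`.
#' @export
efron_ci <- function(sample, alpha = 0.05, k = NULL) {
  stopifnot(inherits(sample, "boot_sample"), alpha > 0, alpha < 1)
  if (sample$B < 2 / alpha) {
    warning(sprintf("B = %d is small for alpha = %g; quantiles are coarse", sample$B, alpha))
  }
  if (sample$statistic == "mean_degree") {
    vals <- as.numeric(sample$values)
    target <- "mean_degree"
  } else {
    if (is.null(k)) stop("k must be given for an fk_vector sample", call. = FALSE)
    if (k < 0 || k >= nrow(sample$values)) {
      vals <- rep(0, sample$B) # mass beyond the observed grid is zero
    } else {
      vals <- sample$values[k + 1L, ]
    }
    target <- sprintf("f(%d)", k)
  }
  b <- efron_bounds(vals, alpha)
  tibble::tibble(
    target = target,
    m = unname(sample$combo["m"]), w = unname(sample$combo["w"]),
    level = 1 - alpha, lower = b[1], upper = b[2], B = sample$B
  )
}
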