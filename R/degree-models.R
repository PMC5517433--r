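#' Parametric degree laws
#'
#' A `degree_model` is a named parametric law for vertex degrees, used both to
#' generate synthetic networks and as the ground truth that Monte Carlo
#' coverage is computed against. Three families are supported:
#'
#' * `"ztp"` — zero-truncated Poisson with rate `lambda > 0`:
#'   `f(k) = exp(-lambda) lambda^k / (k! (1 - exp(-lambda)))`, `k >= 1`.
#' * `"polylog"` — polylogarithmic with exponent `lambda >= 0` and scale
#'   `theta > 0`: `f(k) = k^(-lambda) z^k / Li_lambda(z)` with
#'   `z = exp(-1/theta)`, `k >= 1`. The normalising constant is the
#'   polylogarithm `Li_s(z) = sum_{k>=1} z^k k^(-s)`.
#' * `"empirical"` — an explicit finite probability table over degrees.
#'
#' Both parametric families put no mass at degree 0: they describe networks
#' from which isolated vertices have been removed.
#'
#' @param family One of `"ztp"`, `"polylog"`, `"empirical"`.
#' @param lambda Rate (ztp) or exponent (polylog).
#' @param theta Scale of the polylog family (`z = exp(-1/theta)`).
#' @param k,prob Degree values and probabilities for the empirical family;
#'   `prob` must be non-negative and is normalised to sum to one.
#'
#' @return An object of class `degree_model`.
#' @examples
#' m <- degree_model("polylog", lambda = 0.1, theta = 2)
#' model_mean(m) # 2.42 at two decimals
#' degree_pmf(degree_model("ztp", lambda = 2), 1:5)
#' @export
degree_model <- function(family = c("ztp", "polylog", "empirical"),
                         lambda = NULL, theta = NULL, k = NULL, prob = NULL) {
  family <- match.arg(family)
  params <- switch(family,
    ztp = {
      if (is.null(lambda) || !is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
        stop("ztp family requires a single rate lambda > 0", call. = FALSE)
      }
      list(lambda = as.numeric(lambda))
    },
    polylog = {
      if (is.null(lambda) || lambda < 0) {
        stop("polylog family requires exponent lambda >= 0", call. = FALSE)
      }
      if (is.null(theta) || theta <= 0) {
        stop("polylog family requires scale theta > 0", call. = FALSE)
      }
      list(lambda = as.numeric(lambda), theta = as.numeric(theta))
    },
    empirical = {
      if (is.null(k) || is.null(prob) || length(k) != length(prob)) {
        stop("empirical family requires matching k and prob vectors", call. = FALSE)
      }
      if (any(prob < 0) || sum(prob) <= 0) stop("prob must be non-negative with positive sum", call. = FALSE)
      if (any(k != floor(k)) || any(k < 0)) stop("k must be non-negative integers", call. = FALSE)
      o <- order(k)
      list(k = as.integer(k[o]), prob = prob[o] / sum(prob[o]))
    }
  )
  structure(list(family = family, params = params), class = "degree_model")
}

#' @export
print.degree_model <- function(x, ...) {
  p <- x$params
  lab <- switch(x$family,
    ztp = sprintf("zero-truncated Poisson(%g)", p$lambda),
    polylog = sprintf("polylogarithmic(%g, %g)", p$lambda, p$theta),
    empirical = sprintf("empirical law on %d degrees", length(p$k))
  )
  cat("<degree_model> ", lab, ", mean degree ", format(model_mean(x), digits = 5), "\n", sep = "")
  invisible(x)
}

# Polylogarithm Li_s(z) = sum_{k>=1} z^k / k^s by direct series with Kahan
# compensated summation. Converges geometrically for |z| < 1; the degree laws
# used here have z <= exp(-1/3), so no acceleration is needed.
polylog_li <- function(s, z, tol = 1e-15, max_terms = 1e6L) {
  if (z <= 0 || z >= 1) stop("polylog_li requires 0 < z < 1", call. = FALSE)
  total <- 0
  comp <- 0
  zk <- 1
  for (k in seq_len(max_terms)) {
    zk <- zk * z
    term <- zk / k^s
    y <- term - comp
    t <- total + y
    comp <- (t - total) - y
    total <- t
    # geometric tail bound: remaining mass < term * z / (1 - z) for s >= 0;
    # for s < 0 the k^|s| factor grows polynomially, so require a few extra terms
    if (term < tol && k > 30) break
  }
  total
}

#' Degree-law probability mass function
#'
#' @param model A [degree_model()].
#' @param k Vector of non-negative integer degrees.
#' @return Numeric vector of probabilities `f(k)`.
#' @export
degree_pmf <- function(model, k) {
  stopifnot(inherits(model, "degree_model"))
  if (any(k < 0) || any(k != floor(k))) stop("k must be non-negative integers", call. = FALSE)
  p <- model$params
  switch(model$family,
    ztp = {
      out <- stats::dpois(k, p$lambda) / (1 - exp(-p$lambda))
      out[k == 0] <- 0
      out
    },
    polylog = {
      z <- exp(-1 / p$theta)
      li <- polylog_li(p$lambda, z)
      out <- ifelse(k == 0, 0, k^(-p$lambda) * z^k / li)
      as.numeric(out)
    },
    empirical = {
      out <- p$prob[match(k, p$k)]
      out[is.na(out)] <- 0
      out
    }
  )
}

#' Population mean degree of a degree law
#'
#' Closed forms: `lambda / (1 - exp(-lambda))` for the zero-truncated Poisson
#' and `Li_{lambda-1}(z) / Li_lambda(z)` for the polylogarithmic law.
#'
#' @inheritParams degree_pmf
#' @return The mean degree, a positive scalar.
#' @export
model_mean <- function(model) {
  stopifnot(inherits(model, "degree_model"))
  p <- model$params
  switch(model$family,
    ztp = p$lambda / (1 - exp(-p$lambda)),
    polylog = {
      z <- exp(-1 / p$theta)
      polylog_li(p$lambda - 1, z) / polylog_li(p$lambda, z)
    },
    empirical = sum(p$k * p$prob)
  )
}

# Finite pmf table truncated where the remaining tail mass drops below tail_tol.
pmf_table <- function(model, tail_tol = 1e-10) {
  if (model$family == "empirical") {
    return(list(k = model$params$k, prob = model$params$prob))
  }
  k_max <- 32L
  repeat {
    k <- 0:k_max
    prob <- degree_pmf(model, k)
    if (1 - sum(prob) < tail_tol) break
    k_max <- k_max * 2L
    if (k_max > 2^20) stop("degree law tail does not truncate", call. = FALSE)
  }
  keep <- prob > 0 | k == 0
  list(k = k[keep], prob = prob[keep])
}

#' Sample a degree sequence
#'
#' Draws `n` i.i.d. degrees by inverse-CDF lookup on a pmf table truncated
#' where the tail mass falls below `1e-10`. When `even_sum = TRUE` (the
#' default) an odd-total sequence is repaired by redrawing one uniformly
#' chosen entry until the total is even — the stub-pairing construction of a
#' configuration-model graph needs an even number of edge ends, and redrawing
#' (rather than adding 1 to some entry) leaves the degree law intact.
#'
#' @inheritParams degree_pmf
#' @param n Number of vertices.
#' @param even_sum Enforce an even total (configuration-model requirement).
#' @return Integer vector of length `n`.
#' @export
sample_degrees <- function(model, n, even_sum = TRUE) {
  stopifnot(inherits(model, "degree_model"), n >= 1)
  tab <- pmf_table(model)
  d <- tab$k[sample.int(length(tab$k), n, replace = TRUE, prob = tab$prob)]
  if (even_sum && sum(d) %% 2 == 1) {
    i <- sample.int(n, 1L)
    repeat {
      d[i] <- tab$k[sample.int(length(tab$k), 1L, prob = tab$prob)]
      if (sum(d) %% 2 == 0) break
    }
  }
  as.integer(d)
}
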