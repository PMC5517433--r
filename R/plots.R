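# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline facet_wrap
#'   geom_pointrange geom_hline labs geom_col geom_errorbar position_dodge
NULL

#' Plot a bootstrap sample
#'
#' Mean-degree samples draw a replicate histogram with the percentile
#' interval; `fk_vector` samples draw per-degree interval bars.
#'
#' @param object A `boot_sample`.
#' @param alpha Significance level for the drawn interval.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boot_sample <- function(object, alpha = 0.05, ...) {
  if (object$statistic == "mean_degree") {
    d <- tidy(object)
    b <- efron_bounds(d$mu, alpha)
    ggplot(d, aes(x = .data$mu)) +
      geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
      geom_vline(xintercept = b, linetype = "dashed") +
      labs(
        x = "bootstrap mean degree", y = "replicates",
        title = sprintf("m = %d seeds, w = %d waves", object$combo["m"], object$combo["w"])
      )
  } else {
    d <- tidy(object) |>
      dplyr::group_by(.data$k) |>
      dplyr::summarise(
        est = mean(.data$prob),
        lower = efron_bounds(.data$prob, alpha)[1],
        upper = efron_bounds(.data$prob, alpha)[2],
        .groups = "drop"
      )
    ggplot(d, aes(x = .data$k, y = .data$est)) +
      geom_col(fill = "grey80", colour = "grey30") +
      geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0.25) +
      labs(x = "degree k", y = "bootstrap f(k)")
  }
}

#' Plot a wave diagnostic
#'
#' One histogram of bootstrap mean degrees per wave depth, with the
#' percentile interval (dashed) and, if given, the reference mean (solid).
#'
#' @param object A [wave_diagnostic()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wave_diagnostic <- function(object, ...) {
  p <- ggplot(object$replicates, aes(x = .data$mu)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    facet_wrap(~w, labeller = ggplot2::label_both) +
    geom_vline(
      data = tidyr::pivot_longer(object$summary, c("lower", "upper")),
      aes(xintercept = .data$value), linetype = "dashed"
    ) +
    labs(x = "bootstrap mean degree", y = "replicates")
  if (!is.null(object$mu_ref)) {
    p <- p + geom_vline(xintercept = object$mu_ref)
  }
  p
}

#' Plot a coverage report
#'
#' Empirical coverage (with Monte Carlo error bars) per method and target,
#' against the nominal level.
#'
#' @param object A `coverage_report` from [run_experiment()].
#' @param nominal Nominal coverage in percent.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_report <- function(object, nominal = 95, ...) {
  ggplot(object, aes(x = .data$target, y = .data$coverage, colour = .data$method)) +
    geom_pointrange(
      aes(ymin = .data$coverage - .data$mc_se, ymax = .data$coverage + .data$mc_se),
      position = position_dodge(width = 0.4)
    ) +
    geom_hline(yintercept = nominal, linetype = "dashed") +
    labs(x = NULL, y = "empirical coverage (%)", colour = NULL)
}

#' Plot a cross-validation report
#'
#' Per-combination interval width against proxy coverage; the chosen
#' combination is highlighted.
#'
#' @param object A `cv_report` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_report <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$coverage, y = .data$width)) +
    ggplot2::geom_point(aes(shape = .data$chosen, size = .data$chosen)) +
    ggplot2::scale_size_manual(values = c(2, 4), guide = "none") +
    geom_vline(xintercept = 1 - object$alpha, linetype = "dashed") +
    labs(
      x = "proxy coverage", y = "interval width",
      title = sprintf("seed-wave cross-validation, target %s", object$target)
    )
}
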