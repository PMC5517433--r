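# Monte Carlo engine for the coverage / sharpness study: generate networks
# from a degree law, run the patchwork bootstrap (with cross-validated
# seed-wave selection) and the SRS competitors on each realization, and
# tabulate empirical coverage and mean interval width per method and target.

#' Experiment configuration
#'
#' @param model A [degree_model()] — the ground truth.
#' @param n Graph order per realization.
#' @param methods Subset of `"FPB"`, `"NCI"`, `"QCI"`.
#' @param targets List mixing `"mean"` and integer degrees `k` (for `f(k)`).
#'   The SRS competitors are defined for `f(k)` targets only.
#' @param grid [seed_wave_grid()] for FPB.
#' @param B Bootstrap replicates (FPB per combination; QCI resamples).
#' @param M SRS sample size for NCI/QCI.
#' @param mc_reps Monte Carlo repetitions.
#' @param alpha Significance level.
#' @param rng_seed Base seed; every repetition derives its own stream from it
#'   by a fixed offset, so any single repetition is replayable.
#' @param proxy_size,proxy_reps Cross-validation proxy design.
#' @param cv_target Statistic the seed-wave cross-validation scores combos
#'   on: `"mean"` (the default — one selection per realization, every
#'   target's interval read from the chosen combination) or an integer `k`.
#' @param truth `"model"` (population values of the degree law, the default)
#'   or `"realization"` (empirical values of each generated graph).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(model, n, methods = c("FPB", "NCI", "QCI"),
                              targets = list(2, 3, 4, 5),
                              grid = seed_wave_grid(), B = 500, M = 50,
                              mc_reps = 1000, alpha = 0.05, rng_seed = 1,
                              proxy_size = 100, proxy_reps = 13,
                              cv_target = "mean",
                              truth = c("model", "realization")) {
  stopifnot(inherits(model, "degree_model"), n >= 1, mc_reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  truth <- match.arg(truth)
  if (!length(targets)) stop("at least one target is required", call. = FALSE)
  tgts <- lapply(targets, normalize_target)
  if ("FPB" %in% methods && max(grid$m) > n) {
    stop("grid seed counts exceed graph order", call. = FALSE)
  }
  structure(
    list(
      model = model, n = as.integer(n), methods = methods, targets = tgts,
      grid = grid, B = as.integer(B), M = as.integer(M),
      mc_reps = as.integer(mc_reps), alpha = alpha,
      rng_seed = as.integer(rng_seed),
      proxy_size = as.integer(proxy_size), proxy_reps = as.integer(proxy_reps),
      cv_target = normalize_target(cv_target),
      truth = truth
    ),
    class = "experiment_config"
  )
}

model_label <- function(model) {
  p <- model$params
  switch(model$family,
    ztp = sprintf("ztp(%g)", p$lambda),
    polylog = sprintf("polylog(%g,%g)", p$lambda, p$theta),
    empirical = "empirical"
  )
}

# fixed-offset stream derivation; kept below 2^31 - 1
rep_seed <- function(base, rep) {
  s <- (as.double(base) + 104729 * as.double(rep)) %% 2147483646
  as.integer(s) + 1L
}

# population (or per-realization) value of each target
target_truths <- function(config, graph = NULL) {
  vapply(config$targets, function(tgt) {
    if (config$truth == "model") {
      if (tgt$type == "mean") model_mean(config$model) else degree_pmf(config$model, tgt$k)
    } else {
      if (tgt$type == "mean") mean(graph$deg) else mean(graph$deg == tgt$k)
    }
  }, numeric(1))
}

#' Aggregate per-repetition intervals into a coverage report
#'
#' @param rows Tibble with columns `rep`, `method`, `target`, `lower`,
#'   `upper` (one interval per repetition, method, target), and optionally a
#'   per-row `truth` column (per-realization scoring).
#' @param truths Named numeric vector, one truth per target label; ignored
#'   if `rows` carries its own `truth` column.
#' @param mc_reps Number of repetitions attempted.
#' @return A `coverage_report` tibble: `method`, `target`, `truth`,
#'   `coverage` (percent), `mean_width`, `mc_reps`, `mc_se` (percent).
#' @export
summarize_coverage <- function(rows, truths = NULL, mc_reps = max(rows$rep)) {
  if (!"truth" %in% names(rows)) {
    if (is.null(truths)) stop("either rows$truth or truths is required", call. = FALSE)
    rows <- dplyr::mutate(rows, truth = unname(truths[.data$target]))
  }
  out <- rows |>
    dplyr::group_by(.data$method, .data$target) |>
    dplyr::summarise(
      truth = .data$truth[1],
      coverage = 100 * mean(.data$lower <= .data$truth & .data$truth <= .data$upper),
      mean_width = mean(.data$upper - .data$lower),
      mc_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mc_se = 100 * sqrt((.data$coverage / 100) * (1 - .data$coverage / 100) / .data$mc_reps)
    )
  class(out) <- c("coverage_report", class(out))
  attr(out, "mc_reps_attempted") <- mc_reps
  out
}

#' Run a coverage / sharpness experiment
#'
#' Per repetition: draw a fresh degree sequence from the model, build a
#' simple graph (configuration model + rewiring), and form one confidence
#' interval per selected method and target — FPB with cross-validated
#' seed-wave selection, and/or the SRS-based NCI and QCI (which share one
#' SRS draw per repetition). Coverage is scored against the population
#' values of the degree law (default) so the report reads as calibration of
#' the interval for the hypothetical generating network.
#'
#' Repetitions whose generation or analysis fails are counted and skipped;
#' more than 5 percent failures aborts the run.
#'
#' @param config An [experiment_config()].
#' @param keep_rows Also attach the per-repetition interval rows (attribute
#'   `"rows"`).
#' @return A `coverage_report` tibble (see [summarize_coverage()]) with
#'   columns `model` and `n` prepended.
#' @export
run_experiment <- function(config, keep_rows = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  labels <- vapply(config$targets, function(t) t$label, character(1))
  fk_targets <- Filter(function(t) t$type == "fk", config$targets)
  all_rows <- vector("list", config$mc_reps)
  failures <- 0L
  for (r in seq_len(config$mc_reps)) {
    set.seed(rep_seed(config$rng_seed, r))
    res <- tryCatch({
      graph <- sample_network(config$model, config$n)
      g_truths <- if (config$truth == "realization") {
        stats::setNames(target_truths(config, graph), labels)
      }
      rows <- list()
      if ("FPB" %in% config$methods) {
        eng <- fpb_engine(
          graph, config$grid, config$B, config$alpha, config$targets,
          cv_target = config$cv_target,
          proxy_size = config$proxy_size, proxy_reps = config$proxy_reps
        )
        rows$fpb <- dplyr::mutate(
          eng$target_cis[, c("target", "lower", "upper")],
          rep = r, method = "FPB", .before = 1
        )
      }
      if (any(c("NCI", "QCI") %in% config$methods) && length(fk_targets)) {
        deg <- srs_degrees(graph, config$M)
        if ("NCI" %in% config$methods) {
          rows$nci <- purrr::map_dfr(fk_targets, function(t) {
            ci <- nci(deg, config$n, t$k, config$alpha)
            tibble::tibble(
              rep = r, method = "NCI", target = t$label,
              lower = ci$lower, upper = ci$upper
            )
          })
        }
        if ("QCI" %in% config$methods) {
          rows$qci <- purrr::map_dfr(fk_targets, function(t) {
            ci <- qci(deg, t$k, config$B, config$alpha)
            tibble::tibble(
              rep = r, method = "QCI", target = t$label,
              lower = ci$lower, upper = ci$upper
            )
          })
        }
      }
      out_rows <- dplyr::bind_rows(rows)
      if (config$truth == "realization") {
        out_rows$truth <- unname(g_truths[out_rows$target])
      }
      out_rows
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > 0.05 * config$mc_reps) {
        stop(sprintf(
          "more than 5%% of repetitions failed (last error: %s)", conditionMessage(res)
        ), call. = FALSE)
      }
    } else {
      all_rows[[r]] <- res
    }
  }
  rows <- dplyr::bind_rows(all_rows)
  truths <- if (config$truth == "model") {
    stats::setNames(target_truths(config), labels)
  }
  out <- summarize_coverage(rows, truths, config$mc_reps) |>
    dplyr::mutate(
      model = model_label(config$model), n = config$n,
      .before = 1
    )
  class(out) <- c("coverage_report", class(out))
  attr(out, "failures") <- failures
  if (keep_rows) attr(out, "rows") <- rows
  out
}

#' Bootstrap mean-degree distributions across wave depths
#'
#' Diagnostic for the bias--variance trade-off of patch depth: for one graph
#' and one ordered seed draw, bootstrap the mean degree at several wave
#' depths (0 = seeds only) from views of a single maximal snowball sample,
#' and summarise spread and percentile intervals per depth. The bootstrap
#' spread typically shrinks as waves are added while the centre can drift —
#' the trade-off the cross-validation arbitrates.
#'
#' @param graph A [simple_net()].
#' @param m Seed count.
#' @param wave_list Wave depths to compare.
#' @param B Bootstrap replicates per depth.
#' @param alpha Significance level.
#' @param mu_ref Optional reference mean degree drawn on plots (e.g. the
#'   population mean of the generating law).
#' @return A `wave_diagnostic`: list with `replicates` (tibble `w`,
#'   `replicate`, `mu`), `summary` (tibble `w`, `sd`, `lower`, `upper`), and
#'   `mu_ref`.
#' @export
wave_diagnostic <- function(graph, m = 30, wave_list = 0:3, B = 500,
                            alpha = 0.05, mu_ref = NULL) {
  stopifnot(inherits(graph, "simple_net"))
  seeds <- sample_seeds(graph, m)
  ps <- lsmi(graph, seeds, max(wave_list))
  reps <- purrr::map_dfr(wave_list, function(w) {
    bs <- resample_patches(subpatch(ps, m, w), B, statistic = "mean_degree")
    tibble::tibble(w = w, replicate = seq_len(B), mu = as.numeric(bs$values))
  })
  summ <- reps |>
    dplyr::group_by(.data$w) |>
    dplyr::summarise(
      sd = stats::sd(.data$mu),
      lower = efron_bounds(.data$mu, alpha)[1],
      upper = efron_bounds(.data$mu, alpha)[2],
      .groups = "drop"
    )
  structure(
    list(replicates = reps, summary = summ, mu_ref = mu_ref, alpha = alpha),
    class = "wave_diagnostic"
  )
}

#' @export
print.wave_diagnostic <- function(x, ...) {
  cat("<wave_diagnostic> bootstrap mean degree by wave depth\n")
  print(x$summary)
  invisible(x)
}
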