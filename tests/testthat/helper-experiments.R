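# Heavy Monte Carlo runs shared by several test files, computed once per
# test session and cached. Profile: grid {20,30,40,50} x waves 1..3 with
# B = 500 bootstrap resamples (the study's case-study configuration);
# repetition counts are scaled to keep the suite fast while holding the
# binomial Monte Carlo error of a coverage estimate below ~2 points.

.exp_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .exp_cache)) {
    assign(name, force(expr), envir = .exp_cache)
  }
  get(name, envir = .exp_cache)
}

ztp2 <- function() degree_model("ztp", lambda = 2)
plog23 <- function() degree_model("polylog", lambda = 2, theta = 3)
plog012 <- function() degree_model("polylog", lambda = 0.1, theta = 2)

# FPB + NCI on zero-truncated Poisson(2), n = 2000, targets f(2)..f(5)
ztp_fpb_report <- function() cached("ztp_fpb", {
  cfg <- experiment_config(
    ztp2(), 2000, methods = c("FPB", "NCI"), targets = list(2, 3, 4, 5),
    grid = seed_wave_grid(c(20, 30, 40, 50), 1:3),
    B = 500, M = 50, mc_reps = 400, rng_seed = 42
  )
  run_experiment(cfg)
})

# NCI + QCI on polylog(2, 3), n = 2000, targets f(4), f(5)
p23_srs_report <- function() cached("p23_srs", {
  cfg <- experiment_config(
    plog23(), 2000, methods = c("NCI", "QCI"), targets = list(4, 5),
    B = 500, M = 50, mc_reps = 600, rng_seed = 42
  )
  run_experiment(cfg)
})

# FPB on polylog(2, 3), n = 2000, target f(5)
p23_fpb_report <- function() cached("p23_fpb", {
  cfg <- experiment_config(
    plog23(), 2000, methods = "FPB", targets = list(5),
    grid = seed_wave_grid(c(20, 30, 40, 50), 1:3),
    B = 500, mc_reps = 1000, rng_seed = 42
  )
  run_experiment(cfg)
})

# one fixed ztp(2) realization of order 2000 for sampling-level tests
fixed_ztp_graph <- function() cached("ztp_graph", {
  set.seed(2024)
  sample_network(ztp2(), 2000)
})

report_cell <- function(report, method, target, col) {
  row <- report[report$method == method & report$target == target, ]
  row[[col]]
}
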