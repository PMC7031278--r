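# End-to-end experiment orchestration: simulate (or load) a cohort,
# bootstrap it at the participant level, run each algorithm under the
# configured background knowledge, and aggregate evaluation reports.

#' Experiment configuration
#'
#' @param design `"cross_sectional"` or `"longitudinal"`.
#' @param algorithms subset of `c("fges", "fci", "sem")`.
#' @param knowledge_level 1, 2 or 3.
#' @param n cohort size (defaults to 1008 / 266 by design).
#' @param n_bootstraps number of bootstrap replicates (default 100).
#' @param seed master seed; all replicate seeds derive from it.
#' @param alpha Fisher-z level for FCI.
#' @param penalty_discount BIC penalty multiplier.
#' @param subsample fraction of participants drawn before bootstrapping
#'   (1.0, 0.5 or 0.25 for the sample-size sensitivity runs).
#' @param threshold_pct consensus-graph inclusion threshold.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(design = "cross_sectional",
                              algorithms = c("fges", "fci", "sem"),
                              knowledge_level = 1, n = NULL,
                              n_bootstraps = 100, seed = 1,
                              alpha = 0.05, penalty_discount = 1,
                              subsample = 1.0, threshold_pct = 80) {
  design <- match.arg(design, c("cross_sectional", "longitudinal"))
  algorithms <- match.arg(algorithms, c("fges", "fci", "sem"),
                          several.ok = TRUE)
  stopifnot(knowledge_level %in% 1:3, n_bootstraps >= 1,
            subsample > 0, subsample <= 1)
  if (is.null(n)) n <- if (design == "cross_sectional") 1008 else 266
  structure(list(design = design, algorithms = algorithms,
                 knowledge_level = knowledge_level, n = n,
                 n_bootstraps = n_bootstraps, seed = seed, alpha = alpha,
                 penalty_discount = penalty_discount, subsample = subsample,
                 threshold_pct = threshold_pct),
            class = "experiment_config")
}

#' Deterministic replicate seed derived from a master seed
#'
#' `seed_k = (master * 10007 + 31 * k) mod (2^31 - 1)`, so replicate `k` is
#' reproducible in isolation.
#' @param master master seed (integer).
#' @param k replicate index (0 reserved for the base cohort draw).
#' @return an integer seed.
#' @export
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 10007 + 31 * as.numeric(k)) %% 2147483647)
}

run_algorithm <- function(alg, cov, knowledge, config) {
  sc <- score_config(config$penalty_discount)
  switch(alg,
    fges = fges_search(cov, knowledge, sc),
    fci = fci_search(cov, config$alpha, knowledge),
    sem = {
      empty <- mixed_graph(cov$vars, kind_hint = "DAG")
      stepwise_search(empty, cov, cov$n, knowledge, max_iter = Inf, sc)
    },
    stop("unknown algorithm: ", alg))
}

#' Run the bootstrap causal-discovery experiment
#'
#' Simulates (or accepts) a cohort, draws `n_bootstraps` participant-level
#' resamples, runs each configured algorithm under the configured background
#' knowledge on every resample, and aggregates per-algorithm evaluation
#' reports with consensus graphs. Replicates on which an algorithm fails
#' (e.g. a singular bootstrap covariance) are logged and excluded from the
#' averages, not fatal.
#'
#' @param config an `experiment_config`.
#' @param cohort optional pre-built cohort data frame (otherwise simulated
#'   from [default_parameters()] with the config's design, n and seed).
#' @param params simulator parameters used when `cohort` is NULL.
#' @return a list of class `experiment_result`: `config`, `gold`, `reports`
#'   (one `evaluation_report` per algorithm), `failures` (named counts).
#' @export
run_discovery_experiment <- function(config, cohort = NULL,
                                     params = default_parameters()) {
  stopifnot(inherits(config, "experiment_config"))
  gold <- build_gold_standard(config$design)
  if (is.null(cohort)) {
    cohort <- if (config$design == "cross_sectional") {
      simulate_cross_sectional(params, config$n, derive_seed(config$seed, 0))
    } else {
      simulate_longitudinal(params, config$n, derive_seed(config$seed, 0))
    }
  }
  if (config$subsample < 1) {
    set.seed(derive_seed(config$seed, 999999))
    keep <- sample.int(nrow(cohort), max(2, round(nrow(cohort) * config$subsample)))
    cohort <- cohort[keep, , drop = FALSE]
  }
  knowledge <- build_background_knowledge(config$knowledge_level, gold$nodes)
  graphs <- stats::setNames(vector("list", length(config$algorithms)),
                            config$algorithms)
  failures <- stats::setNames(integer(length(config$algorithms)),
                              config$algorithms)
  for (alg in config$algorithms) graphs[[alg]] <- list()
  for (b in seq_len(config$n_bootstraps)) {
    boot <- bootstrap_resample(cohort, derive_seed(config$seed, b))
    cov <- tryCatch(cohort_cov(boot), error = function(e) NULL)
    for (alg in config$algorithms) {
      g <- if (is.null(cov)) NULL else tryCatch(
        run_algorithm(alg, cov, knowledge, config),
        error = function(e) {
          message("replicate ", b, " (", alg, ") failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(g)) failures[alg] <- failures[alg] + 1L
      else graphs[[alg]][[length(graphs[[alg]]) + 1L]] <- g
    }
  }
  reports <- lapply(config$algorithms, function(alg) {
    evaluation_report(graphs[[alg]], gold, alg, config$knowledge_level,
                      config$threshold_pct)
  })
  names(reports) <- config$algorithms
  structure(list(config = config, gold = gold, reports = reports,
                 failures = failures),
            class = "experiment_result")
}

#' Run the SEM edge-deletion recovery study
#'
#' Wraps [recovery_experiment()] for k = 1 (8 single-deletion runs) and
#' k = 2 (28 pair-deletion runs on the 8-edge gold graph) and emits the
#' two-row summary: k, full-recovery rate, mean precision, mean recall.
#'
#' @param config an `experiment_config` (its design, n, seed and penalty
#'   discount are used).
#' @param cov_or_cohort optional covariance model or cohort; by default a
#'   cohort is simulated from the config.
#' @param max_add cap on edge additions per run (default 5).
#' @param knowledge optional `background_knowledge` applied to the search.
#' @return a list with `summary` (two-row data frame) and `detail`
#'   (per-k `recovery_experiment` outputs).
#' @export
run_recovery_study <- function(config, cov_or_cohort = NULL, max_add = 5,
                               knowledge = NULL) {
  gold <- build_gold_standard(config$design)
  if (is.null(cov_or_cohort)) {
    cov_or_cohort <- if (config$design == "cross_sectional") {
      simulate_cross_sectional(default_parameters(), config$n,
                               derive_seed(config$seed, 0))
    } else {
      simulate_longitudinal(default_parameters(), config$n,
                            derive_seed(config$seed, 0))
    }
  }
  sc <- score_config(config$penalty_discount)
  detail <- lapply(1:2, function(k) {
    recovery_experiment(gold, cov_or_cohort, k, max_add, knowledge, sc)
  })
  summary <- do.call(rbind, lapply(detail, `[[`, "summary"))
  list(summary = summary, detail = detail)
}
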