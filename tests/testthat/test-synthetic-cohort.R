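# Calibrated cohort generator: marginals, structure, bootstrap.

test_that("default parameters reproduce the published marginals exactly", {
  p <- default_parameters()
  expect_equal(unname(p$exogenous$AGE), c(74.09, 7.46))
  expect_equal(unname(p$exogenous$APOE4), c(0.54, 0.36, 0.10))
  # closed-form propagation: implied FDG marginal hits its target
  pc <- population_cov_model(p, "cross_sectional")
  cal <- adcausal:::calibrate_parameters(p, "cross_sectional")
  expect_equal(unname(cal$mean["FDG"]), 1.22, tolerance = 1e-10)
  expect_equal(unname(sqrt(pc$sigma["FDG", "FDG"])), 0.17, tolerance = 1e-10)
  expect_equal(unname(cal$mean["ABETA"]), 986.29, tolerance = 1e-10)
  expect_equal(unname(sqrt(pc$sigma["PTAU", "PTAU"])), 14.76, tolerance = 1e-10)
  # thresholds strictly increasing
  expect_lt(p$dx_thresholds[1], p$dx_thresholds[2])
  # infeasible calibration rejected
  expect_error(
    sem_parameters(std_coefficients = list(
      ABETA = c(AGE = 0.9, APOE4 = 0.9), PTAU = c(ABETA = -0.55),
      FDG = c(ABETA = 0.3, PTAU = -0.45),
      DX = c(PTAU = 0.35, FDG = -0.4, EDU = -0.2))),
    "infeasible")
})

test_that("cross-sectional simulation has the right shape and determinism", {
  p <- default_parameters()
  co <- simulate_cross_sectional(p, 1008, seed = 3)
  expect_equal(nrow(co), 1008)
  expect_equal(ncol(co), 9)  # 8 variables + coded DX
  expect_setequal(colnames(co), c("AGE", "SEX", "EDU", "APOE4", "ABETA",
                                  "PTAU", "FDG", "DX", "DX_star"))
  expect_false(anyNA(co))
  expect_setequal(unique(co$DX), 0:2)
  expect_identical(co, simulate_cross_sectional(p, 1008, seed = 3))
  expect_error(simulate_cross_sectional(p, 0, seed = 1), "at least 1")
  expect_error(simulate_cross_sectional(p, 10), "seed")
})

test_that("regression on a large sample recovers the set coefficients", {
  p <- default_parameters()
  cal <- adcausal:::calibrate_parameters(p, "cross_sectional")
  co <- simulate_cross_sectional(p, 50000, seed = 11)
  fit <- stats::lm(ABETA ~ AGE + APOE4, data = co)
  for (v in c("AGE", "APOE4")) {
    est <- stats::coef(fit)[[v]]
    se <- sqrt(diag(stats::vcov(fit)))[[v]]
    expect_lt(abs(est - cal$beta$ABETA[[v]]), 4 * se)
  }
})

test_that("longitudinal simulation respects the two-visit structure", {
  p <- default_parameters()
  co <- simulate_longitudinal(p, 266, seed = 5)
  expect_equal(nrow(co), 266)
  expect_setequal(colnames(co), c(
    "AGE", "SEX", "EDU", "APOE4",
    paste0(rep(c("ABETA", "PTAU", "FDG", "DX", "DX_star"), 2),
           rep(c(".0", ".24"), each = 5))))
  # within-time paths carry the cross-time dependence given baseline:
  # exact population partial correlations from the analytic covariance
  pcor <- function(sig, x, y, S) {
    prec <- solve(sig[c(x, y, S), c(x, y, S)])
    -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  }
  sig <- population_cov_model(p, "longitudinal")$sigma
  expect_gt(abs(pcor(sig, "ABETA.24", "PTAU.24", c("ABETA.0", "PTAU.0"))), 0.01)
  # removing the within-time paths at month 24 kills that dependence
  p0 <- sem_parameters(t24_scale = 0)
  sig0 <- population_cov_model(p0, "longitudinal")$sigma
  expect_lt(abs(pcor(sig0, "ABETA.24", "PTAU.24", c("ABETA.0", "PTAU.0"))), 1e-10)
  # zero AR coefficients: month-24 block independent of baseline block
  par0 <- sem_parameters(ar_std = c(ABETA = 0, PTAU = 0, FDG = 0, DX = 0))
  sigz <- population_cov_model(par0, "longitudinal")$sigma
  expect_lt(max(abs(sigz[paste0(c("ABETA", "PTAU", "FDG", "DX"), ".24"),
                         paste0(c("ABETA", "PTAU", "FDG", "DX"), ".0")])), 1e-10)
})

test_that("d-separation statements of the generator hold in population", {
  # every d-separation of the cross-sectional gold DAG shows |pcor| ~ 0
  p <- default_parameters()
  gold <- build_gold_standard()
  sig <- population_cov_model(p, "cross_sectional")$sigma
  # latent DX under its graph name; treat coded-DX distortion separately
  nodes <- gold$nodes
  pcor <- function(x, y, S) {
    prec <- solve(sig[c(x, y, S), c(x, y, S)])
    -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  }
  set.seed(42)
  for (rep in 1:40) {
    xy <- sample(nodes, 2)
    others <- setdiff(nodes, xy)
    S <- sample(others, sample(0:3, 1))
    r <- pcor(xy[1], xy[2], S)
    if (d_separated(gold, xy[1], xy[2], S)) {
      expect_lt(abs(r), 1e-10)
    }
  }
  # and at least one dependence is present
  expect_gt(abs(pcor("ABETA", "PTAU", character())), 0.3)
})

test_that("bootstrap resampling is deterministic with binomial inclusion", {
  co <- simulate_cross_sectional(n = 200, seed = 9)
  one <- co[1, , drop = FALSE]
  expect_identical(bootstrap_resample(one, seed = 1), {
    x <- one; rownames(x) <- NULL; x
  })
  expect_identical(bootstrap_resample(co, seed = 4),
                   bootstrap_resample(co, seed = 4))
  expect_error(bootstrap_resample(co[0, ], seed = 1), "empty")
  # inclusion frequency of a given row ~ 1 - (1 - 1/n)^n
  n <- nrow(co)
  co$row_id <- seq_len(n)
  included <- vapply(1:300, function(s) {
    1 %in% bootstrap_resample(co, seed = 1000 + s)$row_id
  }, logical(1))
  p_inc <- 1 - (1 - 1 / n)^n
  ci <- stats::qbinom(c(0.0005, 0.9995), 300, p_inc) / 300
  expect_gte(mean(included), ci[1])
  expect_lte(mean(included), ci[2])
})

test_that("structure recovery is invariant to flipping effect signs", {
  # negate the ABETA variable: every coefficient adjacent to ABETA flips,
  # giving an isomorphic distribution (arbitrary per-edge sign patterns can
  # instead create path cancellations, i.e. a different distribution)
  flipped <- sem_parameters(std_coefficients = list(
    ABETA = c(AGE = 0.35, APOE4 = 0.45), PTAU = c(ABETA = 0.55),
    FDG = c(ABETA = -0.30, PTAU = -0.45),
    DX = c(PTAU = 0.35, FDG = -0.40, EDU = -0.20)))
  # invariance is distributional: compare searches on the exact population
  # covariances (finite samples under one seed are different datasets)
  k2 <- build_background_knowledge(2, build_gold_standard()$nodes)
  g1 <- fges_search(population_cov_model(default_parameters()), k2)
  g2 <- fges_search(population_cov_model(flipped), k2)
  expect_true(graphs_equal(g1, g2))
})
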