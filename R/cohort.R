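# Synthetic ADNI-like cohorts: a linear-Gaussian structural model on the
# gold-standard DAG, calibrated in closed form so every variable reproduces
# the published marginal summary statistics. Diagnosis is generated as a
# latent Gaussian DX* and coded CN/MCI/AD (0/1/2) by thresholding.

#' Structural parameters of the cohort simulator
#'
#' Effect sizes are specified on the standardized scale: each entry of
#' `std_coefficients[[child]]` is the expected change in the child, in child
#' SDs, per one-SD change of the parent. Raw path weights, intercepts and
#' noise scales are then solved in closed form (means and variances propagate
#' linearly through the DAG) so each variable's marginal matches the target
#' mean/SD exactly; DX thresholds are solved against the exact mixture
#' distribution of the latent DX* over APOE4 classes.
#'
#' @param std_coefficients named list: per endogenous node, a named vector of
#'   standardized path weights for its gold-standard parents. Signs default
#'   to the biology (lower ABETA pushes PTAU up, FDG metabolism down, and
#'   worse diagnosis); flipping signs must not change recovered structure.
#' @param exogenous list of exogenous marginals: `AGE` and `EDU` as
#'   `c(mean=, sd=)`, `SEX` as `c(p=)` (Bernoulli), `APOE4` as probabilities
#'   of 0/1/2 alleles.
#' @param endogenous_moments named list of `c(mean=, sd=)` targets for ABETA,
#'   PTAU, FDG and the latent DX (standardized to mean 0, SD 1).
#' @param dx_probs target class mix for coded DX (CN/MCI/AD).
#' @param ar_std standardized autoregressive weights X.0 -> X.24 for the
#'   longitudinal design.
#' @param t24_scale multiplier on within-visit standardized weights at the
#'   24-month visit (keeps the total explained variance feasible once the
#'   autoregressive parent is added).
#' @param gold_edges edge table defining the structural DAG (see
#'   [build_gold_standard()]).
#' @return an object of class `sem_parameters`, with calibrated
#'   cross-sectional `coefficients`, `intercepts`, `noise_scale` and
#'   `dx_thresholds` materialized.
#' @export
sem_parameters <- function(
    std_coefficients = list(
      ABETA = c(AGE = -0.35, APOE4 = -0.45),
      PTAU = c(ABETA = -0.55),
      FDG = c(ABETA = 0.30, PTAU = -0.45),
      DX = c(PTAU = 0.35, FDG = -0.40, EDU = -0.20)),
    exogenous = list(
      AGE = c(mean = 74.09, sd = 7.46),
      SEX = c(p = 0.55),
      EDU = c(mean = 16.15, sd = 2.71),
      APOE4 = c(p0 = 0.54, p1 = 0.36, p2 = 0.10)),
    endogenous_moments = list(
      ABETA = c(mean = 986.29, sd = 459.94),
      PTAU = c(mean = 27.67, sd = 14.76),
      FDG = c(mean = 1.22, sd = 0.17),
      DX = c(mean = 0, sd = 1)),
    dx_probs = c(CN = 0.31, MCI = 0.46, AD = 0.23),
    ar_std = c(ABETA = 0.7, PTAU = 0.7, FDG = 0.7, DX = 0.7),
    t24_scale = 0.5,
    gold_edges = gold_edge_table()) {
  ap <- exogenous$APOE4
  if (abs(sum(ap) - 1) > 1e-8) stop("APOE4 probabilities must sum to 1")
  if (abs(sum(dx_probs) - 1) > 1e-8) stop("DX probabilities must sum to 1")
  params <- structure(list(
    std_coefficients = std_coefficients, exogenous = exogenous,
    endogenous_moments = endogenous_moments, dx_probs = dx_probs,
    ar_std = ar_std, t24_scale = t24_scale, gold_edges = gold_edges),
    class = "sem_parameters")
  cal <- calibrate_parameters(params, "cross_sectional")
  params$coefficients <- cal$beta
  params$intercepts <- cal$intercept
  params$noise_scale <- cal$noise_sd
  params$dx_thresholds <- cal$dx_thresholds$DX
  params$ar_coefficients <- ar_std
  params
}

#' Default calibrated simulator parameters
#'
#' The stated world of the benchmark: exogenous marginals, endogenous
#' mean/SD targets and class mixes follow the published cohort summary
#' (AGE 74.09 (7.46), SEX 0.55, EDU 16.15 (2.71), FDG 1.22 (0.17),
#' ABETA 986.29 (459.94), PTAU 27.67 (14.76), APOE4 54/36/10%,
#' DX 31/46/23%); path coefficients default to moderate standardized
#' effects giving each endogenous node an R-squared between 0.2 and 0.6.
#'
#' @return a calibrated `sem_parameters` object.
#' @examples
#' p <- default_parameters()
#' p$exogenous$AGE
#' @export
default_parameters <- function() sem_parameters()

# marginal mean/var of exogenous variables treated as numeric columns
exogenous_moments <- function(params) {
  ex <- params$exogenous
  ap <- ex$APOE4
  amean <- ap[["p1"]] + 2 * ap[["p2"]]
  avar <- (ap[["p1"]] + 4 * ap[["p2"]]) - amean^2
  list(AGE = c(mean = ex$AGE[["mean"]], var = ex$AGE[["sd"]]^2),
       SEX = c(mean = ex$SEX[["p"]], var = ex$SEX[["p"]] * (1 - ex$SEX[["p"]])),
       EDU = c(mean = ex$EDU[["mean"]], var = ex$EDU[["sd"]]^2),
       APOE4 = c(mean = amean, var = avar))
}

# Structural layout for a design: node list (graph names; DX* is implicit),
# parent sets, and the standardized weight attached to each parent edge.
structural_layout <- function(params, design) {
  base <- names(params$std_coefficients)  # endogenous, in dependency order
  if (design == "cross_sectional") {
    parents <- params$std_coefficients
    targets <- params$endogenous_moments
    return(list(order = c(names(exogenous_moments(params)), base),
                parents = parents, targets = targets))
  }
  dup <- c("ABETA", "PTAU", "FDG", "DX")
  sfx <- function(v, s) if (v %in% dup) paste0(v, s) else v
  parents <- list(); targets <- list()
  for (v in base) {
    w0 <- params$std_coefficients[[v]]
    names(w0) <- vapply(names(w0), sfx, "", s = ".0")
    parents[[paste0(v, ".0")]] <- w0
    targets[[paste0(v, ".0")]] <- params$endogenous_moments[[v]]
    # 24 months: within-visit parents (scaled) plus the autoregressive parent
    w24 <- params$std_coefficients[[v]] * params$t24_scale
    keep <- names(w24) %in% dup  # demographics feed baseline only
    w24 <- w24[keep]
    names(w24) <- vapply(names(w24), sfx, "", s = ".24")
    w24 <- c(w24, stats::setNames(params$ar_std[[v]], paste0(v, ".0")))
    parents[[paste0(v, ".24")]] <- w24
    targets[[paste0(v, ".24")]] <- params$endogenous_moments[[v]]
  }
  ord <- c(names(exogenous_moments(params)),
           paste0(base, ".0"), paste0(base, ".24"))
  list(order = ord, parents = parents, targets = targets)
}

# Closed-form calibration: walk the DAG in topological order keeping the
# exact joint mean/covariance of all processed nodes; convert standardized
# weights to raw ones using the target SD and the parents' current
# covariance; solve the noise variance by subtraction.
calibrate_parameters <- function(params, design) {
  lay <- structural_layout(params, design)
  exo <- exogenous_moments(params)
  ord <- lay$order
  p <- length(ord)
  mu <- stats::setNames(numeric(p), ord)
  sig <- matrix(0, p, p, dimnames = list(ord, ord))
  beta <- list(); intercept <- numeric(); noise_sd <- numeric()
  for (v in ord) {
    if (v %in% names(exo)) {
      mu[v] <- exo[[v]][["mean"]]; sig[v, v] <- exo[[v]][["var"]]
      next
    }
    w <- lay$parents[[v]]
    pa <- names(w)
    tgt <- lay$targets[[v]]
    sdv <- tgt[["sd"]]
    spp <- sig[pa, pa, drop = FALSE]
    dinv <- 1 / sqrt(diag(spp))
    corr_pp <- spp * (dinv %o% dinv)
    expl <- drop(t(w) %*% corr_pp %*% w)  # fraction of child variance explained
    if (expl >= 1) {
      stop("infeasible calibration for ", v, ": standardized parents explain ",
           round(expl, 3), " of the target variance")
    }
    b <- w * sdv / sqrt(diag(spp))  # raw coefficients
    beta[[v]] <- b
    intercept[v] <- tgt[["mean"]] - sum(b * mu[pa])
    noise_sd[v] <- sdv * sqrt(1 - expl)
    mu[v] <- tgt[["mean"]]
    cross <- drop(sig[, pa, drop = FALSE] %*% b)
    sig[, v] <- cross; sig[v, ] <- cross
    sig[v, v] <- drop(t(b) %*% spp %*% b) + noise_sd[v]^2
  }
  dx_nodes <- grep("^DX", ord, value = TRUE)
  thresholds <- lapply(stats::setNames(dx_nodes, dx_nodes), function(dv) {
    solve_dx_thresholds(params, mu, sig, dv)
  })
  list(layout = lay, mean = mu, cov = sig, beta = beta,
       intercept = intercept, noise_sd = noise_sd, dx_thresholds = thresholds)
}

# Conditional on APOE4 every other variable is exactly Gaussian, so the
# latent DX* distribution is a 3-component Gaussian mixture; thresholds are
# solved on its exact CDF so the coded class mix hits the target.
solve_dx_thresholds <- function(params, mu, sig, dx_node) {
  ap <- params$exogenous$APOE4
  wts <- c(ap[["p0"]], ap[["p1"]], ap[["p2"]])
  exo <- exogenous_moments(params)
  amean <- exo$APOE4[["mean"]]; avar <- exo$APOE4[["var"]]
  tot <- sig[dx_node, "APOE4"] / avar  # total raw effect of APOE4 on DX*
  cmeans <- mu[dx_node] + tot * ((0:2) - amean)
  cvar <- sig[dx_node, dx_node] - tot^2 * avar
  csd <- sqrt(max(cvar, 1e-12))
  mix_cdf <- function(t) sum(wts * stats::pnorm((t - cmeans) / csd))
  probs <- params$dx_probs
  lo <- mu[dx_node] - 10 * sqrt(sig[dx_node, dx_node])
  hi <- mu[dx_node] + 10 * sqrt(sig[dx_node, dx_node])
  t1 <- stats::uniroot(function(t) mix_cdf(t) - probs[[1]], c(lo, hi))$root
  t2 <- stats::uniroot(function(t) mix_cdf(t) - (probs[[1]] + probs[[2]]),
                       c(lo, hi))$root
  c(t1, t2)
}

sample_exogenous <- function(params, n) {
  ex <- params$exogenous
  ap <- ex$APOE4
  data.frame(
    AGE = stats::rnorm(n, ex$AGE[["mean"]], ex$AGE[["sd"]]),
    SEX = stats::rbinom(n, 1, ex$SEX[["p"]]),
    EDU = stats::rnorm(n, ex$EDU[["mean"]], ex$EDU[["sd"]]),
    APOE4 = sample(0:2, n, replace = TRUE,
                   prob = c(ap[["p0"]], ap[["p1"]], ap[["p2"]])))
}

simulate_design <- function(params, n, seed, design) {
  if (n < 1) stop("n must be at least 1")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  cal <- calibrate_parameters(params, design)
  lay <- cal$layout
  df <- sample_exogenous(params, n)
  for (v in setdiff(lay$order, colnames(df))) {
    pa <- names(lay$parents[[v]])
    x <- as.matrix(df[, pa, drop = FALSE]) %*% cal$beta[[v]] +
      cal$intercept[[v]] + stats::rnorm(n, 0, cal$noise_sd[[v]])
    df[[v]] <- drop(x)
  }
  # threshold every latent DX* into coded 0/1/2, keep both columns
  for (dv in names(cal$dx_thresholds)) {
    th <- cal$dx_thresholds[[dv]]
    coded <- findInterval(df[[dv]], th)
    latent_name <- sub("^DX", "DX_star", dv)
    df[[latent_name]] <- df[[dv]]
    df[[dv]] <- coded
  }
  df
}

#' Simulate a cross-sectional cohort
#'
#' Samples the structural model in topological order of the gold-standard
#' DAG. The returned table carries the coded diagnosis in `DX` (0 = CN,
#' 1 = MCI, 2 = AD) and the latent Gaussian in `DX_star`.
#'
#' @param params a `sem_parameters` object.
#' @param n number of participants (default 1008, the benchmark cohort size).
#' @param seed RNG seed (required; the draw is deterministic given it).
#' @return a data frame with columns AGE, SEX, EDU, APOE4, ABETA, PTAU, FDG,
#'   DX, DX_star.
#' @export
simulate_cross_sectional <- function(params = default_parameters(), n = 1008,
                                     seed) {
  simulate_design(params, n, seed, "cross_sectional")
}

#' Simulate a two-visit longitudinal cohort
#'
#' Demographics are sampled once; ABETA, PTAU, FDG and the latent diagnosis
#' are duplicated into baseline (".0") and 24-month (".24") copies. Each
#' 24-month variable depends on its own baseline value (autoregressive path)
#' and its within-visit gold-standard parents; demographics feed the
#' baseline only.
#'
#' @param params a `sem_parameters` object.
#' @param n number of participants (default 266, the two-visit cohort size).
#' @param seed RNG seed (required).
#' @return a data frame with demographics plus `ABETA.0`, ..., `DX.24`,
#'   `DX_star.0`, `DX_star.24`.
#' @export
simulate_longitudinal <- function(params = default_parameters(), n = 266,
                                  seed) {
  simulate_design(params, n, seed, "longitudinal")
}

#' Bootstrap resample of a cohort at the participant level
#'
#' @param cohort a nonempty data frame.
#' @param seed RNG seed (required; same seed, same resample).
#' @return a data frame with `nrow(cohort)` rows drawn with replacement.
#' @export
bootstrap_resample <- function(cohort, seed) {
  if (!nrow(cohort)) stop("cannot resample an empty cohort")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  idx <- sample.int(nrow(cohort), nrow(cohort), replace = TRUE)
  out <- cohort[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact population covariance of the structural model
#'
#' Returns the analytically propagated covariance over the gold-standard
#' graph's node names (diagnosis enters as the latent DX*, under its graph
#' name), wrapped as a `cov_model` with a nominal sample size. Useful for
#' faithfulness arguments and for running searches on exactly faithful
#' input with no sampling noise.
#'
#' @param params a `sem_parameters` object.
#' @param design `"cross_sectional"` or `"longitudinal"`.
#' @param n nominal sample size attached to the model (defaults to the
#'   benchmark cohort sizes, 1008 and 266).
#' @return a `cov_model`.
#' @export
population_cov_model <- function(params = default_parameters(),
                                 design = c("cross_sectional", "longitudinal"),
                                 n = NULL) {
  design <- match.arg(design)
  if (is.null(n)) n <- if (design == "cross_sectional") 1008 else 266
  cal <- calibrate_parameters(params, design)
  cov_model(cal$cov, n)
}

#' Write / read a cohort as CSV
#' @param cohort a data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
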