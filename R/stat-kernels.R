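# Gaussian sufficient statistics shared by both structure-search arms:
# Fisher-z conditional-independence testing and decomposable BIC scoring.

#' Covariance model (Gaussian sufficient statistic)
#'
#' @param sigma symmetric covariance matrix with dimnames.
#' @param n sample size the matrix was computed from (or is treated as).
#' @return an object of class `cov_model`.
#' @export
cov_model <- function(sigma, n) {
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma))
  if (is.null(rownames(sigma))) stop("covariance matrix needs dimnames")
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("covariance matrix not symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("covariance matrix not PSD")
  if (n < nrow(sigma) + 2) stop("n must be at least p + 2")
  structure(list(vars = rownames(sigma), sigma = (sigma + t(sigma)) / 2, n = n),
            class = "cov_model")
}

#' Covariance model from a cohort table
#'
#' Uses the maximum-likelihood covariance (denominator `n`) so that BIC
#' scoring and SEM likelihoods share one convention. The latent `DX_star`
#' column, when present, is dropped: search algorithms see the coded DX.
#'
#' @param cohort a data frame of numeric columns.
#' @param n overriding sample size (default `nrow(cohort)`).
#' @return a `cov_model`.
#' @export
cohort_cov <- function(cohort, n = nrow(cohort)) {
  cohort <- cohort[, !grepl("^DX_star", colnames(cohort)), drop = FALSE]
  x <- as.matrix(cohort)
  sigma <- stats::cov(x) * (nrow(x) - 1) / nrow(x)
  cov_model(sigma, n)
}

#' Fisher-z conditional-independence test
#'
#' Tests zero partial correlation of `x` and `y` given `S` under a
#' multivariate-Gaussian model: r is obtained from the inverse of the
#' covariance submatrix over `{x, y} \\u222a S`, then
#' `z = atanh(r) * sqrt(n - |S| - 3)` is referred to the standard normal
#' (two sided).
#'
#' @param cov a `cov_model`.
#' @param x,y variable names, distinct and not in `S`.
#' @param S character vector of conditioning variables.
#' @param alpha significance level in (0, 1).
#' @return a list with `r`, `z`, `p_value`, `independent`, `s` (|S|).
#' @export
fisher_z_test <- function(cov, x, y, S = character(), alpha = 0.05) {
  stopifnot(inherits(cov, "cov_model"), x != y, !(x %in% S), !(y %in% S),
            alpha > 0, alpha < 1)
  df <- cov$n - length(S) - 3
  if (df <= 0) stop("degrees of freedom exhausted (n - |S| - 3 <= 0)")
  vars <- c(x, y, S)
  sub <- cov$sigma[vars, vars, drop = FALSE]
  prec <- tryCatch(solve(sub), error = function(e)
    stop("singular conditioning submatrix for (", x, ",", y, " | ",
         paste(S, collapse = ","), ")"))
  r <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- atanh(r) * sqrt(df)
  p <- 2 * stats::pnorm(-abs(z))
  list(r = r, z = z, p_value = p, independent = p > alpha, s = length(S))
}

#' Score configuration for BIC-based search
#' @param penalty_discount multiplier `c > 0` on the BIC complexity penalty
#'   (default 1, the classical BIC).
#' @return an object of class `score_config`.
#' @export
score_config <- function(penalty_discount = 1) {
  stopifnot(penalty_discount > 0)
  structure(list(penalty_discount = penalty_discount), class = "score_config")
}

# ML residual variance of child regressed on parents, from the covariance
ml_residual_variance <- function(cov, child, parents) {
  s_cc <- cov$sigma[child, child]
  if (!length(parents)) return(s_cc)
  s_pp <- cov$sigma[parents, parents, drop = FALSE]
  s_pc <- cov$sigma[parents, child, drop = FALSE]
  beta <- tryCatch(solve(s_pp, s_pc), error = function(e)
    stop("collinear parents for ", child, ": ", paste(parents, collapse = ",")))
  drop(s_cc - crossprod(s_pc, beta))
}

#' Local Gaussian BIC score of one node given its parents
#'
#' Returns `-n * ln(sigma2_hat) - c * (|parents| + 1) * ln(n)` where
#' `sigma2_hat` is the maximum-likelihood residual variance of the child
#' regressed on its parents. Higher is better; the graph score is the sum of
#' local scores (decomposability), and Markov-equivalent DAGs tie exactly.
#'
#' @param cov a `cov_model`.
#' @param child variable name.
#' @param parents character vector (may be empty), not containing `child`.
#' @param config a `score_config`.
#' @return a real score.
#' @export
local_bic_score <- function(cov, child, parents = character(),
                            config = score_config()) {
  stopifnot(!(child %in% parents))
  sigma2 <- ml_residual_variance(cov, child, parents)
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  n <- cov$n
  -n * log(sigma2) - config$penalty_discount * (length(parents) + 1) * log(n)
}

#' Total BIC score of a DAG
#'
#' Sum of [local_bic_score()] over every node with its directed parents.
#' @param cov a `cov_model`.
#' @param dag a DAG over (a subset of) the covariance variables.
#' @param config a `score_config`.
#' @return a real score (higher is better).
#' @export
graph_bic_score <- function(cov, dag, config = score_config()) {
  if (has_directed_cycle(dag)) stop("graph_bic_score requires an acyclic graph")
  sum(vapply(dag$nodes, function(v) {
    local_bic_score(cov, v, directed_parents(dag, v), config)
  }, numeric(1)))
}

# Score of a CPDAG/PDAG: score of any consistent DAG extension (they tie).
pdag_score <- function(cov, pdag, config = score_config()) {
  graph_bic_score(cov, pdag_to_dag(pdag), config)
}
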