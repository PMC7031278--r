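# Shared fixtures: small linear-Gaussian simulators and independent oracles.

# random DAG on p nodes (edge prob 0.5 over the upper triangle) plus a
# faithful linear-Gaussian sample with coefficients in [0.4, 0.9], unit noise
rand_linear_sim <- function(p, n, seed, edge_prob = 0.5) {
  set.seed(seed)
  nodes <- LETTERS[1:p]
  g <- mixed_graph(nodes, kind_hint = "DAG")
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    if (stats::runif(1) < edge_prob) g <- add_edge(g, nodes[i], nodes[j])
  }
  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, nodes))
  for (j in seq_len(p)) {
    pa <- directed_parents(g, nodes[j])
    if (length(pa)) {
      b <- stats::runif(length(pa), 0.4, 0.9) * sample(c(-1, 1), length(pa), TRUE)
      x[, j] <- x[, j] + as.matrix(x[, pa, drop = FALSE]) %*% b
    }
  }
  list(dag = g, data = as.data.frame(x), cov = cohort_cov(as.data.frame(x)))
}

sim_collider <- function(n, seed, b = 0.7) {
  set.seed(seed)
  A <- stats::rnorm(n); B <- stats::rnorm(n)
  C <- b * A + b * B + stats::rnorm(n)
  data.frame(A = A, B = B, C = C)
}

sim_chain <- function(n, seed, b = 0.7) {
  set.seed(seed)
  A <- stats::rnorm(n)
  B <- b * A + stats::rnorm(n)
  C <- b * B + stats::rnorm(n)
  data.frame(A = A, B = B, C = C)
}

sim_y_structure <- function(n, seed, b = 0.7) {
  set.seed(seed)
  W1 <- stats::rnorm(n); W2 <- stats::rnorm(n)
  X <- b * W1 + b * W2 + stats::rnorm(n)
  Y <- b * X + stats::rnorm(n)
  data.frame(W1 = W1, W2 = W2, X = X, Y = Y)
}

sim_latent_confounder <- function(n, seed, b = 0.8) {
  set.seed(seed)
  L <- stats::rnorm(n)
  data.frame(A = b * L + stats::rnorm(n), B = b * L + stats::rnorm(n))
}

# Independent d-separation oracle: enumerate all undirected paths and apply
# the textbook blocking definition (non-collider in S blocks; collider
# blocks unless it or a descendant is in S). Exponential; tiny graphs only.
dsep_by_paths <- function(g, x, y, S) {
  nodes <- g$nodes
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (a in nodes) for (b in nodes) {
    if (a != b && is_adjacent(g, a, b)) amat[a, b] <- TRUE
  }
  descendants <- function(v) {
    out <- v
    repeat {
      nxt <- unique(unlist(lapply(out, function(u) directed_children(g, u))))
      add <- setdiff(nxt, out)
      if (!length(add)) break
      out <- c(out, add)
    }
    out
  }
  paths <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == y) { paths[[length(paths) + 1L]] <<- path; return() }
    for (v in nodes[amat[cur, ]]) if (!(v %in% path)) walk(c(path, v))
  }
  walk(x)
  for (p in paths) {
    if (length(p) == 2) return(FALSE)  # direct edge never blocked
    blocked <- FALSE
    for (i in 2:(length(p) - 1)) {
      prev <- p[i - 1]; mid <- p[i]; nxt <- p[i + 1]
      is_coll <- g$marks[prev, mid] == adcausal:::MARK_ARROW &&
        g$marks[nxt, mid] == adcausal:::MARK_ARROW
      if (is_coll) {
        if (!any(descendants(mid) %in% S)) { blocked <- TRUE; break }
      } else if (mid %in% S) { blocked <- TRUE; break }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}
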