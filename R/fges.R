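# Score-based search: serial greedy equivalence search (GES) over CPDAGs
# with the decomposable Gaussian BIC, honoring tiered/forbidden background
# knowledge, plus an exhaustive enumeration oracle for small problems.
#
# Insert/delete operators and their validity conditions follow the published
# GES operator definitions: Insert(X,Y,T) requires NA_{Y,X} u T to be a
# clique and to block every semi-directed Y->X path; Delete(X,Y,H) requires
# NA_{Y,X} \ H to be a clique.

# neighbours of y (undirected-adjacent) that are adjacent to x
na_set <- function(g, y, x) {
  intersect(undirected_neighbors(g, y), adjacent_nodes(g, x))
}

is_clique <- function(g, nodes) {
  if (length(nodes) < 2) return(TRUE)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j > i && !is_adjacent(g, nodes[i], nodes[j])) return(FALSE)
  }
  TRUE
}

# does every semi-directed path from y to x pass through `blocked`?
# (semi-directed: each step is undirected or directed forward)
semi_directed_blocked <- function(g, y, x, blocked) {
  if (y %in% blocked) return(TRUE)
  seen <- y
  frontier <- y
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) {
      steps <- union(directed_children(g, u), undirected_neighbors(g, u))
      for (v in steps) {
        if (v %in% blocked || v %in% seen) next
        if (v == x) return(FALSE)
        seen <- c(seen, v); nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
  }
  TRUE
}

subsets_of <- function(x) {
  if (!length(x)) return(list(character()))
  out <- list(character())
  for (el in x) out <- c(out, lapply(out, function(s) c(s, el)))
  out
}

# rebuild the search state after applying an operator: extend the PDAG to a
# DAG, recompute the completed pattern, then re-impose knowledge-forced
# orientations and Meek closure.
rebuild_pattern <- function(pdag, knowledge) {
  g <- dag_to_cpdag(pdag_to_dag(pdag))
  apply_knowledge_pdag(g, knowledge)
}

best_insert <- function(cov, g, knowledge, config) {
  best <- list(delta = 0)
  for (x in g$nodes) for (y in g$nodes) {
    if (x == y || is_adjacent(g, x, y)) next
    if (knowledge_forbids(knowledge, x, y)) next
    nayx <- na_set(g, y, x)
    tpool <- setdiff(undirected_neighbors(g, y), adjacent_nodes(g, x))
    pa_y <- directed_parents(g, y)
    for (T in subsets_of(tpool)) {
      base <- union(nayx, T)
      if (!is_clique(g, base)) next
      if (!semi_directed_blocked(g, y, x, base)) next
      delta <- local_bic_score(cov, y, union(union(pa_y, base), x), config) -
        local_bic_score(cov, y, union(pa_y, base), config)
      if (delta > best$delta + 1e-10 ||
          (delta > best$delta - 1e-10 && length(best) > 1 &&
           paste(x, y) < paste(best$x, best$y))) {
        if (delta > 1e-10) best <- list(delta = delta, x = x, y = y, T = T)
      }
    }
  }
  best
}

best_delete <- function(cov, g, knowledge, config) {
  best <- list(delta = 0)
  for (x in g$nodes) for (y in g$nodes) {
    if (x == y) next
    directed_xy <- g$marks[x, y] == MARK_ARROW && g$marks[y, x] == MARK_TAIL
    undirected <- g$marks[x, y] == MARK_TAIL && g$marks[y, x] == MARK_TAIL
    if (!directed_xy && !undirected) next
    if (knowledge_requires(knowledge, x, y) ||
        knowledge_requires(knowledge, y, x)) next
    nayx <- na_set(g, y, x)
    pa_y <- directed_parents(g, y)
    for (H in subsets_of(nayx)) {
      keep <- setdiff(nayx, H)
      if (!is_clique(g, keep)) next
      base <- setdiff(union(pa_y, keep), x)
      delta <- local_bic_score(cov, y, base, config) -
        local_bic_score(cov, y, union(base, x), config)
      if (delta > best$delta + 1e-10) {
        best <- list(delta = delta, x = x, y = y, H = H,
                     undirected = undirected)
      }
    }
  }
  best
}

apply_insert <- function(g, mv) {
  g <- add_edge(g, mv$x, mv$y, "tail", "arrow")
  for (t in mv$T) g <- add_edge(g, t, mv$y, "tail", "arrow")
  g
}

apply_delete <- function(g, mv) {
  g <- remove_edge(g, mv$x, mv$y)
  for (h in mv$H) {
    g <- add_edge(g, mv$y, h, "tail", "arrow")
    if (g$marks[mv$x, h] == MARK_TAIL && g$marks[h, mv$x] == MARK_TAIL) {
      g <- add_edge(g, mv$x, h, "tail", "arrow")
    }
  }
  g
}

#' Greedy equivalence search with Gaussian BIC
#'
#' Serial GES: starting from the empty graph (plus any knowledge-required
#' edges), the forward phase repeatedly applies the best admissible edge
#' insertion while the total BIC improves, then the backward phase applies
#' the best admissible deletion while the score improves. After every move
#' the completed pattern is rebuilt and knowledge-forced orientations are
#' re-imposed. Returns a CPDAG (tail/arrow marks only).
#'
#' @param cov a `cov_model`.
#' @param knowledge a `background_knowledge` or `NULL`.
#' @param config a `score_config`.
#' @return a `mixed_graph` with `kind_hint = "CPDAG"` and attributes
#'   `score` (total BIC) and `moves` (a data frame log).
#' @export
fges_search <- function(cov, knowledge = NULL, config = score_config()) {
  g <- mixed_graph(cov$vars, kind_hint = "CPDAG")
  if (!is.null(knowledge) && nrow(knowledge$required)) {
    for (k in seq_len(nrow(knowledge$required))) {
      g <- add_edge(g, knowledge$required$from[k], knowledge$required$to[k])
    }
    if (has_directed_cycle(g)) stop("knowledge requires a cyclic graph")
    g <- rebuild_pattern(g, knowledge)
  }
  moves <- list()
  repeat {
    n_before <- length(moves)
    repeat {
      mv <- best_insert(cov, g, knowledge, config)
      if (mv$delta <= 1e-10) break
      g <- rebuild_pattern(apply_insert(g, mv), knowledge)
      moves[[length(moves) + 1L]] <- data.frame(
        phase = "insert", x = mv$x, y = mv$y, delta = mv$delta)
    }
    repeat {
      mv <- best_delete(cov, g, knowledge, config)
      if (mv$delta <= 1e-10) break
      g <- rebuild_pattern(apply_delete(g, mv), knowledge)
      moves[[length(moves) + 1L]] <- data.frame(
        phase = "delete", x = mv$x, y = mv$y, delta = mv$delta)
    }
    if (length(moves) == n_before) break
  }
  attr(g, "score") <- pdag_score(cov, g, config)
  attr(g, "moves") <- if (length(moves)) do.call(rbind, moves) else
    data.frame(phase = character(), x = character(), y = character(),
               delta = numeric())
  g
}

#' Exhaustive BIC search oracle
#'
#' Enumerates every knowledge-admissible DAG on the covariance variables
#' (at most 5), scores each with [graph_bic_score()], and returns the
#' completed pattern of the best-scoring DAG. Ties across distinct
#' equivalence classes are reported in the `ties` attribute.
#'
#' @inheritParams fges_search
#' @return the best CPDAG, with attributes `score` and `ties` (a list of
#'   tied CPDAGs, including the returned one).
#' @export
exhaustive_best_cpdag <- function(cov, knowledge = NULL,
                                  config = score_config()) {
  if (length(cov$vars) > 5) stop("exhaustive search limited to 5 variables")
  dags <- enumerate_dags(cov$vars)
  if (!is.null(knowledge)) {
    dags <- Filter(function(d) {
      ed <- graph_edges(d)
      ok <- TRUE
      for (k in seq_len(nrow(ed))) {
        from <- if (ed$mark_a[k] == "tail") ed$a[k] else ed$b[k]
        to <- setdiff(c(ed$a[k], ed$b[k]), from)
        if (knowledge_forbids(knowledge, from, to)) ok <- FALSE
      }
      if (nrow(knowledge$required)) {
        for (k in seq_len(nrow(knowledge$required))) {
          fr <- knowledge$required$from[k]; to <- knowledge$required$to[k]
          if (!(d$marks[fr, to] == MARK_ARROW && d$marks[to, fr] == MARK_TAIL))
            ok <- FALSE
        }
      }
      ok
    }, dags)
  }
  scores <- vapply(dags, function(d) graph_bic_score(cov, d, config), numeric(1))
  best <- max(scores)
  tied <- dags[scores > best - 1e-8]
  cpdags <- lapply(tied, dag_to_cpdag)
  uniq <- list(cpdags[[1]])
  for (g in cpdags[-1]) {
    if (!any(vapply(uniq, graphs_equal, logical(1), g2 = g))) {
      uniq[[length(uniq) + 1L]] <- g
    }
  }
  out <- uniq[[1]]
  if (!is.null(knowledge)) out <- apply_knowledge_pdag(out, knowledge)
  attr(out, "score") <- best
  attr(out, "ties") <- uniq
  out
}
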