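# Constraint-based search producing a partial ancestral graph (PAG):
# PC-style skeleton pruning with Fisher-z tests, possible-d-sep re-pruning,
# collider orientation and the FCI orientation-rule closure (R1-R4 plus the
# tail-completion rules R8-R10). Selection-bias rules are out of scope.

sepset_key <- function(x, y) paste(sort(c(x, y)), collapse = "|")

#' Conditional-independence test from a covariance model
#'
#' Returns a closure `f(x, y, S)` evaluating the Fisher-z test at level
#' `alpha`. Used as the default test of [learn_skeleton()] / [fci_search()].
#' @param cov a `cov_model`.
#' @param alpha significance level.
#' @return a function `(x, y, S) -> list(independent, p_value)`.
#' @export
fisher_ci_test <- function(cov, alpha = 0.05) {
  function(x, y, S) fisher_z_test(cov, x, y, S, alpha)
}

#' d-separation oracle as a conditional-independence test
#'
#' Substitutes exact d-separation on a known DAG for the statistical test,
#' for soundness checks of the search under perfect information.
#' @param dag the generating DAG.
#' @return a function `(x, y, S) -> list(independent, p_value)`.
#' @export
dsep_ci_test <- function(dag) {
  function(x, y, S) {
    ind <- d_separated(dag, x, y, S)
    list(independent = ind, p_value = if (ind) 1 else 0)
  }
}

#' Learn the skeleton by conditional-independence pruning
#'
#' Starts from the complete graph (pairs forbidden in both directions by
#' knowledge start disconnected) and, at increasing conditioning-set sizes
#' drawn from current adjacencies (PC-stable at each depth), removes edges
#' between conditionally independent pairs, recording the separating set.
#' Surviving edges carry circle marks at both ends.
#'
#' @param cov a `cov_model` (ignored when `ci` is supplied).
#' @param alpha significance level for the default Fisher-z test.
#' @param knowledge a `background_knowledge` or `NULL`.
#' @param ci optional CI-test closure `(x, y, S) -> list(independent, ...)`.
#' @param max_depth cap on conditioning-set size (default unlimited, bounded
#'   by adjacency degree).
#' @return a list with `graph` (circle-circle skeleton) and `sepsets`
#'   (environment keyed by sorted pair).
#' @export
learn_skeleton <- function(cov, alpha = 0.05, knowledge = NULL, ci = NULL,
                           max_depth = Inf) {
  if (is.null(ci)) ci <- fisher_ci_test(cov, alpha)
  nodes <- if (!is.null(cov)) cov$vars else stop("need cov or ci with nodes")
  g <- mixed_graph(nodes, kind_hint = "PAG")
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j > i) g <- add_edge(g, nodes[i], nodes[j], "circle", "circle")
  }
  sepsets <- new.env(parent = emptyenv())
  if (!is.null(knowledge)) {
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
      if (j > i && knowledge_forbids(knowledge, nodes[i], nodes[j]) &&
          knowledge_forbids(knowledge, nodes[j], nodes[i])) {
        g <- remove_edge(g, nodes[i], nodes[j])
        assign(sepset_key(nodes[i], nodes[j]), character(), envir = sepsets)
      }
    }
  }
  depth <- 0
  repeat {
    adj_frozen <- lapply(stats::setNames(nodes, nodes),
                         function(v) adjacent_nodes(g, v))
    any_possible <- FALSE
    for (x in nodes) for (y in nodes) {
      if (x == y || !is_adjacent(g, x, y)) next
      cand <- setdiff(adj_frozen[[x]], y)
      if (length(cand) < depth) next
      any_possible <- TRUE
      removed <- FALSE
      for (S in utils::combn(cand, depth, simplify = FALSE)) {
        res <- ci(x, y, S)
        if (res$independent) {
          g <- remove_edge(g, x, y)
          assign(sepset_key(x, y), S, envir = sepsets)
          removed <- TRUE
          break
        }
      }
      if (removed) next
    }
    depth <- depth + 1
    if (!any_possible || depth > max_depth) break
  }
  list(graph = g, sepsets = sepsets)
}

get_sepset <- function(sepsets, x, y) {
  key <- sepset_key(x, y)
  if (exists(key, envir = sepsets, inherits = FALSE)) {
    get(key, envir = sepsets, inherits = FALSE)
  } else NULL
}

arrowhead_allowed <- function(knowledge, from, to) {
  !knowledge_forbids(knowledge, from, to)
}

# apply forbidden/required pairs to a circle-marked graph, Tetrad style:
# forbidden (from, to) places an arrowhead at `from` (from is no cause of
# to); required (from, to) orients from -> to outright.
apply_knowledge_pag <- function(g, knowledge) {
  if (is.null(knowledge)) return(g)
  for (a in g$nodes) for (b in g$nodes) {
    if (a == b || !is_adjacent(g, a, b)) next
    if (knowledge_forbids(knowledge, a, b) && g$marks[b, a] == MARK_CIRCLE) {
      g$marks[b, a] <- MARK_ARROW  # arrowhead at a
    }
  }
  if (nrow(knowledge$required)) {
    for (k in seq_len(nrow(knowledge$required))) {
      fr <- knowledge$required$from[k]; to <- knowledge$required$to[k]
      if (is_adjacent(g, fr, to)) g <- add_edge(g, fr, to, "tail", "arrow")
    }
  }
  g
}

# R0: orient unshielded triples x *-* z *-* y (x, y nonadjacent) as
# colliders x *-> z <-* y when z is not in sepset(x, y). Conflicts with
# already-placed tails are logged, first orientation winning.
orient_colliders <- function(g, sepsets, knowledge = NULL) {
  conflicts <- character()
  nodes <- g$nodes
  for (z in nodes) {
    adj <- sort(adjacent_nodes(g, z))
    if (length(adj) < 2) next
    for (i in seq_along(adj)) for (j in seq_along(adj)) {
      if (j <= i) next
      x <- adj[i]; y <- adj[j]
      if (is_adjacent(g, x, y)) next
      S <- get_sepset(sepsets, x, y)
      if (is.null(S) || z %in% S) next
      for (from in c(x, y)) {
        if (!is.null(knowledge) && !arrowhead_allowed(knowledge, from, z)) next
        cur <- g$marks[from, z]
        if (cur == MARK_TAIL) {
          conflicts <- c(conflicts, paste0(from, "*->", z, " blocked by tail"))
        } else {
          g$marks[from, z] <- MARK_ARROW
        }
      }
    }
  }
  attr(g, "collider_conflicts") <- conflicts
  g
}

# Possible-D-SEP set of x: nodes reachable from x along paths on which every
# interior vertex is either a collider or part of a triangle.
pds_set <- function(g, x) {
  out <- character()
  # states are (prev, cur); expand while path condition holds
  frontier <- lapply(adjacent_nodes(g, x), function(v) c(x, v))
  seen <- vapply(frontier, paste, "", collapse = "->")
  while (length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      prev <- st[1]; cur <- st[2]
      out <- union(out, cur)
      for (v in adjacent_nodes(g, cur)) {
        if (v == prev || v == x) next
        collider <- g$marks[prev, cur] == MARK_ARROW &&
          g$marks[v, cur] == MARK_ARROW
        triangle <- is_adjacent(g, prev, v)
        if (!collider && !triangle) next
        key <- paste(cur, v, sep = "->")
        if (key %in% seen) next
        seen <- c(seen, key)
        nxt[[length(nxt) + 1L]] <- c(cur, v)
      }
    }
    frontier <- nxt
  }
  setdiff(out, x)
}

# possible-d-sep re-pruning: for each surviving edge, retest conditioning on
# subsets of Possible-D-SEP of either endpoint.
pdsep_prune <- function(g, sepsets, ci, max_depth = Inf) {
  gtmp <- orient_colliders(g, sepsets)
  ed <- graph_edges(g)
  for (k in seq_len(nrow(ed))) {
    x <- ed$a[k]; y <- ed$b[k]
    if (!is_adjacent(g, x, y)) next
    removed <- FALSE
    for (anchor in c(x, y)) {
      pool <- setdiff(pds_set(gtmp, anchor), c(x, y))
      maxs <- min(length(pool), max_depth)
      if (maxs < 1) next
      for (ssize in seq_len(maxs)) {
        for (S in utils::combn(pool, ssize, simplify = FALSE)) {
          res <- ci(x, y, S)
          if (res$independent) {
            g <- remove_edge(g, x, y)
            assign(sepset_key(x, y), S, envir = sepsets)
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
      if (removed) break
    }
  }
  g
}

# uncovered potentially-directed paths from a to b (each step mark at the
# near end is not an arrowhead and at the far end not a tail; consecutive
# path nodes' outer pair nonadjacent). Returns list of paths (node vectors).
upd_paths <- function(g, a, b, max_paths = 50) {
  out <- list()
  recurse <- function(path) {
    if (length(out) >= max_paths) return()
    cur <- path[length(path)]
    if (cur == b && length(path) > 2) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (v in adjacent_nodes(g, cur)) {
      if (v %in% path) next
      if (g$marks[v, cur] == MARK_ARROW) next      # no arrowhead back at cur
      if (g$marks[cur, v] == MARK_TAIL) next       # no tail at v
      if (length(path) >= 2 &&
          is_adjacent(g, path[length(path) - 1], v)) next  # uncovered
      if (v == b || v != b) recurse(c(path, v))
    }
  }
  for (v in adjacent_nodes(g, a)) {
    if (g$marks[v, a] == MARK_ARROW || g$marks[a, v] == MARK_TAIL) next
    if (v == b) next
    recurse(c(a, v))
  }
  out
}

# discriminating paths for triple (l, b, c): <theta, q1..qk, b, c> with every
# interior vertex a collider on the path and a parent of c, theta
# nonadjacent to c. Returns the theta node or NULL.
find_discriminating_theta <- function(g, b, c_) {
  # walk backwards from b through colliders that are parents of c
  found <- NULL
  recurse <- function(path) {
    if (!is.null(found)) return()
    head_ <- path[1]
    for (t in adjacent_nodes(g, head_)) {
      if (t %in% path || t == c_) next
      if (g$marks[t, head_] != MARK_ARROW) next  # t *-> head needed
      if (!is_adjacent(g, t, c_)) {
        # candidate theta: edge t *-> head, head collider chain to b
        found <<- t
        return()
      }
      # t must itself be a collider on the path and a parent of c to extend
      if (g$marks[head_, t] == MARK_ARROW &&
          g$marks[c_, t] == MARK_TAIL && g$marks[t, c_] == MARK_ARROW) {
        recurse(c(t, path))
      }
    }
  }
  # immediate predecessors l with l *-> b and l -> c
  for (l in adjacent_nodes(g, b)) {
    if (l == c_) next
    if (g$marks[l, b] != MARK_ARROW) next
    if (!(g$marks[c_, l] == MARK_TAIL && g$marks[l, c_] == MARK_ARROW)) next
    recurse(c(l, b))
    if (!is.null(found)) return(list(theta = found))
  }
  NULL
}

#' Orient a skeleton into a PAG
#'
#' Applies background-knowledge endpoint constraints, collider orientation
#' (R0), and the FCI orientation-rule closure: R1-R4 (arrowhead/tail
#' propagation and discriminating paths) and the tail-completion rules
#' R8-R10. Selection-bias rules (R5-R7) are not implemented since no
#' selection variables are modelled.
#'
#' @param skeleton circle-marked `mixed_graph` from [learn_skeleton()].
#' @param sepsets sepset environment from [learn_skeleton()].
#' @param knowledge a `background_knowledge` or `NULL`.
#' @return a `mixed_graph` PAG with attribute `collider_conflicts`.
#' @export
orient_pag <- function(skeleton, sepsets, knowledge = NULL) {
  g <- apply_knowledge_pag(skeleton, knowledge)
  g <- orient_colliders(g, sepsets, knowledge)
  conflicts <- attr(g, "collider_conflicts")
  set_mark <- function(g, from, to, mark) {
    # set mark at `to` on edge (from, to), only onto circles
    if (g$marks[from, to] == MARK_CIRCLE) g$marks[from, to] <- mark
    g
  }
  repeat {
    before <- g$marks
    nodes <- g$nodes
    for (a in nodes) for (b in nodes) {
      if (a == b || !is_adjacent(g, a, b)) next
      # R1: a *-> b o-* c, a/c nonadjacent  =>  b -> c
      if (g$marks[a, b] == MARK_ARROW) {
        for (c_ in adjacent_nodes(g, b)) {
          if (c_ == a || is_adjacent(g, a, c_)) next
          if (g$marks[c_, b] == MARK_CIRCLE) {
            if (is.null(knowledge) || arrowhead_allowed(knowledge, b, c_)) {
              g$marks[c_, b] <- MARK_TAIL
              g <- set_mark(g, b, c_, MARK_ARROW)
            }
          }
        }
      }
      # R2: (a -> b *-> c) or (a *-> b -> c), with a *-o c  =>  a *-> c
      for (c_ in adjacent_nodes(g, a)) {
        if (c_ == b || !is_adjacent(g, b, c_)) next
        if (g$marks[a, c_] != MARK_CIRCLE) next
        chain1 <- g$marks[b, a] == MARK_TAIL && g$marks[a, b] == MARK_ARROW &&
          g$marks[b, c_] == MARK_ARROW
        chain2 <- g$marks[a, b] == MARK_ARROW && g$marks[c_, b] == MARK_TAIL &&
          g$marks[b, c_] == MARK_ARROW
        if ((chain1 || chain2) &&
            (is.null(knowledge) || arrowhead_allowed(knowledge, a, c_))) {
          g$marks[a, c_] <- MARK_ARROW
        }
      }
    }
    # R3: a *-> b <-* c, a *-o d o-* c, a/c nonadjacent, d *-o b => d *-> b
    for (b in nodes) for (d_ in nodes) {
      if (b == d_ || !is_adjacent(g, b, d_)) next
      if (g$marks[d_, b] != MARK_CIRCLE) next
      cand <- intersect(adjacent_nodes(g, b), adjacent_nodes(g, d_))
      cand <- setdiff(cand, c(b, d_))
      hit <- FALSE
      for (a in cand) for (c_ in cand) {
        if (a >= c_ || is_adjacent(g, a, c_)) next
        if (g$marks[a, b] == MARK_ARROW && g$marks[c_, b] == MARK_ARROW &&
            g$marks[a, d_] == MARK_CIRCLE && g$marks[c_, d_] == MARK_CIRCLE) {
          hit <- TRUE
        }
      }
      if (hit && (is.null(knowledge) || arrowhead_allowed(knowledge, d_, b))) {
        g$marks[d_, b] <- MARK_ARROW
      }
    }
    # R4: discriminating path for <l, b, c>
    for (b in nodes) for (c_ in nodes) {
      if (b == c_ || !is_adjacent(g, b, c_)) next
      if (g$marks[c_, b] != MARK_CIRCLE) next  # b's mark toward c unknown
      dp <- find_discriminating_theta(g, b, c_)
      if (is.null(dp)) next
      S <- get_sepset(sepsets, dp$theta, c_)
      if (is.null(S)) next
      if (b %in% S) {
        g$marks[c_, b] <- MARK_TAIL
        g <- set_mark(g, b, c_, MARK_ARROW)
      } else {
        g$marks[c_, b] <- MARK_ARROW
        g <- set_mark(g, b, c_, MARK_ARROW)
      }
    }
    # R8: a o-> c and a -> b -> c  =>  a -> c (tail at a)
    for (a in nodes) for (c_ in nodes) {
      if (a == c_ || !is_adjacent(g, a, c_)) next
      if (!(g$marks[c_, a] == MARK_CIRCLE && g$marks[a, c_] == MARK_ARROW)) next
      fired <- FALSE
      for (b in intersect(directed_children(g, a), directed_parents(g, c_))) {
        fired <- TRUE
      }
      # R9: uncovered potentially-directed path a..c avoiding adjacency of c
      if (!fired) {
        for (p in upd_paths(g, a, c_)) {
          if (length(p) >= 3 && !is_adjacent(g, p[2], c_) && p[2] != c_) {
            fired <- TRUE; break
          }
        }
      }
      # R10: two u.p.d. paths from a toward distinct nonadjacent parents of c
      if (!fired) {
        pars <- directed_parents(g, c_)
        if (length(pars) >= 2) {
          firsts <- list()
          for (b in pars) {
            for (p in upd_paths(g, a, b)) firsts[[length(firsts) + 1L]] <-
                c(b, p[2])
            # direct edge a (-o or -) b also counts as a trivial path
            if (is_adjacent(g, a, b) && g$marks[b, a] != MARK_ARROW &&
                g$marks[a, b] != MARK_TAIL) {
              firsts[[length(firsts) + 1L]] <- c(b, b)
            }
          }
          if (length(firsts) >= 2) {
            for (i in seq_along(firsts)) for (j in seq_along(firsts)) {
              if (j <= i || fired) next
              mu <- firsts[[i]][2]; om <- firsts[[j]][2]
              if (firsts[[i]][1] != firsts[[j]][1] && mu != om &&
                  !is_adjacent(g, mu, om)) fired <- TRUE
            }
          }
        }
      }
      if (fired) g$marks[c_, a] <- MARK_TAIL
    }
    if (identical(before, g$marks)) break
  }
  g$kind_hint <- "PAG"
  attr(g, "collider_conflicts") <- conflicts
  g
}

#' Full FCI search
#'
#' Composition of skeleton learning, the possible-d-sep re-pruning stage and
#' PAG orientation.
#'
#' @inheritParams learn_skeleton
#' @param skip_pdsep when `TRUE`, skip the possible-d-sep stage (the cheaper
#'   variant).
#' @return a `mixed_graph` PAG.
#' @export
fci_search <- function(cov, alpha = 0.05, knowledge = NULL,
                       skip_pdsep = FALSE, ci = NULL, max_depth = Inf) {
  if (is.null(ci)) ci <- fisher_ci_test(cov, alpha)
  sk <- learn_skeleton(cov, alpha, knowledge, ci, max_depth)
  g <- sk$graph
  if (!skip_pdsep) {
    g <- pdsep_prune(g, sk$sepsets, ci, max_depth)
  }
  orient_pag(g, sk$sepsets, knowledge)
}
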