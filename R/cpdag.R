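# CPDAG machinery: v-structures, Meek closure, DAG <-> CPDAG conversion,
# consistent extension of a PDAG (Dor-Tarsi), and brute-force enumeration
# helpers used as independent oracles in the tests.

# list of v-structures (unshielded colliders) a -> c <- b, a/b nonadjacent
v_structures <- function(dag) {
  out <- list()
  for (c_ in dag$nodes) {
    pa <- directed_parents(dag, c_)
    if (length(pa) < 2) next
    for (i in seq_along(pa)) for (j in seq_along(pa)) {
      if (j <= i) next
      if (!is_adjacent(dag, pa[i], pa[j])) {
        ab <- sort(c(pa[i], pa[j]))
        out[[length(out) + 1L]] <- c(ab[1], c_, ab[2])
      }
    }
  }
  out
}

# Meek orientation rules applied to a PDAG until closure. `knowledge`, when
# given, is consulted only to avoid orienting an edge into a forbidden
# direction via the pre-orientation step (see apply_knowledge_pdag).
meek_closure <- function(g) {
  repeat {
    changed <- FALSE
    for (a in g$nodes) for (b in g$nodes) {
      if (a == b) next
      # undirected a - b?
      if (!(g$marks[a, b] == MARK_TAIL && g$marks[b, a] == MARK_TAIL)) next
      # R1: exists c -> a, c not adjacent b  =>  a -> b
      fired <- FALSE
      for (c_ in directed_parents(g, a)) {
        if (!is_adjacent(g, c_, b)) { fired <- TRUE; break }
      }
      # R2: a -> c -> b for some c, with a - b  =>  a -> b
      if (!fired) {
        for (c_ in directed_children(g, a)) {
          if (b %in% directed_children(g, c_)) { fired <- TRUE; break }
        }
      }
      # R3: a - c -> b and a - d -> b with c,d nonadjacent  =>  a -> b
      if (!fired) {
        cand <- intersect(undirected_neighbors(g, a), directed_parents(g, b))
        if (length(cand) >= 2) {
          for (i in seq_along(cand)) for (j in seq_along(cand)) {
            if (j <= i || fired) next
            if (!is_adjacent(g, cand[i], cand[j])) fired <- TRUE
          }
        }
      }
      # R4: a - b with a adjacent c, c -> d -> b, b/c nonadjacent  =>  a -> b
      if (!fired) {
        for (d_ in directed_parents(g, b)) {
          for (c_ in directed_parents(g, d_)) {
            if (c_ != a && c_ != b && is_adjacent(g, a, c_) &&
                !is_adjacent(g, c_, b)) { fired <- TRUE; break }
          }
          if (fired) break
        }
      }
      if (fired) {
        g <- add_edge(g, a, b, "tail", "arrow")
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g
}

#' Convert a DAG to its CPDAG (completed pattern)
#'
#' Returns the canonical representative of the DAG's Markov equivalence
#' class: the skeleton with v-structure arrows kept, all remaining edges
#' undirected, then closed under the Meek orientation rules so that every
#' compelled edge is directed.
#'
#' @param dag a `mixed_graph` that is a DAG.
#' @return a `mixed_graph` with `kind_hint = "CPDAG"`.
#' @export
dag_to_cpdag <- function(dag) {
  if (!is_dag(dag)) stop("input must be a DAG (acyclic, all edges directed)")
  g <- mixed_graph(dag$nodes, kind_hint = "CPDAG")
  ed <- graph_edges(dag)
  for (k in seq_len(nrow(ed))) {
    g <- add_edge(g, ed$a[k], ed$b[k], "tail", "tail")
  }
  for (v in v_structures(dag)) {
    g <- add_edge(g, v[1], v[2], "tail", "arrow")
    g <- add_edge(g, v[3], v[2], "tail", "arrow")
  }
  g <- meek_closure(g)
  g$kind_hint <- "CPDAG"
  g
}

# Consistent extension of a PDAG to a DAG (Dor & Tarsi 1992). Directed edges
# are preserved; undirected edges receive an orientation. Errors when no
# consistent extension exists.
pdag_to_dag <- function(g) {
  work <- g
  out <- mixed_graph(g$nodes, kind_hint = "DAG")
  remaining <- g$nodes
  # copy directed edges up front
  ed <- graph_edges(g)
  for (k in seq_len(nrow(ed))) {
    if (ed$mark_a[k] == "tail" && ed$mark_b[k] == "arrow") {
      out <- add_edge(out, ed$a[k], ed$b[k], "tail", "arrow")
    } else if (ed$mark_a[k] == "arrow" && ed$mark_b[k] == "tail") {
      out <- add_edge(out, ed$b[k], ed$a[k], "tail", "arrow")
    } else if (!(ed$mark_a[k] == "tail" && ed$mark_b[k] == "tail")) {
      stop("pdag_to_dag requires a PDAG (tail/arrow marks only)")
    }
  }
  while (length(remaining) > 0) {
    found <- FALSE
    for (v in remaining) {
      if (length(directed_children(work, v)) > 0) next  # must be a sink
      nb_und <- undirected_neighbors(work, v)
      adj_v <- adjacent_nodes(work, v)
      ok <- TRUE
      for (u in nb_und) {
        if (!all(setdiff(adj_v, u) %in% adjacent_nodes(work, u))) { ok <- FALSE; break }
      }
      if (!ok) next
      for (u in nb_und) out <- add_edge(out, u, v, "tail", "arrow")
      for (u in adj_v) work <- remove_edge(work, v, u)
      remaining <- setdiff(remaining, v)
      found <- TRUE
      break
    }
    if (!found) stop("PDAG admits no consistent extension")
  }
  out
}

# All DAGs on a node set: enumerate each unordered pair's state
# (absent, a->b, b->a) and keep the acyclic ones. Oracle-grade only (<=5 nodes).
enumerate_dags <- function(nodes, skeleton = NULL) {
  p <- length(nodes)
  if (p > 5) stop("enumeration limited to 5 nodes")
  pairs <- utils::combn(p, 2)
  npair <- ncol(pairs)
  if (!is.null(skeleton)) {
    keep <- vapply(seq_len(npair), function(k) {
      is_adjacent(skeleton, nodes[pairs[1, k]], nodes[pairs[2, k]])
    }, logical(1))
  } else keep <- rep(TRUE, npair)
  states <- lapply(seq_len(npair), function(k) if (keep[k]) {
    if (is.null(skeleton)) 0:2 else 1:2
  } else 0L)
  grid <- expand.grid(states, KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (r in seq_len(nrow(grid))) {
    g <- mixed_graph(nodes, kind_hint = "DAG")
    for (k in seq_len(npair)) {
      s <- grid[r, k]
      if (s == 1) g <- add_edge(g, nodes[pairs[1, k]], nodes[pairs[2, k]])
      if (s == 2) g <- add_edge(g, nodes[pairs[2, k]], nodes[pairs[1, k]])
    }
    if (!has_directed_cycle(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# Independent Markov-equivalence oracle: two DAGs on the same nodes are
# equivalent iff they imply identical d-separation statements (checked
# exhaustively over all pairs and conditioning sets).
same_d_separations <- function(g1, g2) {
  nodes <- g1$nodes
  p <- length(nodes)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    others <- nodes[-c(i, j)]
    for (ssize in 0:length(others)) {
      subsets <- if (ssize == 0) list(character()) else
        utils::combn(others, ssize, simplify = FALSE)
      for (S in subsets) {
        if (d_separated(g1, nodes[i], nodes[j], S) !=
            d_separated(g2, nodes[i], nodes[j], S)) return(FALSE)
      }
    }
  }
  TRUE
}
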