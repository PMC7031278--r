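# Mixed-graph data model: DAGs, CPDAGs and PAGs share one representation.
#
# Internally a graph is a square integer "marks" matrix M over the node set:
#   M[i, j] = endpoint mark at node j on the edge between i and j
#   0 = no edge, 1 = circle, 2 = arrowhead, 3 = tail
# so a directed edge i -> j is M[i, j] == 2 (arrow at j) and M[j, i] == 3
# (tail at i); an undirected edge is tail/tail; a PAG edge may carry circles.

MARK_NONE <- 0L
MARK_CIRCLE <- 1L
MARK_ARROW <- 2L
MARK_TAIL <- 3L

#' Construct a mixed graph
#'
#' A mixed graph holds a node set and a set of edges whose two endpoints each
#' carry a mark: tail, arrowhead, or circle. The same container represents
#' DAGs (all edges tail/arrow), CPDAGs (tail/arrow and tail/tail) and partial
#' ancestral graphs (PAGs, which may carry circle marks).
#'
#' @param nodes character vector of distinct variable names.
#' @param edges optional data frame with columns `a`, `b`, `mark_a`, `mark_b`;
#'   marks are `"tail"`, `"arrow"` or `"circle"`. At most one edge per
#'   unordered pair; no self loops.
#' @param kind_hint one of `"DAG"`, `"CPDAG"`, `"PAG"`.
#' @return an object of class `mixed_graph`.
#' @examples
#' g <- mixed_graph(c("A", "B"),
#'                  data.frame(a = "A", b = "B",
#'                             mark_a = "tail", mark_b = "arrow"))
#' format(g)
#' @export
mixed_graph <- function(nodes, edges = NULL, kind_hint = c("PAG", "DAG", "CPDAG")) {
  kind_hint <- match.arg(kind_hint)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  p <- length(nodes)
  m <- matrix(MARK_NONE, p, p, dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, marks = m, kind_hint = kind_hint),
                 class = "mixed_graph")
  if (!is.null(edges) && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      g <- add_edge(g, edges$a[k], edges$b[k], edges$mark_a[k], edges$mark_b[k])
    }
  }
  g
}

mark_code <- function(mark) {
  if (is.numeric(mark)) return(as.integer(mark))
  codes <- c(tail = MARK_TAIL, arrow = MARK_ARROW, circle = MARK_CIRCLE)
  out <- codes[as.character(mark)]
  if (anyNA(out)) stop("unknown endpoint mark: ", mark)
  unname(out)
}

mark_name <- function(code) {
  c("circle", "arrow", "tail")[code]
}

#' Add or replace a single edge
#'
#' @param g a `mixed_graph`.
#' @param a,b node names (must be declared in `g`, `a != b`).
#' @param mark_a,mark_b endpoint marks at `a` and `b` (`"tail"`, `"arrow"`,
#'   `"circle"`).
#' @return the modified graph.
#' @export
add_edge <- function(g, a, b, mark_a = "tail", mark_b = "arrow") {
  stopifnot(inherits(g, "mixed_graph"))
  if (!(a %in% g$nodes) || !(b %in% g$nodes)) {
    stop("edge endpoint not among declared nodes: ", a, " / ", b)
  }
  if (a == b) stop("self loops are not allowed")
  g$marks[b, a] <- mark_code(mark_a)  # mark at a
  g$marks[a, b] <- mark_code(mark_b)  # mark at b
  g
}

#' Remove the edge between two nodes, if present
#' @inheritParams add_edge
#' @return the modified graph.
#' @export
remove_edge <- function(g, a, b) {
  g$marks[a, b] <- MARK_NONE
  g$marks[b, a] <- MARK_NONE
  g
}

#' List the edges of a mixed graph
#'
#' @param g a `mixed_graph`.
#' @return a data frame with columns `a`, `b`, `mark_a`, `mark_b`, one row per
#'   edge, in canonical order (pairs sorted by node-list position, `a` before
#'   `b`).
#' @export
graph_edges <- function(g) {
  p <- length(g$nodes)
  out <- list()
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i) next
      if (g$marks[i, j] != MARK_NONE) {
        out[[length(out) + 1L]] <- data.frame(
          a = g$nodes[i], b = g$nodes[j],
          mark_a = mark_name(g$marks[j, i]),
          mark_b = mark_name(g$marks[i, j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(),
                      mark_a = character(), mark_b = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Number of edges in a mixed graph
#' @param g a `mixed_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(g) sum(g$marks != MARK_NONE) / 2L

is_adjacent <- function(g, a, b) g$marks[a, b] != MARK_NONE

#' Test whether two nodes are adjacent
#' @param g a `mixed_graph`.
#' @param a,b node names.
#' @return logical.
#' @export
graph_adjacent <- function(g, a, b) is_adjacent(g, a, b)

adjacent_nodes <- function(g, a) {
  g$nodes[g$marks[a, ] != MARK_NONE | g$marks[, a] != MARK_NONE]
}

# children via fully directed edges a -> x
directed_children <- function(g, a) {
  g$nodes[g$marks[a, ] == MARK_ARROW & g$marks[, a] == MARK_TAIL]
}

directed_parents <- function(g, a) {
  g$nodes[g$marks[, a] == MARK_ARROW & g$marks[a, ] == MARK_TAIL]
}

# neighbours via undirected (tail-tail) edges
undirected_neighbors <- function(g, a) {
  g$nodes[g$marks[a, ] == MARK_TAIL & g$marks[, a] == MARK_TAIL]
}

#' Test whether a graph is a DAG
#'
#' True when every edge is tail/arrow and the directed graph is acyclic.
#' @param g a `mixed_graph`.
#' @return logical.
#' @export
is_dag <- function(g) {
  m <- g$marks
  present <- m != MARK_NONE
  if (!all(m[present] %in% c(MARK_ARROW, MARK_TAIL))) return(FALSE)
  # every edge must be tail at one end, arrow at the other
  for (i in seq_along(g$nodes)) for (j in seq_along(g$nodes)) {
    if (j > i && present[i, j]) {
      if (!((m[i, j] == MARK_ARROW && m[j, i] == MARK_TAIL) ||
            (m[i, j] == MARK_TAIL && m[j, i] == MARK_ARROW))) return(FALSE)
    }
  }
  !has_directed_cycle(g)
}

# adjacency matrix of fully directed (tail -> arrow) edges: A[i,j]=1 iff i->j
directed_amat <- function(g) {
  p <- length(g$nodes)
  a <- matrix(0L, p, p, dimnames = dimnames(g$marks))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (g$marks[i, j] == MARK_ARROW && g$marks[j, i] == MARK_TAIL) a[i, j] <- 1L
  }
  a
}

has_directed_cycle <- function(g) {
  a <- directed_amat(g)
  if (sum(a) == 0) return(FALSE)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "directed")
  !igraph::is_dag(ig)
}

#' Topological order of a DAG
#' @param g a `mixed_graph` that is a DAG.
#' @return character vector of node names, parents before children.
#' @export
topological_order <- function(g) {
  if (!is_dag(g)) stop("topological order requires a DAG")
  a <- directed_amat(g)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "directed")
  g$nodes[as.integer(igraph::topo_sort(ig, mode = "out"))]
}

ancestors_of <- function(g, nodes) {
  # nodes plus all directed ancestors (tail->arrow edges only)
  a <- directed_amat(g)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "directed")
  idx <- match(nodes, g$nodes)
  reach <- unique(unlist(lapply(idx, function(i) {
    as.integer(igraph::subcomponent(ig, i, mode = "in"))
  })))
  g$nodes[sort(reach)]
}

#' d-separation in a DAG
#'
#' Tests whether `x` and `y` are d-separated by the set `S`, using the
#' ancestral moral graph construction: restrict to ancestors of
#' `{x, y} \\u222a S`, moralize (marry co-parents, drop directions), delete `S`,
#' and check that `x` and `y` fall in different connected components.
#'
#' @param g a DAG (`mixed_graph`).
#' @param x,y node names.
#' @param S character vector of conditioning nodes (may be empty).
#' @return logical: `TRUE` when d-separated.
#' @export
d_separated <- function(g, x, y, S = character()) {
  stopifnot(x != y, !(x %in% S), !(y %in% S))
  keep <- ancestors_of(g, unique(c(x, y, S)))
  a <- directed_amat(g)[keep, keep, drop = FALSE]
  p <- length(keep)
  und <- (a + t(a)) > 0
  # marry parents of each node
  for (j in seq_len(p)) {
    pa <- which(a[, j] == 1L)
    if (length(pa) > 1) for (u in pa) for (v in pa) if (u != v) und[u, v] <- TRUE
  }
  drop <- keep %in% S
  und <- und[!drop, !drop, drop = FALSE]
  left <- keep[!drop]
  if (!(x %in% left) || !(y %in% left)) return(TRUE)
  ig <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
  comp <- igraph::components(ig)$membership
  unname(comp[match(x, left)] != comp[match(y, left)])
}

#' @export
format.mixed_graph <- function(x, ...) {
  ed <- graph_edges(x)
  lines <- character(nrow(ed))
  for (k in seq_len(nrow(ed))) {
    lines[k] <- paste(ed$a[k], edge_token(ed$mark_a[k], ed$mark_b[k]), ed$b[k])
  }
  lines
}

#' @export
print.mixed_graph <- function(x, ...) {
  cat(sprintf("<mixed_graph: %s, %d nodes, %d edges>\n",
              x$kind_hint, length(x$nodes), n_edges(x)))
  cat("Nodes:", paste(x$nodes, collapse = ";"), "\n")
  for (l in format(x)) cat(" ", l, "\n")
  invisible(x)
}

edge_token <- function(mark_a, mark_b) {
  left <- c(tail = "-", arrow = "<", circle = "o")[mark_a]
  right <- c(tail = "-", arrow = ">", circle = "o")[mark_b]
  paste0(left, "-", right)
}

#' Graph equality
#'
#' Two mixed graphs are equal when they have the same node set and identical
#' endpoint marks for every pair.
#' @param g1,g2 `mixed_graph` objects.
#' @return logical.
#' @export
graphs_equal <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) return(FALSE)
  ord <- g1$nodes
  all(g1$marks[ord, ord] == g2$marks[ord, ord])
}

#' Write a mixed graph in text edge notation
#'
#' The format mirrors the Tetrad text convention: a node-list header followed
#' by one edge per line using the tokens `-->`, `---`, `o->`, `o-o`, `<->`.
#'
#' @param g a `mixed_graph`.
#' @param path file path, or `NULL` to return the text.
#' @return invisibly, the text written (a character vector of lines).
#' @export
write_graph_text <- function(g, path = NULL) {
  ed <- format(g)
  lines <- c("Graph Nodes:", paste(g$nodes, collapse = ";"),
             "", "Graph Edges:",
             if (length(ed)) paste0(seq_along(ed), ". ", ed))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a mixed graph from text edge notation
#'
#' Accepts the output of [write_graph_text()]: a `Graph Nodes:` header line
#' followed by a `;`- or `,`-separated node list, then `Graph Edges:` and one
#' edge per line (optionally numbered), e.g. `1. ABETA --> FDG`.
#'
#' @param text a character vector of lines, or a length-1 path to a file.
#' @param kind_hint the `kind_hint` to stamp on the result.
#' @return a `mixed_graph`.
#' @export
read_graph_text <- function(text, kind_hint = "PAG") {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  text <- trimws(text)
  ni <- grep("^Graph Nodes:", text)
  ei <- grep("^Graph Edges:", text)
  if (!length(ni) || !length(ei)) stop("missing 'Graph Nodes:'/'Graph Edges:' header")
  nodes <- trimws(strsplit(text[ni[1] + 1L], "[;,]")[[1]])
  nodes <- nodes[nzchar(nodes)]
  g <- mixed_graph(nodes, kind_hint = kind_hint)
  edge_lines <- text[(ei[1] + 1L):length(text)]
  edge_lines <- edge_lines[nzchar(edge_lines)]
  for (line in edge_lines) {
    line2 <- sub("^[0-9]+\\.\\s*", "", line)
    parts <- strsplit(line2, "\\s+")[[1]]
    if (length(parts) != 3) stop("malformed edge line: ", line)
    tok <- parts[2]
    if (!grepl("^[-o<][-][-o>]$", tok)) stop("malformed edge token: ", tok)
    lc <- substr(tok, 1, 1); rc <- substr(tok, 3, 3)
    mark_a <- switch(lc, "-" = "tail", "<" = "arrow", "o" = "circle")
    mark_b <- switch(rc, "-" = "tail", ">" = "arrow", "o" = "circle")
    g <- add_edge(g, parts[1], parts[3], mark_a, mark_b)
  }
  g
}
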