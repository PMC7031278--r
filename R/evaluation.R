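# Edge-level evaluation against the gold standard: correct / semi-correct /
# incorrect classification, precision and recall, bootstrap occurrence
# rates, and consensus graphs.

#' Classify one discovered edge against the gold standard
#'
#' With gold edge X -> Y: the candidate is *correct* iff its marks are
#' exactly tail at X and arrowhead at Y; *incorrect* iff it carries an
#' arrowhead at X (the gold cause's end — this covers reversed, bidirected
#' and circle-arrow-into-X edges, all of which contradict X causing Y);
#' *semi-correct* otherwise (undirected, circle-circle, or X o-> Y: marks
#' that do not contradict the true orientation). A candidate whose pair is
#' not adjacent in the gold graph is incorrect.
#'
#' @param edge one-row data frame with `a`, `b`, `mark_a`, `mark_b` (as
#'   returned by [graph_edges()]).
#' @param gold the gold-standard DAG.
#' @return `"correct"`, `"semi_correct"` or `"incorrect"`.
#' @export
classify_edge <- function(edge, gold) {
  a <- edge$a; b <- edge$b
  if (!(a %in% gold$nodes) || !(b %in% gold$nodes)) {
    stop("edge references nodes absent from the gold graph: ", a, ", ", b)
  }
  if (!is_adjacent(gold, a, b)) return("incorrect")
  # identify the gold cause end
  if (gold$marks[a, b] == MARK_ARROW) { x <- a; y <- b
    mark_x <- edge$mark_a; mark_y <- edge$mark_b
  } else { x <- b; y <- a
    mark_x <- edge$mark_b; mark_y <- edge$mark_a
  }
  if (mark_x == "tail" && mark_y == "arrow") return("correct")
  if (mark_x == "arrow") return("incorrect")
  "semi_correct"
}

#' Score a discovered graph against the gold standard
#'
#' Precision is the proportion of correct or semi-correct edges among all
#' edges the algorithm reported; recall is the proportion of gold edges
#' reported correctly or semi-correctly. An empty graph has recall 0 and
#' undefined (NA) precision.
#'
#' @param graph a discovered `mixed_graph`.
#' @param gold the gold-standard DAG.
#' @return a list: `correct`, `semi_correct`, `incorrect`, `precision`,
#'   `recall`.
#' @export
score_graph <- function(graph, gold) {
  ed <- graph_edges(graph)
  labels <- character(nrow(ed))
  for (k in seq_len(nrow(ed))) labels[k] <- classify_edge(ed[k, ], gold)
  n_corr <- sum(labels == "correct")
  n_semi <- sum(labels == "semi_correct")
  n_inc <- sum(labels == "incorrect")
  total <- nrow(ed)
  precision <- if (total > 0) (n_corr + n_semi) / total else NA_real_
  # recall: gold edges whose pair was reported correctly or semi-correctly
  gold_ed <- graph_edges(gold)
  hit <- 0
  for (k in seq_len(nrow(gold_ed))) {
    pa <- gold_ed$a[k]; pb <- gold_ed$b[k]
    m <- which((ed$a == pa & ed$b == pb) | (ed$a == pb & ed$b == pa))
    if (length(m) && labels[m[1]] %in% c("correct", "semi_correct")) hit <- hit + 1
  }
  recall <- if (nrow(gold_ed) > 0) hit / nrow(gold_ed) else NA_real_
  list(correct = n_corr, semi_correct = n_semi, incorrect = n_inc,
       precision = precision, recall = recall)
}

#' Adjacency-level precision and recall
#'
#' Orientation-blind variant: a reported adjacency counts as a hit when the
#' unordered pair is adjacent in the gold graph.
#' @inheritParams score_graph
#' @return list with `precision`, `recall`.
#' @export
score_adjacencies <- function(graph, gold) {
  ed <- graph_edges(graph)
  gold_ed <- graph_edges(gold)
  pair_id <- function(d) if (nrow(d)) {
    apply(cbind(pmin(d$a, d$b), pmax(d$a, d$b)), 1, paste, collapse = "|")
  } else character()
  got <- pair_id(ed); want <- pair_id(gold_ed)
  hits <- sum(got %in% want)
  list(precision = if (length(got)) hits / length(got) else NA_real_,
       recall = if (length(want)) sum(want %in% got) / length(want) else NA_real_)
}

#' Adjacency occurrence rates over a set of graphs
#'
#' The percentage of graphs (e.g. 100 bootstrap runs) in which each
#' unordered pair is adjacent, orientation ignored.
#'
#' @param graphs nonempty list of `mixed_graph`s over one node set.
#' @return data frame with `a`, `b`, `rate` (percent, 0-100), one row per
#'   pair that occurs at least once.
#' @export
occurrence_rates <- function(graphs) {
  if (!length(graphs)) stop("need at least one graph")
  nodes <- graphs[[1]]$nodes
  for (g in graphs) if (!setequal(g$nodes, nodes)) stop("inconsistent node sets")
  counts <- list()
  for (g in graphs) {
    ed <- graph_edges(g)
    for (k in seq_len(nrow(ed))) {
      key <- paste(sort(c(ed$a[k], ed$b[k])), collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  if (!length(counts)) {
    return(data.frame(a = character(), b = character(), rate = numeric()))
  }
  pairs <- strsplit(names(counts), "|", fixed = TRUE)
  data.frame(a = vapply(pairs, `[`, "", 1), b = vapply(pairs, `[`, "", 2),
             rate = 100 * unlist(counts) / length(graphs),
             row.names = NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Consensus graph over bootstrap runs
#'
#' Includes every unordered pair whose adjacency occurrence rate is at least
#' `threshold_pct`. Endpoint marks are the majority mark configuration among
#' the graphs containing the pair; ties fall back to circle marks.
#'
#' @param graphs nonempty list of `mixed_graph`s over one node set.
#' @param threshold_pct inclusion threshold in percent (default 80).
#' @return a `mixed_graph`.
#' @export
consensus_graph <- function(graphs, threshold_pct = 80) {
  rates <- occurrence_rates(graphs)
  nodes <- graphs[[1]]$nodes
  out <- mixed_graph(nodes, kind_hint = "PAG")
  keep <- rates[rates$rate >= threshold_pct, , drop = FALSE]
  for (k in seq_len(nrow(keep))) {
    a <- keep$a[k]; b <- keep$b[k]
    configs <- character()
    for (g in graphs) {
      if (is_adjacent(g, a, b)) {
        configs <- c(configs, paste(mark_name(g$marks[b, a]),
                                    mark_name(g$marks[a, b])))
      }
    }
    tab <- sort(table(configs), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      out <- add_edge(out, a, b, "circle", "circle")
    } else {
      mk <- strsplit(names(tab)[1], " ")[[1]]
      out <- add_edge(out, a, b, mk[1], mk[2])
    }
  }
  out
}

#' Build an evaluation report across bootstrap graphs
#'
#' Computes the per-bootstrap correct/semi-correct/incorrect counts and
#' precision/recall (averaged across runs), the adjacency occurrence rates,
#' the consensus graph at the given threshold and its own score.
#'
#' @param graphs list of discovered `mixed_graph`s (one per bootstrap run).
#' @param gold the gold-standard DAG.
#' @param algorithm,knowledge_level metadata recorded in the report.
#' @param threshold_pct consensus inclusion threshold.
#' @return an object of class `evaluation_report` (a list).
#' @export
evaluation_report <- function(graphs, gold, algorithm = NA_character_,
                              knowledge_level = NA_integer_,
                              threshold_pct = 80) {
  per_run <- lapply(graphs, score_graph, gold = gold)
  mean_of <- function(f) mean(vapply(per_run, `[[`, numeric(1), f), na.rm = TRUE)
  cons <- consensus_graph(graphs, threshold_pct)
  structure(list(
    algorithm = algorithm, knowledge_level = knowledge_level,
    n_bootstraps = length(graphs),
    mean_correct = mean_of("correct"),
    mean_semi_correct = mean_of("semi_correct"),
    mean_incorrect = mean_of("incorrect"),
    mean_precision = mean_of("precision"),
    mean_recall = mean_of("recall"),
    occurrence = occurrence_rates(graphs),
    consensus = cons,
    consensus_score = score_graph(cons, gold)),
    class = "evaluation_report")
}

#' Serialize an evaluation report to JSON
#' @param report an `evaluation_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  obj <- report
  obj$consensus <- write_graph_text(report$consensus)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
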