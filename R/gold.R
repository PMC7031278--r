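# The literature-derived gold-standard causal graph of the Alzheimer's
# biomarker cascade, and the three tiers of background knowledge used to
# constrain structure search.

#' Variables of the Alzheimer's biomarker cascade
#'
#' Demographics: AGE (years), SEX (0/1), EDU (years of education), APOE4
#' (number of APOE epsilon-4 alleles, 0/1/2). Biomarkers: ABETA (CSF
#' amyloid-beta), PTAU (CSF phosphorylated tau), FDG (FDG-PET metabolic
#' summary). Outcome: DX (diagnosis, CN/MCI/AD coded 0/1/2).
#' @name ad_variables
#' @keywords internal
NULL

AD_DEMOGRAPHICS <- c("AGE", "SEX", "EDU", "APOE4")
AD_MARKERS <- c("ABETA", "PTAU", "FDG", "DX")

# Default gold edge list; a data constant so users can supply their own.
gold_edge_table <- function() {
  data.frame(
    from = c("AGE", "APOE4", "ABETA", "ABETA", "PTAU", "PTAU", "FDG", "EDU"),
    to   = c("ABETA", "ABETA", "PTAU", "FDG", "FDG", "DX", "DX", "DX"),
    stringsAsFactors = FALSE)
}

#' Build the gold-standard causal DAG
#'
#' The cross-sectional graph covers AGE, SEX, EDU, APOE4, ABETA, PTAU, FDG
#' and DX with 8 directed edges encoding the amyloid cascade: age and APOE4
#' allele count drive amyloid (AGE->ABETA, APOE4->ABETA); amyloid drives tau
#' pathology and metabolic decline (ABETA->PTAU, ABETA->FDG, PTAU->FDG); tau
#' and metabolism drive diagnosis (PTAU->DX, FDG->DX); education buffers
#' cognition (EDU->DX). SEX appears as an isolated node: its influences are
#' deliberately excluded from the gold standard.
#'
#' The longitudinal graph duplicates the biomarker/diagnosis block into
#' baseline (".0") and 24-month (".24") copies, repeats the within-time
#' structure at both visits, adds an autoregressive edge X.0 -> X.24 for each
#' duplicated variable, and attaches demographics to baseline targets only.
#'
#' @param design `"cross_sectional"` or `"longitudinal"`.
#' @param edges optional replacement edge table (data frame with `from`,
#'   `to`) for the cross-sectional structure.
#' @return a `mixed_graph` DAG.
#' @examples
#' g <- build_gold_standard("cross_sectional")
#' n_edges(g)  # 8
#' @export
build_gold_standard <- function(design = c("cross_sectional", "longitudinal"),
                                edges = gold_edge_table()) {
  design <- match.arg(design)
  if (design == "cross_sectional") {
    g <- mixed_graph(c(AD_DEMOGRAPHICS, AD_MARKERS), kind_hint = "DAG")
    for (k in seq_len(nrow(edges))) g <- add_edge(g, edges$from[k], edges$to[k])
    return(g)
  }
  dup <- AD_MARKERS
  nodes <- c(AD_DEMOGRAPHICS, paste0(dup, ".0"), paste0(dup, ".24"))
  g <- mixed_graph(nodes, kind_hint = "DAG")
  suffixed <- function(v, s) if (v %in% dup) paste0(v, s) else v
  for (k in seq_len(nrow(edges))) {
    from <- edges$from[k]; to <- edges$to[k]
    # within-time structure at both visits; demographics feed time 0 only
    g <- add_edge(g, suffixed(from, ".0"), suffixed(to, ".0"))
    if (from %in% dup) {
      g <- add_edge(g, suffixed(from, ".24"), suffixed(to, ".24"))
    }
  }
  for (v in dup) g <- add_edge(g, paste0(v, ".0"), paste0(v, ".24"))
  g
}

#' Background knowledge container
#'
#' Holds must-not-have edges (ordered pairs), must-have edges, and temporal
#' tiers. Any directed edge from a strictly higher tier to a lower tier is
#' treated as forbidden; edges within a tier are unconstrained.
#'
#' @param forbidden data frame with columns `from`, `to` (may be empty).
#' @param required data frame with columns `from`, `to`.
#' @param tiers named integer vector mapping node -> tier index, or `NULL`.
#' @return an object of class `background_knowledge`.
#' @export
background_knowledge <- function(forbidden = NULL, required = NULL, tiers = NULL) {
  empty <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  if (is.null(forbidden)) forbidden <- empty
  if (is.null(required)) required <- empty
  if (nrow(forbidden) && nrow(required)) {
    fb <- paste(forbidden$from, forbidden$to)
    rq <- paste(required$from, required$to)
    if (length(intersect(fb, rq))) {
      stop("pairs cannot be both forbidden and required: ",
           paste(intersect(fb, rq), collapse = ", "))
    }
  }
  structure(list(forbidden = forbidden, required = required, tiers = tiers),
            class = "background_knowledge")
}

#' Does knowledge forbid the directed edge from -> to?
#' @param k a `background_knowledge`.
#' @param from,to node names.
#' @return logical.
#' @export
knowledge_forbids <- function(k, from, to) {
  if (is.null(k)) return(FALSE)
  if (nrow(k$forbidden) &&
      any(k$forbidden$from == from & k$forbidden$to == to)) return(TRUE)
  if (!is.null(k$tiers) && from %in% names(k$tiers) && to %in% names(k$tiers)) {
    if (k$tiers[[from]] > k$tiers[[to]]) return(TRUE)
  }
  FALSE
}

#' Does knowledge require the directed edge from -> to?
#' @param k a `background_knowledge`.
#' @param from,to node names.
#' @return logical.
#' @export
knowledge_requires <- function(k, from, to) {
  if (is.null(k) || !nrow(k$required)) return(FALSE)
  any(k$required$from == from & k$required$to == to)
}

# expand tiers into explicit forbidden pairs (for set comparisons)
knowledge_forbidden_pairs <- function(k, nodes) {
  out <- character()
  for (a in nodes) for (b in nodes) {
    if (a != b && knowledge_forbids(k, a, b)) out <- c(out, paste(a, b))
  }
  out
}

#' Build the three levels of background knowledge
#'
#' Level 1 ("no knowledge"): nothing is prohibited. Level 2 ("trivial
#' knowledge"): any edge pointing into a demographic variable (AGE, SEX,
#' EDU, APOE4) is prohibited, whatever its source. Level 3 ("longitudinal"):
#' level 2 plus temporal tiers — demographics in tier 0, baseline variables
#' in tier 1, 24-month variables in tier 2 — so edges from a later visit to
#' an earlier one are also prohibited.
#'
#' @param level 1, 2 or 3.
#' @param nodes the node set the knowledge applies to.
#' @param time_suffix_map for level 3: named integer vector mapping each
#'   non-demographic node to its visit index (0 or 1 for baseline/24 months).
#'   When `NULL`, nodes ending in `".0"`/`".24"` are mapped automatically;
#'   level 3 errors if any non-demographic node cannot be assigned a visit.
#' @param demographics which nodes count as demographic.
#' @return a `background_knowledge`.
#' @export
build_background_knowledge <- function(level, nodes, time_suffix_map = NULL,
                                       demographics = AD_DEMOGRAPHICS) {
  if (!level %in% 1:3) stop("level must be 1, 2 or 3")
  if (level == 1) return(background_knowledge())
  demo <- intersect(nodes, demographics)
  forb <- expand.grid(from = nodes, to = demo, stringsAsFactors = FALSE)
  forb <- forb[forb$from != forb$to, , drop = FALSE]
  rownames(forb) <- NULL
  if (level == 2) return(background_knowledge(forbidden = forb))
  nondemo <- setdiff(nodes, demo)
  if (is.null(time_suffix_map)) {
    visit <- ifelse(grepl("\\.24$", nondemo), 1L,
                    ifelse(grepl("\\.0$", nondemo), 0L, NA_integer_))
    names(visit) <- nondemo
    if (anyNA(visit)) {
      stop("level 3 requires a visit assignment for: ",
           paste(nondemo[is.na(visit)], collapse = ", "))
    }
    time_suffix_map <- visit
  }
  missing_nodes <- setdiff(nondemo, names(time_suffix_map))
  if (length(missing_nodes)) {
    stop("level 3 requires a visit assignment for: ",
         paste(missing_nodes, collapse = ", "))
  }
  tiers <- c(stats::setNames(rep(0L, length(demo)), demo),
             stats::setNames(as.integer(time_suffix_map[nondemo]) + 1L, nondemo))
  background_knowledge(forbidden = forb, tiers = tiers)
}

#' Write background knowledge to a JSON file
#' @param k a `background_knowledge`.
#' @param path output path.
#' @export
write_knowledge <- function(k, path) {
  obj <- list(
    forbidden = if (nrow(k$forbidden)) k$forbidden else NULL,
    required = if (nrow(k$required)) k$required else NULL,
    tiers = if (!is.null(k$tiers)) as.list(k$tiers) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read background knowledge from a JSON file
#' @param path file written by [write_knowledge()].
#' @return a `background_knowledge`.
#' @export
read_knowledge <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tiers <- if (!is.null(obj$tiers)) unlist(obj$tiers) else NULL
  background_knowledge(forbidden = obj$forbidden, required = obj$required,
                       tiers = tiers)
}

# Orient undirected edges of a PDAG whose one direction is forbidden, then
# close under Meek rules. Contradictions (both directions forbidden) are left
# untouched and reported via a warning.
apply_knowledge_pdag <- function(g, knowledge) {
  if (is.null(knowledge)) return(g)
  repeat {
    changed <- FALSE
    for (a in g$nodes) for (b in g$nodes) {
      if (a >= b) next
      if (g$marks[a, b] == MARK_TAIL && g$marks[b, a] == MARK_TAIL) {
        # a required edge forbids its reversal
        fab <- knowledge_forbids(knowledge, a, b) ||
          knowledge_requires(knowledge, b, a)
        fba <- knowledge_forbids(knowledge, b, a) ||
          knowledge_requires(knowledge, a, b)
        if (fab && fba) {
          warning("knowledge forbids both directions of ", a, " - ", b)
        } else if (fab) {
          g <- add_edge(g, b, a, "tail", "arrow"); changed <- TRUE
        } else if (fba) {
          g <- add_edge(g, a, b, "tail", "arrow"); changed <- TRUE
        }
      }
    }
    if (!changed) break
    g <- meek_closure(g)
  }
  g
}
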