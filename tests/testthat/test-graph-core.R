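# Graph data model, gold standard, knowledge levels, CPDAG utilities, I/O.

test_that("edge notation parses and round-trips", {
  g <- read_graph_text(c("Graph Nodes:", "ABETA;FDG;PTAU;DX", "", "Graph Edges:",
                         "1. ABETA --> FDG", "2. PTAU o-> DX", "3. ABETA o-o PTAU",
                         "4. FDG <-> DX", "5. ABETA --- DX"))
  ed <- graph_edges(g)
  expect_equal(ed$mark_a[ed$a == "ABETA" & ed$b == "FDG"], "tail")
  expect_equal(ed$mark_b[ed$a == "ABETA" & ed$b == "FDG"], "arrow")
  expect_equal(ed$mark_a[ed$a == "PTAU" & ed$b == "DX"], "circle")
  expect_equal(ed$mark_b[ed$a == "PTAU" & ed$b == "DX"], "arrow")
  expect_equal(ed$mark_a[ed$a == "ABETA" & ed$b == "PTAU"], "circle")
  # bidirected and undirected kinds survive a write/read cycle
  g2 <- read_graph_text(write_graph_text(g))
  expect_true(graphs_equal(g, g2))
  # malformed input
  expect_error(read_graph_text(c("Graph Nodes:", "A;B", "Graph Edges:",
                                 "1. A ==> B")), "malformed")
  expect_error(read_graph_text(c("Graph Nodes:", "A;B", "Graph Edges:",
                                 "1. A --> C")), "not among declared nodes")
})

test_that("gold standard graph has the published structure", {
  g <- build_gold_standard("cross_sectional")
  expect_equal(length(g$nodes), 8)
  expect_equal(n_edges(g), 8)
  expect_true(is_dag(g))
  # risk factors for amyloid
  expect_equal(unname(g$marks["AGE", "ABETA"]), adcausal:::MARK_ARROW)
  expect_equal(unname(g$marks["APOE4", "ABETA"]), adcausal:::MARK_ARROW)
  # SEX is isolated
  expect_equal(length(adjacent_nodes(g, "SEX")), 0)
  # round-trip through the text notation is identity
  expect_true(graphs_equal(g, read_graph_text(write_graph_text(g))))
})

test_that("longitudinal gold standard duplicates markers with AR edges", {
  g <- build_gold_standard("longitudinal")
  expect_setequal(g$nodes, c("AGE", "SEX", "EDU", "APOE4",
                             paste0(rep(c("ABETA", "PTAU", "FDG", "DX"), 2),
                                    rep(c(".0", ".24"), each = 4))))
  expect_true(is_dag(g))
  # autoregressive edges
  for (v in c("ABETA", "PTAU", "FDG", "DX")) {
    expect_equal(unname(g$marks[paste0(v, ".0"), paste0(v, ".24")]),
                 adcausal:::MARK_ARROW)
  }
  # demographics attach to time 0 only
  expect_true(is_adjacent(g, "AGE", "ABETA.0"))
  expect_false(is_adjacent(g, "AGE", "ABETA.24"))
  expect_false(is_adjacent(g, "EDU", "DX.24"))
  # within-time structure repeated at month 24
  expect_true(is_adjacent(g, "ABETA.24", "PTAU.24"))
  expect_error(build_gold_standard("monthly"))
})

test_that("background knowledge levels match their definitions", {
  nodes <- build_gold_standard()$nodes
  k1 <- build_background_knowledge(1, nodes)
  expect_equal(nrow(k1$forbidden), 0)
  expect_null(k1$tiers)

  k2 <- build_background_knowledge(2, nodes)
  expect_true(knowledge_forbids(k2, "ABETA", "AGE"))
  expect_false(knowledge_forbids(k2, "AGE", "ABETA"))
  expect_true(knowledge_forbids(k2, "EDU", "AGE"))  # demographic -> demographic
  expect_true(knowledge_forbids(k2, "DX", "SEX"))
  expect_false(knowledge_forbids(k2, "PTAU", "DX"))

  lnodes <- build_gold_standard("longitudinal")$nodes
  k3 <- build_background_knowledge(3, lnodes)
  expect_true(knowledge_forbids(k3, "DX.24", "PTAU.0"))    # later -> earlier
  expect_false(knowledge_forbids(k3, "PTAU.0", "DX.24"))
  expect_false(knowledge_forbids(k3, "PTAU.0", "DX.0"))    # within tier allowed
  expect_true(knowledge_forbids(k3, "ABETA.0", "AGE"))     # level-2 set kept
  # monotone: forbidden(level 2) subset of forbidden(level 3)
  k2l <- build_background_knowledge(2, lnodes)
  expect_true(all(adcausal:::knowledge_forbidden_pairs(k2l, lnodes) %in%
                    adcausal:::knowledge_forbidden_pairs(k3, lnodes)))
  # level 3 without visit annotation on unannotated nodes errors
  expect_error(build_background_knowledge(3, nodes), "visit")
  expect_error(build_background_knowledge(5, nodes))
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_knowledge(k3, path)
  k3b <- read_knowledge(path)
  expect_equal(sort(adcausal:::knowledge_forbidden_pairs(k3, lnodes)),
               sort(adcausal:::knowledge_forbidden_pairs(k3b, lnodes)))
})

test_that("d-separation agrees with the independent path-blocking oracle", {
  for (s in 1:15) {
    sim <- rand_linear_sim(4, 10, seed = 100 + s)
    g <- sim$dag
    nodes <- g$nodes
    for (i in 1:3) for (j in (i + 1):4) {
      others <- nodes[-c(i, j)]
      for (S in c(list(character()), as.list(others), list(others))) {
        expect_equal(d_separated(g, nodes[i], nodes[j], S),
                     dsep_by_paths(g, nodes[i], nodes[j], S),
                     info = paste("seed", s, nodes[i], nodes[j],
                                  paste(S, collapse = ",")))
      }
    }
  }
})

test_that("dag_to_cpdag: chains dissolve, colliders persist", {
  chain <- mixed_graph(c("A", "B", "C"),
                       data.frame(a = c("A", "B"), b = c("B", "C"),
                                  mark_a = "tail", mark_b = "arrow"))
  cp <- dag_to_cpdag(chain)
  expect_equal(unname(cp$marks["A", "B"]), adcausal:::MARK_TAIL)
  expect_equal(unname(cp$marks["B", "A"]), adcausal:::MARK_TAIL)
  expect_equal(unname(cp$marks["C", "B"]), adcausal:::MARK_TAIL)

  coll <- mixed_graph(c("A", "B", "C"),
                      data.frame(a = c("A", "B"), b = c("C", "C"),
                                 mark_a = "tail", mark_b = "arrow"))
  cp2 <- dag_to_cpdag(coll)
  expect_true(graphs_equal(cp2, coll))
  # cyclic input rejected
  cyc <- mixed_graph(c("A", "B"), kind_hint = "PAG")
  cyc$marks[] <- adcausal:::MARK_ARROW
  diag(cyc$marks) <- 0L
  expect_error(dag_to_cpdag(cyc), "DAG")
})

test_that("dag_to_cpdag matches brute-force equivalence-class enumeration", {
  # an edge is compelled iff every d-separation-equivalent DAG orients it
  # identically; checked by exhaustive enumeration on 4-node DAGs
  for (s in c(2, 5, 11, 23)) {
    sim <- rand_linear_sim(4, 10, seed = s)
    dag <- sim$dag
    cp <- dag_to_cpdag(dag)
    skel_dags <- enumerate_dags(dag$nodes, skeleton = dag)
    equiv <- Filter(function(d) same_d_separations(d, dag), skel_dags)
    expect_gte(length(equiv), 1)
    for (a in dag$nodes) for (b in dag$nodes) {
      if (a >= b || !is_adjacent(dag, a, b)) next
      dirs <- vapply(equiv, function(d) {
        if (d$marks[a, b] == adcausal:::MARK_ARROW) "ab" else "ba"
      }, "")
      if (length(unique(dirs)) == 1) {
        # compelled: CPDAG must direct it the common way
        if (dirs[1] == "ab") {
          expect_equal(unname(cp$marks[a, b]), adcausal:::MARK_ARROW)
        } else {
          expect_equal(unname(cp$marks[b, a]), adcausal:::MARK_ARROW)
        }
      } else {
        expect_equal(unname(cp$marks[a, b]), adcausal:::MARK_TAIL)
        expect_equal(unname(cp$marks[b, a]), adcausal:::MARK_TAIL)
      }
    }
    # idempotence on a member DAG of its own class
    expect_true(graphs_equal(cp, dag_to_cpdag(adcausal:::pdag_to_dag(cp))))
  }
})
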