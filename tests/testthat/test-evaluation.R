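# Edge classification, precision/recall, occurrence rates, consensus graphs.

mk_edge <- function(a, b, mark_a, mark_b) {
  data.frame(a = a, b = b, mark_a = mark_a, mark_b = mark_b,
             stringsAsFactors = FALSE)
}

test_that("classify_edge reproduces the exhaustive label table", {
  gold <- build_gold_standard()  # contains ABETA -> FDG; SEX-EDU not adjacent
  # the five edge kinds stated with ABETA first, against gold ABETA -> FDG
  kinds <- list(
    c("tail", "arrow", "correct"),       # ABETA --> FDG
    c("tail", "tail", "semi_correct"),   # ABETA --- FDG
    c("circle", "arrow", "semi_correct"),# ABETA o-> FDG
    c("circle", "circle", "semi_correct"),# ABETA o-o FDG
    c("arrow", "arrow", "incorrect"))    # ABETA <-> FDG
  for (k in kinds) {
    expect_equal(classify_edge(mk_edge("ABETA", "FDG", k[1], k[2]), gold),
                 k[3], info = paste(k[1], k[2]))
    # same edge written with endpoints swapped must classify identically
    expect_equal(classify_edge(mk_edge("FDG", "ABETA", k[2], k[1]), gold),
                 k[3], info = paste("swapped", k[1], k[2]))
  }
  # orientation against the gold direction
  reversed <- list(
    c("arrow", "tail", "incorrect"),     # ABETA <-- FDG
    c("arrow", "circle", "incorrect"),   # ABETA <-o FDG
    c("circle", "tail", "semi_correct")) # ABETA o-- FDG (no arrow at cause)
  for (k in reversed) {
    expect_equal(classify_edge(mk_edge("ABETA", "FDG", k[1], k[2]), gold),
                 k[3], info = paste(k[1], k[2]))
  }
  # pair absent from gold: always incorrect, for every edge kind
  for (k in kinds) {
    expect_equal(classify_edge(mk_edge("SEX", "EDU", k[1], k[2]), gold),
                 "incorrect")
  }
  expect_error(classify_edge(mk_edge("ABETA", "XYZ", "tail", "arrow"), gold),
               "absent")
})

test_that("score_graph: identity, empty graph, and the hand fixture", {
  gold <- build_gold_standard()
  sc <- score_graph(gold, gold)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$incorrect, 0)

  empty <- mixed_graph(gold$nodes)
  sc0 <- score_graph(empty, gold)
  expect_true(is.na(sc0$precision))
  expect_equal(sc0$recall, 0)

  # 3 correct + 1 semi-correct + 2 incorrect -> precision 4/6, recall 4/8
  cand <- mixed_graph(gold$nodes)
  cand <- add_edge(cand, "AGE", "ABETA", "tail", "arrow")    # correct
  cand <- add_edge(cand, "APOE4", "ABETA", "tail", "arrow")  # correct
  cand <- add_edge(cand, "ABETA", "PTAU", "tail", "arrow")   # correct
  cand <- add_edge(cand, "PTAU", "FDG", "circle", "circle")  # semi
  cand <- add_edge(cand, "DX", "FDG", "tail", "arrow")       # incorrect (reversed)
  cand <- add_edge(cand, "SEX", "EDU", "tail", "arrow")      # incorrect (absent)
  sc <- score_graph(cand, gold)
  expect_equal(sc$correct, 3)
  expect_equal(sc$semi_correct, 1)
  expect_equal(sc$incorrect, 2)
  expect_equal(sc$precision, 4 / 6)
  expect_equal(sc$recall, 4 / 8)

  # recall is monotone under adding a correct edge
  cand2 <- add_edge(cand, "EDU", "DX", "tail", "arrow")
  expect_gte(score_graph(cand2, gold)$recall, sc$recall)
})

test_that("occurrence rates count adjacencies orientation-blind", {
  g1 <- mixed_graph(c("A", "B", "C"),
                    data.frame(a = "A", b = "B", mark_a = "tail", mark_b = "arrow"))
  g2 <- mixed_graph(c("A", "B", "C"),
                    data.frame(a = "B", b = "A", mark_a = "tail", mark_b = "arrow"))
  g3 <- mixed_graph(c("A", "B", "C"),
                    data.frame(a = c("A", "B"), b = c("B", "C"),
                               mark_a = "circle", mark_b = "circle"))
  rates <- occurrence_rates(list(g1, g2, g3))
  expect_equal(rates$rate[rates$a == "A" & rates$b == "B"], 100)
  expect_equal(rates$rate[rates$a == "B" & rates$b == "C"], 100 / 3)
  # single graph: rates in {0, 100} (absent pairs are simply not listed)
  r1 <- occurrence_rates(list(g1))
  expect_true(all(r1$rate == 100))
  expect_error(occurrence_rates(list(g1, mixed_graph(c("A", "B")))),
               "inconsistent")
})

test_that("consensus graph applies threshold and majority marks", {
  base <- mixed_graph(c("A", "B"),
                      data.frame(a = "A", b = "B", mark_a = "tail",
                                 mark_b = "arrow"))
  und <- mixed_graph(c("A", "B"),
                     data.frame(a = "A", b = "B", mark_a = "tail",
                                mark_b = "tail"))
  none <- mixed_graph(c("A", "B"))
  # all identical: that graph
  expect_true(graphs_equal(consensus_graph(rep(list(base), 5)), base))
  # 79.9% < threshold 80: excluded; exactly 80%: included
  gs <- c(rep(list(base), 799), rep(list(none), 201))
  expect_equal(n_edges(consensus_graph(gs, 80)), 0)
  gs <- c(rep(list(base), 800), rep(list(none), 200))
  expect_equal(n_edges(consensus_graph(gs, 80)), 1)
  # 60 directed vs 40 undirected: majority directed
  gs <- c(rep(list(base), 60), rep(list(und), 40))
  cons <- consensus_graph(gs, 80)
  expect_equal(unname(cons$marks["A", "B"]), adcausal:::MARK_ARROW)
  # exact tie: circle marks
  gs <- c(rep(list(base), 50), rep(list(und), 50))
  cons <- consensus_graph(gs, 80)
  expect_equal(unname(cons$marks["A", "B"]), adcausal:::MARK_CIRCLE)
  expect_equal(unname(cons$marks["B", "A"]), adcausal:::MARK_CIRCLE)
})

test_that("evaluation reports aggregate and serialize", {
  gold <- build_gold_standard()
  g <- dag_to_cpdag(gold)
  rep_ <- evaluation_report(list(g, g, gold), gold, algorithm = "fges",
                            knowledge_level = 2)
  expect_equal(rep_$n_bootstraps, 3)
  expect_equal(rep_$mean_precision, 1)
  expect_equal(rep_$mean_recall, 1)
  expect_equal(rep_$consensus_score$precision, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$algorithm, "fges")
  expect_equal(parsed$mean_recall, 1)
})
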