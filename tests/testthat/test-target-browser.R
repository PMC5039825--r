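# The browsable target tree: hierarchy, counts, search, serialization.

motif_tree <- function(slim_terms = c("GO:0009636", "GO:0046677",
                                      "GO:0005515", "GO:0017124")) {
  fx <- go_motif_fixture()
  g <- parse_obo(fx$obo)
  ann <- parse_gaf(fx$gaf, g)
  list(g = g, ann = ann,
       tree = build_target_tree(g, slim_set(g, slim_terms), ann))
}

test_that("response to antibiotic renders as a child of response to toxic substance", {
  mt <- motif_tree()
  expect_true("GO:0046677" %in% mt$tree$children[["GO:0009636"]])
  expect_true("GO:0009636" %in% mt$tree$ns_roots$biological_process)
  expect_false("GO:0046677" %in% mt$tree$ns_roots$biological_process)
})

test_that("cumulative counts union direct proteins with all slim descendants", {
  mt <- motif_tree()
  nd <- mt$tree$nodes
  # GO:0046677 direct: P22222, P33333; GO:0009636 direct: P11111
  expect_equal(mt$tree$direct[["GO:0046677"]], c("P22222", "P33333"))
  expect_equal(mt$tree$direct[["GO:0009636"]], "P11111")
  expect_equal(proteins_for_node(mt$tree, "GO:0009636"),
               c("P11111", "P22222", "P33333"))
  expect_equal(nd$n_cumulative[nd$term == "GO:0009636"], 3L)
  # leaf: cumulative equals direct
  expect_equal(proteins_for_node(mt$tree, "GO:0046677"), c("P22222", "P33333"))
  # overlap is counted once: P22222 sits below both GO:0005515 and GO:0046677
  expect_equal(proteins_for_node(mt$tree, "biological_process"),
               c("P11111", "P22222", "P33333"))
  expect_error(proteins_for_node(mt$tree, "GO:1111111"), "not in the tree")
})

test_that("single-term slims hang off the namespace root with cumulative = direct", {
  mt <- motif_tree("GO:0009636")
  expect_equal(mt$tree$ns_roots$biological_process, "GO:0009636")
  expect_equal(proteins_for_node(mt$tree, "GO:0009636"),
               mt$tree$direct[["GO:0009636"]])
})

test_that("a diamond slim term appears under both parents with identical counts", {
  fx <- go_motif_fixture()
  g <- parse_obo(fx$obo)
  ann <- parse_gaf(fx$gaf, g)
  s <- slim_set(g, c("GO:0042221", "GO:0006950", "GO:0009636"))
  tree <- build_target_tree(g, s, ann)
  expect_true("GO:0009636" %in% tree$children[["GO:0042221"]])
  expect_true("GO:0009636" %in% tree$children[["GO:0006950"]])
  # shared node, computed once: one cumulative entry
  expect_equal(tree$nodes$n_cumulative[tree$nodes$term == "GO:0009636"], 3L)
})

test_that("slim hierarchy skips dropped GO intermediates", {
  fx <- go_motif_fixture()
  g <- parse_obo(fx$obo)
  ann <- parse_gaf(fx$gaf, g)
  # GO:0046677 is_a GO:0009636 is_a GO:0042221: without GO:0009636 in the
  # slim, GO:0046677 must attach directly under GO:0042221
  tree <- build_target_tree(g, slim_set(g, c("GO:0042221", "GO:0046677")), ann)
  expect_true("GO:0046677" %in% tree$children[["GO:0042221"]])
})

test_that("search is a case-insensitive substring match over names and synonyms", {
  mt <- motif_tree()
  hit <- search_tree(mt$tree, "toxic substance")
  expect_equal(hit$term, "GO:0009636")
  expect_equal(hit$cumulative_count, 3L)
  # case folding
  expect_equal(search_tree(mt$tree, "RESPONSE")$term,
               c("GO:0009636", "GO:0046677"))
  # synonym hit: "SH3 binding" is an exact synonym of GO:0017124
  expect_equal(search_tree(mt$tree, "sh3 binding")$term, "GO:0017124")
  # no match and empty query
  expect_equal(nrow(search_tree(mt$tree, "zzz-nothing")), 0)
  expect_error(search_tree(mt$tree, "   "), "non-empty")
})

test_that("every node's own name finds it", {
  mt <- motif_tree()
  for (i in seq_len(nrow(mt$tree$nodes))) {
    res <- search_tree(mt$tree, mt$tree$nodes$name[i])
    expect_true(mt$tree$nodes$term[i] %in% res$term)
  }
})

test_that("node protein sets match the inclusive-mapping containment oracle", {
  spec <- fixture_spec(seed = 104, n_terms = 40, n_proteins = 80, n_drugs = 0)
  b <- make_fixture_bundle(spec)
  g <- parse_obo(b$obo)
  ann <- parse_gaf(b$gaf, g)
  s <- slim_set(g, random_slim_terms(104, g, max_size = 8))
  tree <- build_target_tree(g, s, ann)
  m <- map_all(g, s, unique(ann$term))
  for (t in s$terms) {
    oracle <- sort(unique(ann$accession[
      map_lgl(ann$term, function(at) t %in% m$inclusive[[at]])
    ]))
    expect_equal(proteins_for_node(tree, t), oracle, info = t)
  }
  # parent cumulative count dominates every child's
  for (p in tree$nodes$term) {
    for (k in tree$children[[p]]) {
      expect_gte(tree$nodes$n_cumulative[tree$nodes$term == p],
                 tree$nodes$n_cumulative[tree$nodes$term == k])
    }
  }
})

test_that("tree export/import round-trips and is byte-stable", {
  mt <- motif_tree()
  json1 <- export_tree(mt$tree)
  json2 <- export_tree(mt$tree)
  expect_identical(json1, json2)
  back <- import_tree(json1)
  expect_equal(back$nodes, mt$tree$nodes)
  expect_equal(back$children, mt$tree$children)
  expect_equal(back$ns_roots, mt$tree$ns_roots)
  expect_equal(back$direct, mt$tree$direct)
  expect_equal(back$cumulative, mt$tree$cumulative)
  expect_identical(export_tree(back), json1)
})

test_that("an empty slim is rejected", {
  fx <- go_motif_fixture()
  g <- parse_obo(fx$obo)
  ann <- parse_gaf(fx$gaf, g)
  s <- slim_set(g, character(0))
  expect_error(build_target_tree(g, s, ann), "empty slim")
})
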