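# OBO parsing, validation, subset export and traversal primitives.

test_that("a minimal two-term file parses into one edge with the right root", {
  g <- parse_obo(paste(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: A", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: B", "namespace: biological_process",
    "is_a: GO:0000001", ""
  ), collapse = "\n"))
  expect_equal(nrow(g$terms), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$relation, "is_a")
  expect_equal(g$roots$biological_process, "GO:0000001")
})

test_that("the antibiotic/toxic-substance stanza yields the expected is_a edge", {
  g <- parse_obo(go_motif_fixture()$obo)
  e <- g$edges[g$edges$child == "GO:0046677", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$parent, "GO:0009636")
  expect_equal(e$relation, "is_a")
})

test_that("parser rejects cycles, missing ids, and names the problem", {
  cyc <- paste(c(
    "[Term]", "id: GO:0000001", "name: A", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "name: B", "namespace: biological_process",
    "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000003", "name: C", "namespace: biological_process",
    "is_a: GO:0000001", ""
  ), collapse = "\n")
  expect_error(parse_obo(cyc), "cyclic")

  no_id <- paste(c("[Term]", "name: A", "namespace: biological_process"),
                 collapse = "\n")
  expect_error(parse_obo(no_id), "missing id")
})

test_that("unknown tags warn in default mode and error in strict mode", {
  txt <- paste(c(
    "[Term]", "id: GO:0000001", "name: A", "namespace: biological_process",
    "made_up_tag: zzz", ""
  ), collapse = "\n")
  expect_warning(g <- parse_obo(txt), "made_up_tag")
  expect_equal(nrow(g$terms), 1)
  expect_error(parse_obo(txt, strict = TRUE), "made_up_tag")
})

test_that("obsolete terms keep replaced_by but lose all edges", {
  g <- parse_obo(go_motif_fixture()$obo)
  i <- match("GO:0016302", g$terms$id)
  expect_true(g$terms$is_obsolete[i])
  expect_equal(g$terms$replaced_by[i], "GO:0016301")
  expect_false("GO:0016302" %in% g$edges$child)
  expect_false("GO:0016302" %in% g$edges$parent)
})

test_that("ancestors follow the requested relations transitively", {
  g <- toy_graph()
  # chain D is_a C is_a B is_a A
  expect_equal(go_ancestors(g, toy_ids[["D"]], "is_a"),
               unname(toy_ids[c("A", "B", "C")]))
  # roots have no ancestors
  expect_equal(go_ancestors(g, toy_ids[["A"]]), character(0))
  # F: is_a-only misses the part_of leg; both relations pick it up
  expect_equal(go_ancestors(g, toy_ids[["F"]], "is_a"),
               unname(toy_ids[c("A", "B", "E")]))
  expect_equal(go_ancestors(g, toy_ids[["F"]], c("is_a", "part_of")),
               unname(toy_ids[c("A", "B", "C", "E")]))
  expect_error(go_ancestors(g, "GO:9999999"), "unknown term")
})

test_that("ancestors match the matrix-closure oracle on random DAGs", {
  for (seed in 1:25) {
    g <- parse_obo(random_dag_obo(seed))
    for (rels in list("is_a", c("is_a", "part_of"))) {
      R <- ancestors_closure_oracle(g, rels)
      for (t in g$terms$id) {
        expect_equal(go_ancestors(g, t, rels), sort(colnames(R)[R[t, ]]),
                     info = sprintf("seed %d term %s", seed, t))
      }
    }
  }
})

test_that("ancestors are monotone in the relation set", {
  for (seed in 26:40) {
    g <- parse_obo(random_dag_obo(seed))
    for (t in g$terms$id) {
      expect_true(all(go_ancestors(g, t, "is_a") %in%
                        go_ancestors(g, t, c("is_a", "part_of"))))
    }
  }
})

test_that("write_obo_subset of all terms round-trips to an isomorphic graph", {
  g <- parse_obo(go_motif_fixture()$obo)
  keep <- g$terms$id[!g$terms$is_obsolete]
  g2 <- parse_obo(write_obo_subset(g, keep))
  expect_equal(g2$terms$id, sort(keep))
  expect_equal(g2$terms$name, g$terms$name[match(g2$terms$id, g$terms$id)])
  expect_equal(g2$terms$namespace,
               g$terms$namespace[match(g2$terms$id, g$terms$id)])
  up <- function(gr) {
    e <- gr$edges[gr$edges$relation %in% c("is_a", "part_of"), ]
    e[order(e$child, e$relation, e$parent), ]
  }
  expect_equal(up(g2), up(g))
})

test_that("subset export contracts dropped intermediates to nearest kept ancestor", {
  g <- toy_graph()
  # chain A <- B <- C: keep {A, C} means C is_a A directly
  out <- write_obo_subset(g, c(toy_ids[["A"]], toy_ids[["C"]]))
  g2 <- parse_obo(out)
  expect_equal(g2$edges$child, toy_ids[["C"]])
  expect_equal(g2$edges$parent, toy_ids[["A"]])
  expect_equal(g2$edges$relation, "is_a")
  # subset tag present on every kept term
  expect_true(all(map_lgl(g2$terms$subsets,
                          function(s) "chembl_protein_target_slim" %in% s)))
})

test_that("a part_of-only path contracts to a part_of link", {
  g <- toy_graph()
  # F part_of C is_a B: keep {F, B} -> F relationship part_of ... via C is
  # mixed; keep {F, C} preserves the direct part_of edge
  g2 <- parse_obo(write_obo_subset(g, c(toy_ids[["F"]], toy_ids[["C"]])))
  expect_equal(g2$edges$relation, "part_of")
})

test_that("empty subsets and invalid keep sets are handled", {
  g <- toy_graph()
  empty <- write_obo_subset(g, character(0))
  g0 <- parse_obo(empty)
  expect_equal(nrow(g0$terms), 0)
  expect_error(write_obo_subset(g, "GO:9999999"), "unknown")
  gm <- parse_obo(go_motif_fixture()$obo)
  expect_error(write_obo_subset(gm, c("GO:0016301", "GO:0016302")), "obsolete")
})

test_that("subset export is deterministic and ordered by term id", {
  g <- parse_obo(go_motif_fixture()$obo)
  keep <- c("GO:0046677", "GO:0009636", "GO:0005515")
  expect_identical(write_obo_subset(g, keep), write_obo_subset(g, rev(keep)))
  ids <- regmatches(write_obo_subset(g, keep),
                    gregexpr("id: GO:[0-9]{7}", write_obo_subset(g, keep)))[[1]]
  expect_equal(ids, sort(ids))
})
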