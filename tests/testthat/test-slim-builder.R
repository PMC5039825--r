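# Coverage measurement, pruning, greedy suggestion, IC report, refinement.

toy_setup <- function(slim_terms = c(toy_ids[["B"]], toy_ids[["C"]])) {
  g <- toy_graph()
  list(g = g, s = slim_set(g, slim_terms), ann = parse_gaf(toy_gaf(), g))
}

test_that("coverage counts proteins reaching a non-root slim term", {
  ts <- toy_setup()
  rep <- slim_coverage(ts$g, ts$s, ts$ann)
  # P1 (D), P2 (F), P3 (E) all reach B or C inclusively
  expect_equal(rep$overall_coverage, 1)
  expect_equal(rep$unmapped, character(0))

  # slim of only the root A earns no coverage credit
  rep_root <- slim_coverage(ts$g, slim_set(ts$g, toy_ids[["A"]]), ts$ann)
  expect_equal(rep_root$overall_coverage, 0)
  expect_equal(length(rep_root$unmapped), 3)

  # slim covering 2 of 3 proteins: {C} reaches P1 (D is_a C) and P2 (part_of)
  rep_c <- slim_coverage(ts$g, slim_set(ts$g, toy_ids[["C"]]), ts$ann)
  expect_equal(rep_c$overall_coverage, 2 / 3)
  expect_equal(rep_c$unmapped, "P3")
  expect_error(slim_coverage(ts$g, ts$s, ts$ann, target = 1.5), "target")
})

test_that("zero-count slim terms are reported and pruned without coverage change", {
  ts <- toy_setup(c(toy_ids[["C"]], toy_ids[["D"]], toy_ids[["E"]]))
  # P2 -> F sits below C (part_of) and E (is_a), but not below D
  ann <- parse_gaf(gaf_text(gaf_line("P2", toy_ids[["F"]])), ts$g)
  rep <- slim_coverage(ts$g, ts$s, ann)
  expect_equal(rep$zero_count_terms, unname(toy_ids[["D"]]))
  pruned <- prune_zero_terms(ts$s, rep)
  expect_equal(pruned$terms, unname(sort(toy_ids[c("C", "E")])))
  rep2 <- slim_coverage(ts$g, pruned, ann)
  expect_identical(rep2$overall_coverage, rep$overall_coverage)
  expect_identical(rep2$per_namespace$coverage, rep$per_namespace$coverage)
  # mismatched report is rejected
  expect_error(prune_zero_terms(slim_set(ts$g, toy_ids[["B"]]), rep),
               "not computed against")
})

test_that("pruning an all-empty slim leaves an empty slim and zero coverage", {
  g <- toy_graph()
  ann <- parse_gaf(gaf_text(gaf_line("P1", toy_ids[["D"]])), g)
  s <- slim_set(g, toy_ids[["E"]])  # E is not on P1's path
  rep <- slim_coverage(g, s, ann)
  expect_equal(rep$overall_coverage, 0)
  pruned <- prune_zero_terms(s, rep)
  expect_equal(pruned$terms, character(0))
})

test_that("greedy suggestions prefer depth on gain ties and stop at target", {
  g <- toy_graph()
  ann <- parse_gaf(toy_gaf(), g)
  # slim {C} covers P1, P2; P3 (annotated to E) is uncovered.
  # Candidates gaining P3: E (depth 2) and B (depth 1) -> E wins by depth.
  sugg <- suggest_terms(g, slim_set(g, toy_ids[["C"]]), ann, target = 1)
  expect_equal(sugg$term[1], unname(toy_ids[["E"]]))
  expect_equal(sugg$gain[1], 1L)
  expect_equal(sugg$depth[1], 2L)
  expect_equal(nrow(sugg), 1)  # P3 covered; target reached

  # coverage already at target -> no suggestions
  s_full <- slim_set(g, c(toy_ids[["B"]], toy_ids[["C"]]))
  expect_equal(nrow(suggest_terms(g, s_full, ann, target = 0.9)), 0)
  expect_error(suggest_terms(g, s_full, ann, target = 2), "target")
})

test_that("disjoint uncovered branches yield one suggestion each", {
  g <- parse_obo(go_motif_fixture()$obo)
  # two proteins in different namespaces: no shared non-root ancestor
  ann <- parse_gaf(gaf_text(
    gaf_line("P1", "GO:0017124", aspect = "F"),
    gaf_line("P2", "GO:0046677", aspect = "P")
  ), g)
  sugg <- suggest_terms(g, slim_set(g, "GO:0005634"), ann, target = 1)
  expect_equal(nrow(sugg), 2)
  expect_equal(sugg$gain, c(1L, 1L))
  # gain ties break towards the deeper (more specific) term: the antibiotic
  # term sits 4 levels below its root, the SH3 term 3
  expect_equal(sugg$term, c("GO:0046677", "GO:0017124"))
  expect_equal(sugg$depth, c(4L, 3L))
})

test_that("information content follows -log2 of mapping frequency", {
  g <- toy_graph()
  s <- slim_set(g, c(toy_ids[["B"]], toy_ids[["C"]], toy_ids[["E"]]))
  # 8 proteins, exactly 1 below C (depth via D), all 8 below B
  rows <- c(
    gaf_line("P1", toy_ids[["D"]]),
    vapply(2:8, function(i) gaf_line(paste0("P", i), toy_ids[["E"]]), "")
  )
  ann <- parse_gaf(gaf_text(rows), g)
  ic <- information_report(g, s, ann, ic_threshold = 1)
  val <- function(term) ic$ic[ic$term == term]
  expect_equal(val(toy_ids[["B"]]), 0)            # all 8 proteins -> -log2(1)
  expect_equal(val(toy_ids[["C"]]), 3)            # 1 of 8 -> -log2(1/8)
  expect_true(ic$low_ic[ic$term == toy_ids[["B"]]])
  expect_false(toy_ids[["D"]] %in% ic$term)       # zero-count terms omitted
  # E collects 7 of 8 proteins: ic ~ 0.19, also below the 1-bit threshold
  expect_equal(attr(ic, "low_ic_terms"), unname(sort(toy_ids[c("B", "E")])))
  expect_error(information_report(g, s, ann, ic_threshold = -1), "non-negative")
})

test_that("refinement returns immediately when already at target", {
  ts <- toy_setup()
  res <- refine_slim(ts$g, ts$s, ts$ann, target = 0.9)
  expect_length(res$trail, 1)
  expect_equal(res$slim$terms, ts$s$terms)
})

test_that("one round applies exactly one prune plus one suggestion batch", {
  g <- toy_graph()
  ann <- parse_gaf(gaf_text(
    gaf_line("P1", toy_ids[["D"]]),
    gaf_line("P2", toy_ids[["E"]])
  ), g)
  # F has zero count (nothing annotated at/below it); P2 uncovered by {C,F}
  s0 <- slim_set(g, c(toy_ids[["C"]], toy_ids[["F"]]))
  res <- refine_slim(g, s0, ann, target = 1, max_rounds = 1)
  expect_length(res$trail, 2)
  expect_false(toy_ids[["F"]] %in% res$slim$terms)       # pruned
  expect_true(toy_ids[["E"]] %in% res$slim$terms)        # suggested
  expect_gte(res$trail[[2]]$overall_coverage,
             res$trail[[1]]$overall_coverage)
})

test_that("refinement reaches the target on a seeded synthetic benchmark", {
  spec <- fixture_spec(seed = 101, n_terms = 60, n_proteins = 150, n_drugs = 0)
  b <- make_fixture_bundle(spec)
  g <- parse_obo(b$obo)
  ann <- parse_gaf(b$gaf, g)
  starter <- slim_set(g, random_slim_terms(101, g, max_size = 5))
  res <- refine_slim(g, starter, ann, target = 0.9)
  final <- res$trail[[length(res$trail)]]
  expect_gte(final$overall_coverage, 0.9)
  cov <- vapply(res$trail, function(r) r$overall_coverage, 0)
  expect_true(all(diff(cov) >= 0))
})

test_that("adding a term never lowers coverage (monotonicity)", {
  spec <- fixture_spec(seed = 102, n_terms = 40, n_proteins = 80, n_drugs = 0)
  b <- make_fixture_bundle(spec)
  g <- parse_obo(b$obo)
  ann <- parse_gaf(b$gaf, g)
  s <- slim_set(g, random_slim_terms(102, g, max_size = 6))
  base <- slim_coverage(g, s, ann)$overall_coverage
  extra <- setdiff(g$terms$id, s$terms)
  withr::with_seed(102, extra <- sample(extra, 10))
  for (t in extra) {
    cov <- slim_coverage(g, slim_set(g, c(s$terms, t)), ann)$overall_coverage
    expect_gte(cov, base)
  }
})

test_that("summed greedy gains bound the realised coverage improvement", {
  spec <- fixture_spec(seed = 103, n_terms = 40, n_proteins = 80, n_drugs = 0)
  b <- make_fixture_bundle(spec)
  g <- parse_obo(b$obo)
  ann <- parse_gaf(b$gaf, g)
  s <- slim_set(g, random_slim_terms(103, g, max_size = 4))
  before <- slim_coverage(g, s, ann)
  sugg <- suggest_terms(g, s, ann, target = 1)
  after <- slim_coverage(g, slim_set(g, c(s$terms, sugg$term)), ann)
  expect_gte(sum(sugg$gain), after$n_covered - before$n_covered)
})
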