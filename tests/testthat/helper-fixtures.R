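suppressPackageStartupMessages({
  library(dplyr)
  library(purrr)
  library(withr)
})

# Shared fixtures: the six-term toy DAG used across the mapper tests, a
# random-DAG generator for property tests, and independent oracles
# (matrix-closure ancestors; igraph-reachability direct mapping; literal
# all-paths enumeration) that never touch the package's own traversal code.

# Toy DAG: A <- B <- C <- D (is_a chain), E is_a B, F is_a E, F part_of C.
# Ids: A=GO:0000001 ... F=GO:0000006, all biological_process.
toy_obo <- function() {
  paste(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: A", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: B", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: C", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: D", "namespace: biological_process",
    "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000005", "name: E", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000006", "name: F", "namespace: biological_process",
    "is_a: GO:0000005", "relationship: part_of GO:0000003", ""
  ), collapse = "\n")
}

toy_graph <- function() parse_obo(toy_obo())

toy_ids <- c(A = "GO:0000001", B = "GO:0000002", C = "GO:0000003",
             D = "GO:0000004", E = "GO:0000005", F = "GO:0000006")

gaf_line <- function(acc, term, aspect = "P", qualifier = "",
                     evidence = "IEA", taxon = 9606) {
  paste("DB", acc, acc, qualifier, term, "REF", evidence, "", aspect,
        acc, "", "protein", paste0("taxon:", taxon), "20160927", "src",
        "", "", sep = "\t")
}

gaf_text <- function(...) {
  paste(c("!gaf-version: 2.1", ...), collapse = "\n")
}

# P1 -> D, P2 -> F, P3 -> E (the worked count-mode example)
toy_gaf <- function() {
  gaf_text(
    gaf_line("P1", toy_ids[["D"]]),
    gaf_line("P2", toy_ids[["F"]]),
    gaf_line("P3", toy_ids[["E"]])
  )
}

# Random DAG as OBO text: n terms, every non-root picks 1..max_parents
# parents among earlier terms (acyclic by construction), each edge is_a
# with prob .8 else part_of.
random_dag_obo <- function(seed, n_min = 5, n_max = 50, max_parents = 3) {
  withr::with_seed(seed, {
    n <- sample(n_min:n_max, 1)
    stanzas <- character(0)
    for (i in seq_len(n)) {
      id <- sprintf("GO:%07d", i)
      stanza <- c("[Term]", paste0("id: ", id),
                  sprintf("name: term %d", i),
                  "namespace: biological_process")
      if (i > 1) {
        k <- sample(seq_len(min(max_parents, i - 1)), 1)
        ps <- sample(seq_len(i - 1), k)
        for (p in ps) {
          pid <- sprintf("GO:%07d", p)
          stanza <- c(stanza, if (stats::runif(1) < 0.8) {
            paste0("is_a: ", pid)
          } else {
            paste0("relationship: part_of ", pid)
          })
        }
      }
      stanzas <- c(stanzas, stanza, "")
    }
    paste(c("format-version: 1.2", "", stanzas), collapse = "\n")
  })
}

random_slim_terms <- function(seed, graph, max_size = 10) {
  withr::with_seed(seed + 13L, {
    ids <- graph$terms$id
    k <- sample(seq_len(min(max_size, length(ids))), 1)
    sample(ids, k)
  })
}

# Oracle 1: transitive closure by repeated squaring of the boolean
# adjacency matrix restricted to the allowed relations.
ancestors_closure_oracle <- function(graph, relations) {
  ids <- graph$terms$id
  n <- length(ids)
  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- graph$edges[graph$edges$relation %in% relations, ]
  if (nrow(e) > 0) M[cbind(e$child, e$parent)] <- TRUE
  R <- M
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# Oracle 2: direct slim mapping via igraph vertex-deletion reachability.
# t direct-maps to slim term s iff t can reach s in the graph where every
# OTHER slim term has been deleted (so no slim term sits strictly between).
direct_map_igraph_oracle <- function(graph, slim_terms, relations) {
  e <- graph$edges[graph$edges$relation %in% relations, ]
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$child, to = e$parent),
    vertices = data.frame(name = graph$terms$id), directed = TRUE
  )
  ids <- graph$terms$id
  res <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (s in slim_terms) {
    keepv <- setdiff(ids, setdiff(slim_terms, s))
    sg <- igraph::induced_subgraph(ig, keepv)
    d <- igraph::distances(sg, to = s, mode = "out")
    reach <- setdiff(rownames(d)[is.finite(d[, 1])], s)
    for (t in reach) res[[t]] <- c(res[[t]], s)
  }
  for (s in slim_terms) res[[s]] <- s
  lapply(res, function(v) sort(unique(v)))
}

# Oracle 3: literal enumeration of every directed path (tiny graphs only),
# applying the slim-free-interior rule exactly as stated.
direct_map_paths_oracle <- function(graph, slim_terms, relations, term) {
  if (term %in% slim_terms) return(term)
  e <- graph$edges[graph$edges$relation %in% relations, ]
  parents_of <- split(e$parent, e$child)
  hits <- character(0)
  walk <- function(node, interior) {
    for (p in parents_of[[node]]) {
      if (p %in% slim_terms) {
        if (!any(interior %in% slim_terms)) hits <<- c(hits, p)
        # a slim endpoint still extends as interior of longer paths
        walk(p, c(interior, p))
      } else {
        walk(p, c(interior, p))
      }
    }
  }
  walk(term, character(0))
  sort(unique(hits))
}

# Path to the installed CLI script (NULL when not available).
cli_script <- function() {
  p <- system.file("cli", "targetslim.R", package = "targetslim")
  if (nzchar(p)) p else NULL
}

run_cli <- function(args, ...) {
  out <- tempfile(); err <- tempfile()
  status <- system2("Rscript", c(shQuote(cli_script()), shQuote(args)),
                    stdout = out, stderr = err, ...)
  list(status = status,
       stdout = paste(readLines(out, warn = FALSE), collapse = "\n"),
       stderr = paste(readLines(err, warn = FALSE), collapse = "\n"))
}

write_motif_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fx <- go_motif_fixture()
  obo <- file.path(dir, "motif.obo")
  gaf <- file.path(dir, "motif.gaf")
  writeLines(fx$obo, obo)
  writeLines(fx$gaf, gaf)
  list(dir = dir, obo = obo, gaf = gaf)
}
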