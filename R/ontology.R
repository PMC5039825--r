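# OBO ontology parsing, validation, subset export and DAG traversal.

# Tags of an OBO 1.2 [Term] stanza this parser understands. Anything else is
# ignored with a warning (non-strict) or rejected (strict).
OBO_KNOWN_TAGS <- c(
  "id", "name", "namespace", "def", "comment", "synonym", "subset",
  "is_a", "relationship", "is_obsolete", "replaced_by", "consider",
  "alt_id", "xref", "created_by", "creation_date", "property_value"
)

new_ontology_graph <- function(terms, edges) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  terms <- arrange(terms, .data$id)
  edges <- arrange(edges, .data$child, .data$relation, .data$parent)
  g <- structure(
    list(terms = terms, edges = edges),
    class = "ontology_graph"
  )
  g$roots <- compute_roots(g)
  g
}

compute_roots <- function(graph) {
  up <- graph$edges[graph$edges$relation %in% c("is_a", "part_of"), ]
  active <- graph$terms[!graph$terms$is_obsolete, ]
  root_ids <- setdiff(active$id, unique(up$child))
  split(root_ids, active$namespace[match(root_ids, active$id)])
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "<ontology_graph> %d terms (%d obsolete), %d edges\n",
    nrow(x$terms), sum(x$terms$is_obsolete), nrow(x$edges)
  ))
  ns <- table(x$terms$namespace[!x$terms$is_obsolete])
  for (n in names(ns)) cat(sprintf("  %s: %d terms\n", n, ns[[n]]))
  invisible(x)
}

#' Parse an OBO 1.2 ontology
#'
#' Reads `[Term]` stanzas into an ontology graph: a term table, a typed edge
#' table (child, relation, parent) and per-namespace roots. `is_a` and
#' `relationship:` lines become edges; obsolete terms are retained in the
#' term table but stripped of outgoing edges so they are never traversed.
#' The graph is validated to be acyclic under `is_a`/`part_of`.
#'
#' @param x Path to an OBO file, a single string of OBO text, or a connection.
#' @param strict If `TRUE`, unknown stanza tags and edges to undeclared terms
#'   are errors; if `FALSE` (default) they are dropped with a warning.
#' @return An `ontology_graph`: list with `terms` (tibble: id, name,
#'   namespace, definition, is_obsolete, replaced_by, synonyms, subsets),
#'   `edges` (tibble: child, relation, parent) and `roots` (per-namespace
#'   term ids with no `is_a`/`part_of` parents).
#' @examples
#' g <- parse_obo(go_motif_fixture()$obo)
#' g
#' @export
parse_obo <- function(x, strict = FALSE) {
  lines <- read_input_lines(x)
  lines <- sub("\r$", "", lines)

  # stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  term_rows <- list()
  edge_rows <- list()
  unknown_tags <- character(0)

  for (si in seq_along(stanza_starts)) {
    start <- stanza_starts[si]
    end <- if (si < length(stanza_starts)) stanza_starts[si + 1] - 1 else length(lines)
    if (lines[start] != "[Term]") next
    body <- lines[(start + 1):end]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    if (length(body) == 0) next

    tag_split <- regmatches(body, regexpr(": ", body), invert = TRUE)
    tags <- vapply(tag_split, `[`, "", 1)
    vals <- vapply(tag_split, function(p) if (length(p) > 1) p[2] else "", "")
    # strip trailing OBO comments ("! text") from value lines
    vals <- sub("\\s*!.*$", "", vals)

    unk <- setdiff(unique(tags), OBO_KNOWN_TAGS)
    if (length(unk) > 0) {
      if (strict) {
        abort(sprintf(
          "unknown OBO tag(s) in stanza near line %d: %s",
          start, paste(unk, collapse = ", ")
        ))
      }
      unknown_tags <- union(unknown_tags, unk)
      keepers <- tags %in% OBO_KNOWN_TAGS
      tags <- tags[keepers]
      vals <- vals[keepers]
    }

    id <- vals[tags == "id"][1]
    if (is.na(id) || !nzchar(id)) {
      abort(sprintf("malformed [Term] stanza near line %d: missing id", start))
    }

    syn_raw <- vals[tags == "synonym"]
    synonyms <- stringr::str_match(syn_raw, '^"(.*)"')[, 2]
    synonyms <- synonyms[!is.na(synonyms)]

    obsolete <- any(tags == "is_obsolete" & vals == "true")

    term_rows[[length(term_rows) + 1]] <- list(
      id = id,
      name = vals[tags == "name"][1] %||% NA_character_,
      namespace = vals[tags == "namespace"][1] %||% NA_character_,
      definition = {
        d <- vals[tags == "def"][1]
        if (is.na(d)) "" else {
          m <- stringr::str_match(d, '^"(.*)"')[, 2]
          if (is.na(m)) d else m
        }
      },
      is_obsolete = obsolete,
      replaced_by = vals[tags == "replaced_by"][1] %||% NA_character_,
      synonyms = list(synonyms),
      subsets = list(vals[tags == "subset"])
    )

    if (!obsolete) {
      for (p in vals[tags == "is_a"]) {
        edge_rows[[length(edge_rows) + 1]] <- c(id, "is_a", trimws(p))
      }
      for (r in vals[tags == "relationship"]) {
        parts <- strsplit(trimws(r), "\\s+")[[1]]
        if (length(parts) < 2) {
          abort(sprintf("malformed relationship line in stanza near line %d: '%s'", start, r))
        }
        rel <- if (parts[1] %in% RELATION_LEVELS) parts[1] else "other"
        edge_rows[[length(edge_rows) + 1]] <- c(id, rel, parts[2])
      }
    }
  }

  if (length(unknown_tags) > 0) {
    warn(sprintf("ignored unknown OBO tag(s): %s", paste(unknown_tags, collapse = ", ")))
  }
  if (length(term_rows) == 0) {
    return(new_ontology_graph(empty_term_table(), empty_edge_table()))
  }

  terms <- bind_rows(lapply(term_rows, as_tibble))
  if (anyDuplicated(terms$id)) {
    abort(sprintf(
      "duplicate term id(s): %s",
      paste(unique(terms$id[duplicated(terms$id)]), collapse = ", ")
    ))
  }
  bad_name <- !terms$is_obsolete & (is.na(terms$name) | !nzchar(terms$name))
  if (any(bad_name)) {
    abort(sprintf(
      "non-obsolete term(s) without a name: %s",
      paste(terms$id[bad_name], collapse = ", ")
    ))
  }

  if (length(edge_rows) > 0) {
    em <- do.call(rbind, edge_rows)
    edges <- tibble(child = em[, 1], relation = em[, 2], parent = em[, 3])
  } else {
    edges <- empty_edge_table()
  }

  missing_parent <- !(edges$parent %in% terms$id)
  if (any(missing_parent)) {
    offenders <- unique(edges$parent[missing_parent])
    if (strict) {
      abort(sprintf("edge(s) to undeclared term(s): %s", paste(offenders, collapse = ", ")))
    }
    warn(sprintf(
      "dropped %d edge(s) to undeclared term(s): %s",
      sum(missing_parent), paste(utils::head(offenders, 5), collapse = ", ")
    ))
    edges <- edges[!missing_parent, ]
  }
  # edges out of obsolete parents' children are fine; edges INTO obsolete
  # parents are dropped (obsolete terms are edge-less islands)
  obs_ids <- terms$id[terms$is_obsolete]
  edges <- edges[!(edges$parent %in% obs_ids), ]
  edges <- distinct(edges)

  g <- new_ontology_graph(terms, edges)
  cyc <- find_cycle(g, c("is_a", "part_of"))
  if (!is.null(cyc)) {
    abort(sprintf(
      "ontology is cyclic under is_a/part_of: %s",
      paste(cyc, collapse = " -> ")
    ))
  }
  g
}

empty_term_table <- function() {
  tibble(
    id = character(), name = character(), namespace = character(),
    definition = character(), is_obsolete = logical(),
    replaced_by = character(), synonyms = list(), subsets = list()
  )
}

empty_edge_table <- function() {
  tibble(child = character(), relation = character(), parent = character())
}

# Kahn topological sort; returns NULL if acyclic, else one cycle as id path.
find_cycle <- function(graph, relations) {
  e <- graph$edges[graph$edges$relation %in% relations, ]
  ids <- graph$terms$id
  out_of <- split(e$parent, e$child)  # node -> its upward neighbours
  indeg <- rep(0L, length(ids)); names(indeg) <- ids
  tab <- table(e$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- ids[indeg == 0]
  seen <- 0L
  while (length(queue) > 0) {
    n <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (p in out_of[[n]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(ids)) return(NULL)
  # find a concrete cycle among remaining nodes by DFS
  remaining <- names(indeg)[indeg > 0]
  state <- new.env(parent = emptyenv())
  path <- character(0)
  cycle_found <- NULL
  visit <- function(n) {
    if (!is.null(cycle_found)) return()
    st <- state[[n]] %||% 0L
    if (st == 1L) {
      i <- match(n, path)
      cycle_found <<- c(path[i:length(path)], n)
      return()
    }
    if (st == 2L) return()
    state[[n]] <- 1L
    path <<- c(path, n)
    for (p in out_of[[n]]) visit(p)
    path <<- path[-length(path)]
    state[[n]] <- 2L
  }
  for (n in remaining) {
    visit(n)
    if (!is.null(cycle_found)) break
  }
  cycle_found %||% remaining
}

#' Ancestors of a term under a relation set
#'
#' All terms reachable from `term` by composing one or more edges whose
#' relation is in `relations`; the term itself is excluded.
#'
#' @param graph An `ontology_graph`.
#' @param term A term id.
#' @param relations Character vector of relation labels to traverse
#'   (default `is_a` + `part_of`).
#' @return Sorted character vector of ancestor term ids.
#' @examples
#' g <- parse_obo(go_motif_fixture()$obo)
#' go_ancestors(g, "GO:0017124")
#' @export
go_ancestors <- function(graph, term, relations = default_relations()) {
  lookup_term(graph, term)
  pm <- parent_map(graph, relations)
  sort(bfs_up(pm, term))
}

lookup_term <- function(graph, term, allow_obsolete = FALSE) {
  i <- match(term, graph$terms$id)
  if (is.na(i)) abort(sprintf("unknown term id: %s", term))
  if (!allow_obsolete && graph$terms$is_obsolete[i]) {
    abort(sprintf("term %s is obsolete", term))
  }
  invisible(i)
}

# Longest is_a/part_of path length from each term up to a root.
# Roots (no parents) have depth 0. Memoised DP over the DAG.
term_depths <- function(graph, relations = default_relations()) {
  pm <- parent_map(graph, relations)
  ids <- graph$terms$id
  depth <- rep(NA_integer_, length(ids)); names(depth) <- ids
  get_depth <- function(t) {
    d <- depth[[t]]
    if (!is.na(d)) return(d)
    ps <- pm[[t]]
    d <- if (is.null(ps) || length(ps) == 0) 0L else 1L + max(vapply(ps, get_depth, 0L))
    depth[[t]] <<- d
    d
  }
  for (t in ids) get_depth(t)
  depth
}

#' Write an OBO subset of an ontology
#'
#' Emits OBO 1.2 text containing exactly the terms in `keep`. Parent links
#' are rewritten to the nearest kept ancestor(s) under `is_a`/`part_of`:
#' dropped intermediate terms are skipped, so a chain A <- B <- C exported
#' with `keep = {A, C}` yields `C is_a A`. Every kept term is tagged with
#' `subset: <subset_name>`, and term stanzas are sorted by id so output is
#' reproducible byte for byte.
#'
#' @param graph An `ontology_graph`.
#' @param keep Character vector of term ids to retain (no obsolete terms).
#' @param subset_name Subset label written into `subsetdef`/`subset` tags.
#' @return A single string of OBO text.
#' @export
write_obo_subset <- function(graph, keep,
                             subset_name = "chembl_protein_target_slim") {
  keep <- unique(keep)
  unknown <- setdiff(keep, graph$terms$id)
  obs <- intersect(keep, graph$terms$id[graph$terms$is_obsolete])
  if (length(unknown) > 0 || length(obs) > 0) {
    abort(sprintf(
      "invalid subset: unknown term(s) [%s]; obsolete term(s) [%s]",
      paste(unknown, collapse = ", "), paste(obs, collapse = ", ")
    ))
  }

  keep <- sort(keep)
  pm_both <- parent_map(graph, c("is_a", "part_of"))
  pm_isa <- parent_map(graph, "is_a")
  keep_set <- stats::setNames(rep(TRUE, length(keep)), keep)

  out <- c(
    "format-version: 1.2",
    sprintf("subsetdef: %s \"%s\"", subset_name, subset_name),
    ""
  )
  trow <- graph$terms[match(keep, graph$terms$id), ]
  for (i in seq_along(keep)) {
    t <- keep[i]
    parents_all <- nearest_in_set(pm_both, t, keep_set)
    parents_isa <- intersect(nearest_in_set(pm_isa, t, keep_set), parents_all)
    parents_po <- setdiff(parents_all, parents_isa)
    stanza <- c(
      "[Term]",
      sprintf("id: %s", t),
      sprintf("name: %s", trow$name[i]),
      sprintf("namespace: %s", trow$namespace[i])
    )
    if (nzchar(trow$definition[i]) && !is.na(trow$definition[i])) {
      stanza <- c(stanza, sprintf("def: \"%s\" []", trow$definition[i]))
    }
    for (s in trow$synonyms[[i]]) {
      stanza <- c(stanza, sprintf("synonym: \"%s\" EXACT []", s))
    }
    stanza <- c(stanza, sprintf("subset: %s", subset_name))
    for (p in sort(parents_isa)) stanza <- c(stanza, sprintf("is_a: %s", p))
    for (p in sort(parents_po)) stanza <- c(stanza, sprintf("relationship: part_of %s", p))
    out <- c(out, stanza, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# Nearest members of `set` strictly above `t`: reachable by a path whose
# interior nodes are all outside `set` (path contraction over dropped terms).
nearest_in_set <- function(pm, t, set) {
  found <- character(0)
  visited <- character(0)
  frontier <- pm[[t]] %||% character(0)
  while (length(frontier) > 0) {
    in_set <- !is.na(set[frontier])
    found <- c(found, frontier[in_set])
    expand <- setdiff(frontier[!in_set], visited)
    visited <- c(visited, expand)
    frontier <- unique(unlist(pm[expand], use.names = FALSE))
    frontier <- setdiff(frontier, c(visited, found))
  }
  sort(unique(found))
}
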