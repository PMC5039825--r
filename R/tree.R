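# The browsable protein-target tree: slim-induced hierarchy with per-node
# protein counts, keyword search, and a deterministic text serialization.

#' Build the protein target tree
#'
#' Arranges the slim terms into a navigation hierarchy: slim term `p` is a
#' parent of slim term `s` when `p` is a slim ancestor of `s` with no other
#' slim term strictly in between (dropped GO intermediates are contracted
#' away). Slim terms with no slim ancestor hang off their namespace root
#' node. Each node carries the accessions whose annotations direct-map to it
#' and a cumulative set (node plus all slim descendants); displayed counts
#' are cumulative, so a parent's number includes its children's proteins,
#' counted once each. A slim term with several slim parents is rendered
#' under each of them with identical counts (a navigation tree cannot show
#' a DAG node once); the underlying protein sets are computed once and
#' shared.
#'
#' @param graph An `ontology_graph`.
#' @param slim A non-empty `slim_set`.
#' @param annotations An `annotation_set`.
#' @return A `target_tree`: list with `nodes` (tibble: term, name, namespace,
#'   n_direct, n_cumulative), `children` (named list, parent -> ordered child
#'   terms), `ns_roots` (named list, namespace -> top-level terms),
#'   `direct` / `cumulative` (named lists of accession vectors) and
#'   `synonyms` (named list, for search).
#' @examples
#' fx <- go_motif_fixture()
#' g <- parse_obo(fx$obo)
#' ann <- parse_gaf(fx$gaf, g)
#' tree <- build_target_tree(g, slim_set(g, c("GO:0009636", "GO:0046677")), ann)
#' search_tree(tree, "toxic substance")
#' @export
build_target_tree <- function(graph, slim, annotations) {
  if (length(slim$terms) == 0) abort("cannot build a tree from an empty slim")
  counts <- count_mode(graph, slim, annotations)
  direct <- attr(counts, "proteins_direct")

  pm <- parent_map(graph, slim$relations)
  keep_set <- stats::setNames(rep(TRUE, length(slim$terms)), slim$terms)
  parents_of <- lapply(stats::setNames(slim$terms, slim$terms), function(s) {
    ks <- keep_set
    ks <- ks[names(ks) != s]
    nearest_in_set(pm, s, ks)
  })

  children_of <- list()
  for (s in slim$terms) {
    for (p in parents_of[[s]]) {
      children_of[[p]] <- c(children_of[[p]], s)
    }
  }

  cumulative <- new.env(parent = emptyenv())
  cum_of <- function(s) {
    v <- cumulative[[s]]
    if (!is.null(v)) return(v)
    v <- sort(unique(c(
      direct[[s]],
      unlist(lapply(children_of[[s]], cum_of), use.names = FALSE)
    )))
    cumulative[[s]] <- v
    v
  }
  cum <- lapply(stats::setNames(slim$terms, slim$terms), cum_of)

  order_children <- function(kids) {
    if (length(kids) == 0) return(character(0))
    kids <- unique(kids)
    kids[order(-lengths(cum[kids]), kids)]
  }
  children_of <- lapply(stats::setNames(slim$terms, slim$terms), function(s) {
    order_children(children_of[[s]])
  })

  ti <- match(slim$terms, graph$terms$id)
  ns <- graph$terms$namespace[ti]
  top_level <- slim$terms[lengths(parents_of[slim$terms]) == 0]
  ns_roots <- lapply(
    stats::setNames(NAMESPACES, NAMESPACES),
    function(n) order_children(top_level[ns[match(top_level, slim$terms)] == n])
  )
  ns_roots <- ns_roots[lengths(ns_roots) > 0]

  nodes <- tibble(
    term = slim$terms,
    name = graph$terms$name[ti],
    namespace = ns,
    n_direct = unname(lengths(direct[slim$terms])),
    n_cumulative = unname(lengths(cum[slim$terms]))
  )

  structure(
    list(
      nodes = nodes,
      children = children_of,
      ns_roots = ns_roots,
      direct = direct[slim$terms],
      cumulative = cum,
      synonyms = stats::setNames(graph$terms$synonyms[ti], slim$terms)
    ),
    class = "target_tree"
  )
}

#' @export
print.target_tree <- function(x, max_depth = 3, ...) {
  cat(sprintf("<target_tree> %d slim terms across %d namespace(s)\n",
              nrow(x$nodes), length(x$ns_roots)))
  show <- function(term, indent, depth) {
    i <- match(term, x$nodes$term)
    cat(sprintf("%s%s %s (%d)\n", strrep("  ", indent), term,
                x$nodes$name[i], x$nodes$n_cumulative[i]))
    if (depth < max_depth) {
      for (k in x$children[[term]]) show(k, indent + 1, depth + 1)
    }
  }
  for (n in names(x$ns_roots)) {
    total <- length(unique(unlist(x$cumulative[x$ns_roots[[n]]], use.names = FALSE)))
    cat(sprintf("%s (%d)\n", n, total))
    for (k in x$ns_roots[[n]]) show(k, 1, 1)
  }
  invisible(x)
}

#' Search the target tree by keyword
#'
#' Case-insensitive substring match of the query against node names and
#' synonyms; e.g. the phrase "toxic substance" retrieves the node for
#' response to toxic substance together with its cumulative protein count.
#'
#' @param tree A `target_tree`.
#' @param query Search string (non-empty after trimming).
#' @return A tibble (term, name, cumulative_count), sorted by descending
#'   count then term id.
#' @export
search_tree <- function(tree, query) {
  query <- trimws(query)
  if (!nzchar(query)) abort("search query must be non-empty")
  q <- tolower(query)
  hay <- map2(tree$nodes$name, tree$synonyms[tree$nodes$term],
              function(n, s) tolower(c(n, s)))
  hit <- map_lgl(hay, function(h) any(grepl(q, h, fixed = TRUE)))
  out <- tibble(
    term = tree$nodes$term[hit],
    name = tree$nodes$name[hit],
    cumulative_count = tree$nodes$n_cumulative[hit]
  )
  arrange(out, desc(.data$cumulative_count), .data$term)
}

#' Proteins annotated at or below a tree node
#'
#' Returns the cumulative accession set of a node: proteins whose
#' annotations map to the term itself or to any of its slim descendants.
#' A namespace name ("biological_process", "molecular_function",
#' "cellular_component") returns every covered protein in that namespace.
#'
#' @param tree A `target_tree`.
#' @param term A slim term id present in the tree, or a namespace name.
#' @return Sorted character vector of accessions.
#' @export
proteins_for_node <- function(tree, term) {
  if (term %in% names(tree$ns_roots)) {
    return(sort(unique(unlist(tree$cumulative[tree$ns_roots[[term]]],
                              use.names = FALSE))))
  }
  if (!term %in% tree$nodes$term) {
    abort(sprintf("term %s is not in the tree", term))
  }
  tree$cumulative[[term]]
}

#' Serialize a target tree to JSON
#'
#' Deterministic nested serialization (term, name, count, direct proteins,
#' children, recursively) with one top-level entry per namespace. Node order
#' is the tree's display order, so repeated exports of the same tree are
#' byte-identical, and [import_tree()] reproduces an equal tree.
#'
#' @param tree A `target_tree`.
#' @return A single JSON string.
#' @export
export_tree <- function(tree) {
  node_json <- function(term) {
    i <- match(term, tree$nodes$term)
    list(
      term = term,
      name = tree$nodes$name[i],
      namespace = tree$nodes$namespace[i],
      count = tree$nodes$n_cumulative[i],
      proteins = as.list(tree$direct[[term]]),
      synonyms = as.list(tree$synonyms[[term]] %||% character(0)),
      children = lapply(tree$children[[term]], node_json)
    )
  }
  payload <- lapply(names(tree$ns_roots), function(n) {
    list(
      namespace = n,
      children = lapply(tree$ns_roots[[n]], node_json)
    )
  })
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE))
}

#' Reload a target tree from its JSON serialization
#'
#' @param x JSON text produced by [export_tree()] (string or file path).
#' @return A `target_tree` equal to the exported one.
#' @export
import_tree <- function(x) {
  txt <- paste(read_input_lines(x), collapse = "\n")
  payload <- jsonlite::fromJSON(txt, simplifyVector = FALSE)

  nodes <- new.env(parent = emptyenv())
  edges <- list()
  walk_node <- function(nd) {
    t <- nd$term
    if (is.null(nodes[[t]])) {
      nodes[[t]] <- list(
        term = t, name = nd$name, namespace = nd$namespace,
        direct = sort(unlist(nd$proteins, use.names = FALSE) %||% character(0)),
        synonyms = unlist(nd$synonyms, use.names = FALSE) %||% character(0)
      )
    }
    edges[[t]] <<- unique(c(edges[[t]] %||% character(0),
                            map_chr(nd$children, "term")))
    for (k in nd$children) walk_node(k)
  }
  ns_roots <- list()
  for (entry in payload) {
    ns_roots[[entry$namespace]] <- map_chr(entry$children, "term")
    for (k in entry$children) walk_node(k)
  }

  terms <- sort(ls(nodes))
  info <- lapply(stats::setNames(terms, terms), function(t) nodes[[t]])
  direct <- lapply(info, function(n) if (length(n$direct)) n$direct else character(0))
  children_of <- lapply(stats::setNames(terms, terms),
                        function(t) edges[[t]] %||% character(0))

  cumulative <- new.env(parent = emptyenv())
  cum_of <- function(s) {
    v <- cumulative[[s]]
    if (!is.null(v)) return(v)
    v <- sort(unique(c(
      direct[[s]],
      unlist(lapply(children_of[[s]], cum_of), use.names = FALSE)
    )))
    cumulative[[s]] <- v
    v
  }
  cum <- lapply(stats::setNames(terms, terms), cum_of)

  structure(
    list(
      nodes = tibble(
        term = terms,
        name = unname(map_chr(info, "name")),
        namespace = unname(map_chr(info, "namespace")),
        n_direct = unname(lengths(direct[terms])),
        n_cumulative = unname(lengths(cum[terms]))
      ),
      children = children_of,
      ns_roots = ns_roots,
      direct = direct,
      cumulative = cum,
      synonyms = lapply(info, function(n) n$synonyms)
    ),
    class = "target_tree"
  )
}

#' @export
#' @rdname build_target_tree
#' @param x A `target_tree`.
#' @param ... Unused.
#' @method tidy target_tree
tidy.target_tree <- function(x, ...) {
  as_tibble(x$nodes)
}
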