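# map2slim semantics: direct and inclusive slim mappings, and "count mode"
# protein tallies per slim term. This is the heart of the package.

#' Define a GO slim
#'
#' A slim is a named set of high-level terms together with the relation set
#' used to map annotations up to it.
#'
#' @param graph An `ontology_graph` the slim terms must belong to.
#' @param terms Character vector of slim term ids (non-obsolete).
#' @param name Slim name, used when exporting.
#' @param relations Relations traversed during mapping.
#' @return A `slim_set` (list with `name`, `terms`, `relations`).
#' @export
slim_set <- function(graph, terms, name = "slim",
                     relations = default_relations()) {
  terms <- unique(terms)
  unknown <- setdiff(terms, graph$terms$id)
  if (length(unknown) > 0) {
    abort(sprintf("slim term(s) not in ontology: %s", paste(unknown, collapse = ", ")))
  }
  obs <- intersect(terms, graph$terms$id[graph$terms$is_obsolete])
  if (length(obs) > 0) {
    abort(sprintf("obsolete term(s) not allowed in a slim: %s", paste(obs, collapse = ", ")))
  }
  structure(
    list(name = name, terms = sort(terms), relations = relations),
    class = "slim_set"
  )
}

#' @export
print.slim_set <- function(x, ...) {
  cat(sprintf("<slim_set> '%s': %d terms, relations {%s}\n",
              x$name, length(x$terms), paste(x$relations, collapse = ", ")))
  invisible(x)
}

#' Read a slim from a file
#'
#' Accepts either an OBO subset file (terms carrying the named `subset` tag,
#' or all terms when the tag is absent) or a plain-text list with one term id
#' per line and `#` comments.
#'
#' @param path File path.
#' @param graph An `ontology_graph` to validate against.
#' @param name Slim name.
#' @param relations Relations used for mapping.
#' @param subset_name For OBO input: keep only terms tagged with this subset
#'   label; `NULL` keeps every term in the file.
#' @return A `slim_set`.
#' @export
read_slim <- function(path, graph, name = "slim",
                      relations = default_relations(), subset_name = NULL) {
  lines <- read_input_lines(path)
  if (any(grepl("^\\[Term\\]", lines))) {
    sub_graph <- suppressWarnings(parse_obo(paste(lines, collapse = "\n")))
    ids <- sub_graph$terms$id[!sub_graph$terms$is_obsolete]
    if (!is.null(subset_name)) {
      tagged <- map_lgl(sub_graph$terms$subsets, function(s) subset_name %in% s)
      ids <- intersect(ids, sub_graph$terms$id[tagged])
    }
  } else {
    lines <- trimws(sub("#.*$", "", lines))
    ids <- lines[nzchar(lines)]
  }
  slim_set(graph, ids, name = name, relations = relations)
}

#' Map one term to its direct slim ancestors
#'
#' The map2slim direct mapping: a slim term in the slim maps to itself and is
#' never generalised further (an annotation to a granular slim member such as
#' SH3 domain binding stays there rather than collapsing into protein
#' binding). A non-slim term maps to every slim term reachable by a directed
#' path with no slim term strictly in between; terms with no slim ancestor
#' map to nothing. A term below several such slim terms keeps all of them.
#'
#' @param graph An `ontology_graph`.
#' @param slim A `slim_set`.
#' @param term A term id (must exist, non-obsolete).
#' @return Sorted character vector of slim term ids (possibly empty).
#' @examples
#' fx <- go_motif_fixture()
#' g <- parse_obo(fx$obo)
#' s <- slim_set(g, c("GO:0017124", "GO:0005515"))
#' map_term(g, s, "GO:0017124")  # stays at SH3 domain binding
#' @export
map_term <- function(graph, slim, term) {
  lookup_term(graph, term)
  pm <- parent_map(graph, slim$relations)
  direct_map_one(pm, slim$terms, term)
}

direct_map_one <- function(pm, slim_terms, term) {
  if (term %in% slim_terms) return(term)
  found <- character(0)
  visited <- character(0)
  frontier <- pm[[term]] %||% character(0)
  while (length(frontier) > 0) {
    hit <- frontier %in% slim_terms
    found <- c(found, frontier[hit])
    expand <- frontier[!hit]
    visited <- c(visited, expand)
    frontier <- unique(unlist(pm[expand], use.names = FALSE))
    frontier <- setdiff(frontier, c(visited, found))
  }
  sort(unique(found))
}

#' Map a set of terms to the slim
#'
#' Computes, for every input term, both the direct mapping (see
#' [map_term()]) and the inclusive mapping: all slim terms among the term
#' itself and its ancestors under the slim's relation set.
#'
#' @param graph An `ontology_graph`.
#' @param slim A `slim_set`.
#' @param terms Character vector of term ids.
#' @return A `slim_mapping`: list with `direct` and `inclusive`, each a named
#'   list term id -> character vector of slim term ids.
#' @export
map_all <- function(graph, slim, terms) {
  terms <- unique(terms)
  for (t in terms) lookup_term(graph, t)
  pm <- parent_map(graph, slim$relations)
  anc_cache <- new.env(parent = emptyenv())
  anc_of <- function(t) {
    a <- anc_cache[[t]]
    if (!is.null(a)) return(a)
    ps <- pm[[t]] %||% character(0)
    a <- if (length(ps) == 0) character(0) else {
      sort(unique(c(ps, unlist(lapply(ps, anc_of), use.names = FALSE))))
    }
    anc_cache[[t]] <- a
    a
  }
  direct <- lapply(stats::setNames(terms, terms), function(t) direct_map_one(pm, slim$terms, t))
  inclusive <- lapply(stats::setNames(terms, terms), function(t) {
    sort(intersect(slim$terms, c(t, anc_of(t))))
  })
  structure(list(direct = direct, inclusive = inclusive), class = "slim_mapping")
}

#' Tally proteins per slim term ("count mode")
#'
#' For every slim term, counts the distinct proteins having at least one
#' annotation whose direct (respectively inclusive) slim mapping contains the
#' term. Slim terms no protein maps to are reported with count 0; annotations
#' whose term has no slim ancestor contribute to no slim term but are
#' tracked for coverage reporting downstream.
#'
#' @param graph An `ontology_graph`.
#' @param slim A `slim_set`.
#' @param annotations An `annotation_set` from [parse_gaf()].
#' @return A `slim_counts` object: tibble with columns term, name, namespace,
#'   n_direct, n_inclusive (one row per slim term, sorted by id), carrying
#'   the per-term protein sets and the set of accessions with no slim mapping
#'   as attributes `proteins_direct`, `proteins_inclusive` and `unmapped`.
#' @examples
#' fx <- go_motif_fixture()
#' g <- parse_obo(fx$obo)
#' ann <- parse_gaf(fx$gaf, g)
#' s <- slim_set(g, c("GO:0009636", "GO:0005515"))
#' count_mode(g, s, ann)
#' @export
count_mode <- function(graph, slim, annotations) {
  uterms <- unique(annotations$term)
  mapping <- map_all(graph, slim, uterms)

  prot_sets <- function(maps) {
    # maps: named list annotation term -> slim terms; invert to slim term ->
    # distinct accessions
    pairs <- tibble(
      term = annotations$term,
      accession = annotations$accession
    )
    hits <- tibble(
      term = as.character(rep(names(maps), lengths(maps))),
      slim_term = unlist(maps, use.names = FALSE) %||% character(0)
    )
    joined <- inner_join(pairs, hits, by = "term",
                         relationship = "many-to-many")
    sets <- joined |>
      distinct(.data$slim_term, .data$accession) |>
      summarise(accs = list(sort(.data$accession)), .by = "slim_term")
    out <- stats::setNames(vector("list", length(slim$terms)), slim$terms)
    for (t in slim$terms) out[[t]] <- character(0)
    out[sets$slim_term] <- sets$accs
    out
  }

  direct_sets <- prot_sets(mapping$direct)
  inclusive_sets <- prot_sets(mapping$inclusive)

  mapped_any <- unique(unlist(inclusive_sets, use.names = FALSE))
  unmapped <- sort(setdiff(unique(annotations$accession), mapped_any))

  ti <- match(slim$terms, graph$terms$id)
  counts <- tibble(
    term = slim$terms,
    name = graph$terms$name[ti],
    namespace = graph$terms$namespace[ti],
    n_direct = unname(lengths(direct_sets)[slim$terms]),
    n_inclusive = unname(lengths(inclusive_sets)[slim$terms])
  ) |> arrange(.data$term)

  structure(
    counts,
    proteins_direct = direct_sets,
    proteins_inclusive = inclusive_sets,
    unmapped = unmapped,
    class = c("slim_counts", class(counts))
  )
}

#' @export
#' @rdname count_mode
#' @param x A `slim_counts` object.
#' @param ... Unused.
#' @method tidy slim_counts
tidy.slim_counts <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "proteins_direct") <- NULL
  attr(out, "proteins_inclusive") <- NULL
  attr(out, "unmapped") <- NULL
  out
}

#' Bar chart of protein counts per slim term
#'
#' @param object A `slim_counts` object.
#' @param top_n How many slim terms to show (by inclusive count).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot slim_counts
autoplot.slim_counts <- function(object, top_n = 20, ...) {
  df <- tidy.slim_counts(object) |>
    arrange(desc(.data$n_inclusive)) |>
    utils::head(top_n) |>
    tidyr::pivot_longer(c("n_direct", "n_inclusive"),
                        names_to = "mode", values_to = "n_proteins") |>
    mutate(mode = sub("^n_", "", .data$mode))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(paste(.data$term, .data$name), .data$n_proteins),
    y = .data$n_proteins, fill = .data$mode
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "distinct proteins", fill = NULL) +
    ggplot2::theme_minimal()
}
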