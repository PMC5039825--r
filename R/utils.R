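# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_lgl map2 imap keep
NULL

TERM_ID_PATTERN <- "^GO:[0-9]{7}$"

RELATION_LEVELS <- c(
  "is_a", "part_of", "regulates",
  "positively_regulates", "negatively_regulates", "other"
)

NAMESPACES <- c("biological_process", "molecular_function", "cellular_component")

#' Default relation set used for slim traversal
#'
#' Slimming follows `is_a` and `part_of` edges; the regulates family is
#' parsed but excluded from traversal unless explicitly requested.
#'
#' @return Character vector of relation labels.
#' @export
default_relations <- function() c("is_a", "part_of")

is_term_id <- function(x) {
  is.character(x) & grepl(TERM_ID_PATTERN, x)
}

assert_term_ids <- function(x, what = "term") {
  bad <- x[!is_term_id(x)]
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s identifier(s): %s (expected 'GO:' + 7 digits)",
      what, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  invisible(x)
}

# Reads lines from a path, a literal multi-line string, or a connection.
read_input_lines <- function(x) {
  if (inherits(x, "connection")) {
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x) && length(x) == 1 && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

# Named list child -> character vector of parents, restricted to relations.
parent_map <- function(graph, relations) {
  e <- graph$edges
  e <- e[e$relation %in% relations, , drop = FALSE]
  if (nrow(e) == 0) {
    return(structure(list(), names = character()))
  }
  split(e$parent, factor(e$child, levels = unique(e$child)))
}

# Breadth-first upward closure from `start` (excluded) over a parent map.
bfs_up <- function(pm, start) {
  seen <- character(0)
  frontier <- unique(unlist(pm[start], use.names = FALSE))
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(pm[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  unique(seen)
}
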