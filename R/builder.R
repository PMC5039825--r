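# Slim construction: coverage measurement, zero-term pruning, greedy term
# suggestion, information-content screening, and the round-based refinement
# loop that drives a slim towards a target coverage.

#' Measure slim coverage of an annotated protein set
#'
#' A protein counts as covered when at least one of its annotations has a
#' non-empty inclusive slim mapping to a non-root slim term. Mapping every
#' protein to a namespace root would trivially give full coverage with zero
#' information, so roots never earn coverage credit. Coverage is reported
#' both per namespace (over proteins annotated in that namespace) and
#' overall (over distinct annotated accessions).
#'
#' @param graph An `ontology_graph`.
#' @param slim A `slim_set`.
#' @param annotations An `annotation_set`.
#' @param target Target coverage fraction in `[0, 1]` (default 0.90), carried
#'   into the report for comparison.
#' @return A `coverage_report`: list with `target_coverage`,
#'   `overall_coverage`, `n_proteins`, `n_covered`, `per_namespace` (tibble),
#'   `unmapped` (uncovered accessions), `zero_count_terms` (slim terms with
#'   inclusive count 0) and `counts` (the [count_mode()] tally).
#' @export
slim_coverage <- function(graph, slim, annotations, target = 0.9) {
  if (!is.numeric(target) || length(target) != 1 || is.na(target) ||
      target < 0 || target > 1) {
    abort("target coverage must be a single number in [0, 1]")
  }
  counts <- count_mode(graph, slim, annotations)
  inc_sets <- attr(counts, "proteins_inclusive")
  roots <- unlist(graph$roots, use.names = FALSE)
  credit_terms <- setdiff(slim$terms, roots)

  annotated <- unique(annotations$accession)
  covered <- sort(unique(unlist(inc_sets[credit_terms], use.names = FALSE)))
  covered <- intersect(covered, annotated)

  ns_of_slim <- graph$terms$namespace[match(slim$terms, graph$terms$id)]
  ann_ns <- graph$terms$namespace[match(annotations$term, graph$terms$id)]
  per_ns <- lapply(NAMESPACES, function(ns) {
    in_ns <- unique(annotations$accession[!is.na(ann_ns) & ann_ns == ns])
    ns_credit <- credit_terms[ns_of_slim[match(credit_terms, slim$terms)] == ns]
    ns_cov <- unique(unlist(inc_sets[ns_credit], use.names = FALSE))
    n_cov <- length(intersect(ns_cov, in_ns))
    tibble(
      namespace = ns,
      n_proteins = length(in_ns),
      n_covered = n_cov,
      coverage = if (length(in_ns) == 0) 0 else n_cov / length(in_ns)
    )
  })

  structure(
    list(
      target_coverage = target,
      n_proteins = length(annotated),
      n_covered = length(covered),
      overall_coverage = if (length(annotated) == 0) 0 else length(covered) / length(annotated),
      per_namespace = bind_rows(per_ns),
      unmapped = sort(setdiff(annotated, covered)),
      zero_count_terms = counts$term[counts$n_inclusive == 0],
      counts = counts
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> overall %.1f%% (%d/%d proteins; target %.0f%%)\n",
    100 * x$overall_coverage, x$n_covered, x$n_proteins,
    100 * x$target_coverage
  ))
  for (i in seq_len(nrow(x$per_namespace))) {
    r <- x$per_namespace[i, ]
    cat(sprintf("  %s: %.1f%% (%d/%d)\n", r$namespace, 100 * r$coverage,
                r$n_covered, r$n_proteins))
  }
  cat(sprintf("  %d uncovered accession(s), %d zero-count slim term(s)\n",
              length(x$unmapped), length(x$zero_count_terms)))
  invisible(x)
}

#' @export
#' @rdname slim_coverage
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @method tidy coverage_report
tidy.coverage_report <- function(x, ...) {
  bind_rows(
    x$per_namespace,
    tibble(namespace = "overall", n_proteins = x$n_proteins,
           n_covered = x$n_covered, coverage = x$overall_coverage)
  )
}

#' @export
#' @rdname slim_coverage
#' @method glance coverage_report
glance.coverage_report <- function(x, ...) {
  tibble(
    n_proteins = x$n_proteins,
    n_covered = x$n_covered,
    overall_coverage = x$overall_coverage,
    target_coverage = x$target_coverage,
    n_slim_terms = nrow(x$counts),
    n_zero_count_terms = length(x$zero_count_terms),
    at_target = x$overall_coverage >= x$target_coverage
  )
}

#' Coverage bar chart per namespace
#'
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot coverage_report
autoplot.coverage_report <- function(object, ...) {
  df <- tidy.coverage_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$namespace, y = .data$coverage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$target_coverage, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "protein coverage") +
    ggplot2::theme_minimal()
}

#' Drop slim terms that tally no proteins
#'
#' Removes the slim terms whose inclusive count is zero; since they covered
#' nobody, coverage is unchanged.
#'
#' @param slim A `slim_set`.
#' @param report A `coverage_report` computed against `slim`.
#' @return A `slim_set` without the zero-count terms.
#' @export
prune_zero_terms <- function(slim, report) {
  if (!setequal(report$counts$term, slim$terms)) {
    abort("coverage report was not computed against this slim")
  }
  keep <- setdiff(slim$terms, report$zero_count_terms)
  structure(
    list(name = slim$name, terms = sort(keep), relations = slim$relations),
    class = "slim_set"
  )
}

# For every term that could be added to a slim, the distinct proteins whose
# annotations sit at or below it (i.e. would inclusively map to it).
proteins_under_terms <- function(graph, relations, annotations) {
  pm <- parent_map(graph, relations)
  uterms <- unique(annotations$term)
  prot_by_term <- lapply(
    split(annotations$accession, annotations$term),
    unique
  )
  acc <- new.env(parent = emptyenv())
  for (t in uterms) {
    targets <- c(t, bfs_up(pm, t))
    for (a in targets) {
      acc[[a]] <- c(acc[[a]], prot_by_term[[t]])
    }
  }
  out <- as.list(acc)
  lapply(out, function(v) sort(unique(v)))
}

#' Suggest high-yield slim additions
#'
#' Greedy selection of terms to add: repeatedly picks the non-slim, non-root,
#' non-obsolete term that would cover the most currently-uncovered proteins
#' (via inclusive mapping after a hypothetical addition), committing each
#' pick before the next. Ties break towards the deeper term (longest
#' `is_a`/`part_of` path to a root — prefer the more specific, information-
#' richer candidate), then the smaller term id. Stops once coverage reaches
#' `target`, no candidate gains a protein, or `max_suggestions` picks.
#'
#' @param graph An `ontology_graph`.
#' @param slim A `slim_set`.
#' @param annotations An `annotation_set`.
#' @param target Target coverage fraction in `[0, 1]`.
#' @param max_suggestions Maximum number of terms to suggest (default
#'   unlimited).
#' @return A tibble of suggestions in pick order: term, name, namespace,
#'   gain (uncovered proteins newly covered), depth,
#'   n_descendant_terms_absorbed (annotated terms that would map into it).
#' @export
suggest_terms <- function(graph, slim, annotations, target = 0.9,
                          max_suggestions = Inf) {
  if (!is.numeric(target) || length(target) != 1 || is.na(target) ||
      target < 0 || target > 1) {
    abort("target coverage must be a single number in [0, 1]")
  }
  report <- slim_coverage(graph, slim, annotations, target)
  unmapped <- report$unmapped
  n_total <- report$n_proteins

  roots <- unlist(graph$roots, use.names = FALSE)
  p_under <- proteins_under_terms(graph, slim$relations, annotations)
  candidates <- setdiff(names(p_under), c(slim$terms, roots))
  candidates <- setdiff(candidates, graph$terms$id[graph$terms$is_obsolete])
  depths <- term_depths(graph, slim$relations)

  # annotated terms mapping into each candidate, for the absorbed-terms count
  uterms <- unique(annotations$term)
  pm <- parent_map(graph, slim$relations)
  absorbed <- new.env(parent = emptyenv())
  for (t in uterms) {
    for (a in c(t, bfs_up(pm, t))) absorbed[[a]] <- (absorbed[[a]] %||% 0L) + 1L
  }

  picks <- list()
  covered_n <- n_total - length(unmapped)
  while (length(picks) < max_suggestions &&
         (n_total == 0 || covered_n / n_total < target)) {
    if (length(candidates) == 0 || length(unmapped) == 0) break
    gains <- vapply(candidates, function(cand) {
      length(intersect(p_under[[cand]], unmapped))
    }, 0L)
    best_gain <- max(gains)
    if (best_gain < 1) break
    top <- candidates[gains == best_gain]
    top <- top[order(-depths[top], top)]
    pick <- top[[1]]
    picks[[length(picks) + 1]] <- tibble(
      term = pick,
      gain = best_gain,
      depth = as.integer(depths[[pick]]),
      n_descendant_terms_absorbed = absorbed[[pick]]
    )
    newly <- intersect(p_under[[pick]], unmapped)
    unmapped <- setdiff(unmapped, newly)
    covered_n <- covered_n + length(newly)
    candidates <- setdiff(candidates, pick)
  }

  out <- if (length(picks) == 0) {
    tibble(term = character(), gain = integer(), depth = integer(),
           n_descendant_terms_absorbed = integer())
  } else {
    bind_rows(picks)
  }
  ti <- match(out$term, graph$terms$id)
  out$name <- graph$terms$name[ti]
  out$namespace <- graph$terms$namespace[ti]
  select(out, "term", "name", "namespace", "gain", "depth",
         "n_descendant_terms_absorbed")
}

#' Information content of slim terms
#'
#' For each slim term with at least one inclusively mapped protein, reports
#' `ic = -log2(f)` where `f` is the fraction of annotated proteins mapping
#' to the term. A term every protein maps to has ic 0; terms below the
#' caller's threshold are flagged as overly generic — the cue to keep the
#' granular children (e.g. SH3 domain binding) in the slim rather than
#' collapsing everything into a catch-all parent (protein binding).
#' Zero-count terms are omitted.
#'
#' @param graph An `ontology_graph`.
#' @param slim A `slim_set`.
#' @param annotations An `annotation_set`.
#' @param ic_threshold Non-negative flagging threshold in bits.
#' @return An `information_report` tibble: term, name, namespace,
#'   n_proteins, ic, low_ic; attribute `low_ic_terms`.
#' @export
information_report <- function(graph, slim, annotations, ic_threshold = 1) {
  if (!is.numeric(ic_threshold) || ic_threshold < 0) {
    abort("ic_threshold must be a non-negative number")
  }
  counts <- count_mode(graph, slim, annotations)
  n_total <- n_distinct(annotations$accession)
  per <- as_tibble(counts) |>
    filter(.data$n_inclusive > 0) |>
    mutate(
      ic = -log2(.data$n_inclusive / n_total),
      low_ic = .data$ic < ic_threshold
    ) |>
    select("term", "name", "namespace", n_proteins = "n_inclusive",
           "ic", "low_ic")
  structure(
    per,
    low_ic_terms = per$term[per$low_ic],
    ic_threshold = ic_threshold,
    class = c("information_report", class(per))
  )
}

#' Refine a slim towards a coverage target
#'
#' Automates the manual addition/removal loop used when tailoring a slim to
#' a protein set: each round first prunes slim terms with no proteins, then
#' commits greedy term suggestions, stopping when coverage reaches the
#' target, a round changes nothing, or `max_rounds` is exhausted.
#'
#' @param graph An `ontology_graph`.
#' @param slim0 Starting `slim_set`.
#' @param annotations An `annotation_set`.
#' @param target Target overall coverage fraction (default 0.90).
#' @param max_rounds Maximum refinement rounds (default 10).
#' @param max_suggestions_per_round Cap on greedy additions per round.
#' @return A `slim_refinement`: list with `slim` (final `slim_set`) and
#'   `trail` (list of `coverage_report`, one before refinement plus one per
#'   round).
#' @export
refine_slim <- function(graph, slim0, annotations, target = 0.9,
                        max_rounds = 10, max_suggestions_per_round = Inf) {
  if (max_rounds < 1) abort("max_rounds must be >= 1")
  slim <- slim0
  rep <- slim_coverage(graph, slim, annotations, target)
  trail <- list(rep)
  round <- 0
  while (round < max_rounds && rep$overall_coverage < target) {
    round <- round + 1
    pruned <- prune_zero_terms(slim, rep)
    sugg <- suggest_terms(graph, pruned, annotations, target,
                          max_suggestions_per_round)
    new_terms <- sort(union(pruned$terms, sugg$term))
    if (setequal(new_terms, slim$terms)) break
    slim <- structure(
      list(name = slim$name, terms = new_terms, relations = slim$relations),
      class = "slim_set"
    )
    rep <- slim_coverage(graph, slim, annotations, target)
    trail <- c(trail, list(rep))
  }
  structure(list(slim = slim, trail = trail), class = "slim_refinement")
}

#' @export
print.slim_refinement <- function(x, ...) {
  final <- x$trail[[length(x$trail)]]
  cat(sprintf(
    "<slim_refinement> %d round(s): %d slim terms, overall coverage %.1f%% (target %.0f%%)\n",
    length(x$trail) - 1, length(x$slim$terms),
    100 * final$overall_coverage, 100 * final$target_coverage
  ))
  invisible(x)
}

#' @export
#' @rdname refine_slim
#' @param x A `slim_refinement`.
#' @param ... Unused.
#' @method tidy slim_refinement
tidy.slim_refinement <- function(x, ...) {
  tibble(
    round = seq_along(x$trail) - 1L,
    n_slim_terms = map_int(x$trail, function(r) nrow(r$counts)),
    n_zero_count_terms = map_int(x$trail, function(r) length(r$zero_count_terms)),
    coverage = vapply(x$trail, function(r) r$overall_coverage, 0)
  )
}

#' @export
#' @rdname refine_slim
#' @method glance slim_refinement
glance.slim_refinement <- function(x, ...) {
  final <- x$trail[[length(x$trail)]]
  tibble(
    n_rounds = length(x$trail) - 1L,
    n_slim_terms = length(x$slim$terms),
    final_coverage = final$overall_coverage,
    target_coverage = final$target_coverage,
    reached_target = final$overall_coverage >= final$target_coverage
  )
}

#' Coverage trajectory across refinement rounds
#'
#' @param object A `slim_refinement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot slim_refinement
autoplot.slim_refinement <- function(object, ...) {
  df <- tidy.slim_refinement(object)
  tgt <- object$trail[[1]]$target_coverage
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = tgt, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "refinement round", y = "overall coverage") +
    ggplot2::theme_minimal()
}
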