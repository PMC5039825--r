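# Linking drugs to GO slim categories of their mechanism-of-action targets:
# ATC-class target retrieval, Venn-style category membership counts, and
# mechanism breakdowns.

ATC_LEVEL_LENGTHS <- c(1L, 3L, 4L, 5L, 7L)

#' Read the drug, mechanism and target tables
#'
#' The three flat inputs of the drug-link analysis: drugs
#' (`drug_id`, `name`, pipe-separated `atc_codes`), mechanisms (`drug_id`,
#' `accession`, `action`), and targets (`accession`, `taxid`, `organism`).
#' All are tab-separated with a single header row.
#'
#' @param path File path, literal text, or connection.
#' @return A tibble; for drugs, `atc_codes` is a list-column of uppercase
#'   code vectors.
#' @export
read_drug_table <- function(path) {
  df <- readr::read_tsv(I(paste0(paste(read_input_lines(path), collapse = "\n"), "\n")),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("drug_id", "name", "atc_codes")
  if (!all(need %in% names(df))) {
    abort(sprintf("drug table must have columns: %s", paste(need, collapse = ", ")))
  }
  df$atc_codes <- map(strsplit(df$atc_codes, "|", fixed = TRUE),
                      function(x) toupper(x[nzchar(x)]))
  df
}

#' @rdname read_drug_table
#' @export
read_mechanism_table <- function(path) {
  df <- readr::read_tsv(I(paste0(paste(read_input_lines(path), collapse = "\n"), "\n")),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("drug_id", "accession", "action")
  if (!all(need %in% names(df))) {
    abort(sprintf("mechanism table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(!nzchar(df$drug_id)) || any(!nzchar(df$accession))) {
    abort("mechanism rows must have non-empty drug_id and accession")
  }
  df
}

#' @rdname read_drug_table
#' @export
read_target_table <- function(path) {
  df <- readr::read_tsv(I(paste0(paste(read_input_lines(path), collapse = "\n"), "\n")),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("accession", "taxid", "organism")
  if (!all(need %in% names(df))) {
    abort(sprintf("target table must have columns: %s", paste(need, collapse = ", ")))
  }
  df$taxid <- as.integer(df$taxid)
  df
}

validate_atc_prefix <- function(atc_prefix) {
  if (!is.character(atc_prefix) || length(atc_prefix) != 1 ||
      is.na(atc_prefix) || !nzchar(atc_prefix)) {
    abort("atc_prefix must be a single non-empty string")
  }
  if (!nchar(atc_prefix) %in% ATC_LEVEL_LENGTHS) {
    abort(sprintf(
      "atc_prefix length %d does not match an ATC level boundary (1, 3, 4, 5 or 7 characters)",
      nchar(atc_prefix)
    ))
  }
  toupper(atc_prefix)
}

#' Mechanism-of-action targets of drugs in an ATC class
#'
#' Accessions of mechanism targets of every drug holding at least one ATC
#' code that starts with `atc_prefix`. The prefix must sit on an ATC level
#' boundary (1, 3, 4, 5 or 7 characters), e.g. "L" for antineoplastic and
#' immunomodulating agents or "P01" for antiprotozoals — "L0" is rejected.
#'
#' @param drugs A drug tibble from [read_drug_table()].
#' @param mechanisms A mechanism tibble from [read_mechanism_table()].
#' @param atc_prefix ATC code prefix at a level boundary.
#' @return Sorted character vector of target accessions.
#' @export
targets_for_atc <- function(drugs, mechanisms, atc_prefix) {
  atc_prefix <- validate_atc_prefix(atc_prefix)
  in_class <- map_lgl(drugs$atc_codes, function(codes) {
    any(startsWith(codes, atc_prefix))
  })
  ids <- drugs$drug_id[in_class]
  sort(unique(mechanisms$accession[mechanisms$drug_id %in% ids]))
}

#' Drug membership across GO slim categories
#'
#' For a chosen set of slim categories (e.g. five biological-process terms),
#' computes which categories each drug's mechanism targets fall into: a
#' target covers a category when the category appears in the inclusive slim
#' mapping of at least one of its annotations, and a drug's covered set is
#' the union over its mechanism targets (restricted to `target_accessions`).
#' Region counts are standard disjoint Venn counts — each drug is counted
#' once, in the region of its exact covered set — so the central region of a
#' five-category diagram counts the drugs whose targets span all five.
#'
#' @param target_accessions Accessions to consider (e.g. from
#'   [targets_for_atc()]).
#' @param annotations An `annotation_set`.
#' @param graph An `ontology_graph`.
#' @param slim A `slim_set`.
#' @param categories Character vector of slim term ids to use as categories.
#' @param mechanisms A mechanism tibble.
#' @return A `category_membership`: list with `categories`, `per_target`
#'   (named list accession -> covered categories), `per_drug` (named list
#'   drug -> covered categories; drugs covering nothing are dropped) and
#'   `per_region` (tibble: region as "+"-joined sorted category ids,
#'   category_names, n_drugs).
#' @export
category_membership <- function(target_accessions, annotations, graph, slim,
                                categories, mechanisms) {
  categories <- unique(categories)
  missing_cat <- setdiff(categories, slim$terms)
  if (length(missing_cat) > 0) {
    abort(sprintf("category term(s) not in the slim: %s",
                  paste(missing_cat, collapse = ", ")))
  }

  ann <- annotations[annotations$accession %in% target_accessions, ]
  mapping <- map_all(graph, slim, unique(ann$term))
  per_target <- lapply(
    split(ann$term, ann$accession),
    function(ts) {
      sort(intersect(
        categories,
        unique(unlist(mapping$inclusive[unique(ts)], use.names = FALSE))
      ))
    }
  )

  mech <- mechanisms[mechanisms$accession %in% target_accessions, ]
  per_drug <- lapply(
    split(mech$accession, mech$drug_id),
    function(accs) {
      sort(unique(unlist(per_target[unique(accs)], use.names = FALSE)))
    }
  )
  per_drug <- per_drug[lengths(per_drug) > 0]

  region_key <- map_chr(per_drug, paste, collapse = "+")
  reg <- tibble(region = region_key) |>
    count(.data$region, name = "n_drugs") |>
    arrange(desc(.data$n_drugs), .data$region)
  name_of <- stats::setNames(graph$terms$name[match(categories, graph$terms$id)],
                             categories)
  reg$category_names <- map_chr(strsplit(reg$region, "+", fixed = TRUE),
                                function(ts) paste(name_of[ts], collapse = "+"))

  structure(
    list(
      categories = sort(categories),
      per_target = per_target,
      per_drug = per_drug,
      per_region = select(reg, "region", "category_names", "n_drugs")
    ),
    class = "category_membership"
  )
}

#' @export
print.category_membership <- function(x, ...) {
  cat(sprintf(
    "<category_membership> %d categories, %d drug(s) with >=1 covered category\n",
    length(x$categories), length(x$per_drug)
  ))
  print(x$per_region, n = 10)
  invisible(x)
}

#' @export
#' @rdname category_membership
#' @param x A `category_membership`.
#' @param ... Unused.
#' @method tidy category_membership
tidy.category_membership <- function(x, ...) {
  x$per_region
}

#' @export
#' @rdname category_membership
#' @method glance category_membership
glance.category_membership <- function(x, ...) {
  all_key <- paste(x$categories, collapse = "+")
  n_all <- x$per_region$n_drugs[x$per_region$region == all_key]
  tibble(
    n_categories = length(x$categories),
    n_drugs_categorized = length(x$per_drug),
    n_regions = nrow(x$per_region),
    n_drugs_in_all_categories = if (length(n_all)) n_all else 0L
  )
}

#' Venn-region bar chart of drug category membership
#'
#' @param object A `category_membership`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot category_membership
autoplot.category_membership <- function(object, ...) {
  df <- object$per_region
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$region, .data$n_drugs), y = .data$n_drugs
  )) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "category region", y = "drugs") +
    ggplot2::theme_minimal()
}

#' Mechanism-of-action breakdown of a drug set
#'
#' Distinct drugs per mechanism action label among the given drugs; a drug
#' with two recorded actions counts once under each. Drugs absent from the
#' mechanism table contribute nothing (a message notes how many).
#'
#' @param drug_ids Character vector of drug ids.
#' @param mechanisms A mechanism tibble.
#' @return A tibble (action, n_drugs), sorted by descending count then
#'   action.
#' @export
mechanism_breakdown <- function(drug_ids, mechanisms) {
  drug_ids <- unique(drug_ids)
  mech <- mechanisms[mechanisms$drug_id %in% drug_ids, ]
  absent <- setdiff(drug_ids, mech$drug_id)
  if (length(absent) > 0) {
    inform(sprintf("%d drug(s) have no mechanism records", length(absent)))
  }
  mech |>
    distinct(.data$drug_id, .data$action) |>
    count(.data$action, name = "n_drugs") |>
    arrange(desc(.data$n_drugs), .data$action)
}
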