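# GAF 2.1/2.2 annotation parsing, filtering and summary statistics.

GAF_COLUMNS <- c(
  "db", "accession", "symbol", "qualifier", "term", "reference",
  "evidence", "with_from", "aspect", "name", "synonym", "type",
  "taxon", "date", "assigned_by", "extension", "gene_product_form"
)

#' Parse a GAF annotation file
#'
#' Reads GAF 2.1 or 2.2 (17 tab-separated columns, `!`-prefixed comment
#' lines) into a tibble of annotations, applying the standard slimming
#' filters: rows whose qualifier contains `NOT` are dropped (negative
#' assertions must not contribute to slim counts), rows failing an optional
#' evidence-code whitelist are dropped, annotations to obsolete terms are
#' redirected via `replaced_by` when possible, and exact duplicates on
#' (accession, qualifiers, term, evidence, taxon) are collapsed. Protein
#' identity is the column-2 accession alone.
#'
#' @param x Path to a GAF file, a single string of GAF text, or a connection.
#' @param graph An `ontology_graph` used to validate terms.
#' @param drop_not Drop rows with a `NOT` qualifier (default `TRUE`).
#' @param evidence_whitelist Optional character vector of evidence codes to
#'   keep; `NULL` (default) keeps all evidence codes.
#' @param remap_obsolete Redirect annotations to obsolete terms through
#'   `replaced_by` when a replacement exists (default `TRUE`); terms without
#'   a replacement are dropped with a warning.
#' @param strict If `TRUE`, an annotation to a term absent from `graph` is
#'   an error; otherwise it is dropped with a warning.
#' @return An `annotation_set`: tibble with columns db, accession, symbol,
#'   qualifiers (list of character), term, evidence, aspect, taxon (integer),
#'   date, assigned_by, plus a `provenance` attribute.
#' @examples
#' fx <- go_motif_fixture()
#' g <- parse_obo(fx$obo)
#' ann <- parse_gaf(fx$gaf, g)
#' ann
#' @export
parse_gaf <- function(x, graph, drop_not = TRUE, evidence_whitelist = NULL,
                      remap_obsolete = TRUE, strict = FALSE) {
  lines <- read_input_lines(x)
  lines <- sub("\r$", "", lines)
  src <- if (is.character(x) && length(x) == 1 && !grepl("\n", x, fixed = TRUE) &&
             file.exists(x)) x else "<text>"
  data_idx <- which(nzchar(lines) & !startsWith(lines, "!"))

  if (length(data_idx) == 0) {
    ann <- empty_annotation_set()
    return(finish_annotation_set(ann, src, drop_not, evidence_whitelist))
  }

  # sentinel keeps trailing empty columns from being dropped by strsplit
  fields <- strsplit(paste0(lines[data_idx], "\tEND"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  nf <- lengths(fields)
  bad <- which(nf != 17)
  if (length(bad) > 0) {
    abort(sprintf(
      "GAF line %d has %d columns, expected 17",
      data_idx[bad[1]], nf[bad[1]]
    ))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- GAF_COLUMNS
  ann <- as_tibble(m)

  if (any(!nzchar(ann$accession))) {
    abort("GAF record with empty accession (column 2)")
  }

  ann <- mutate(
    ann,
    qualifiers = map(strsplit(.data$qualifier, "|", fixed = TRUE),
                     function(q) q[nzchar(q)]),
    taxon = as.integer(sub("^taxon:", "", sub("\\|.*$", "", .data$taxon)))
  )

  if (drop_not) {
    ann <- ann[!map_lgl(ann$qualifiers, function(q) "NOT" %in% q), ]
  }
  if (!is.null(evidence_whitelist)) {
    ann <- ann[ann$evidence %in% evidence_whitelist, ]
  }

  # term validation against the ontology
  i <- match(ann$term, graph$terms$id)
  unknown <- is.na(i)
  if (any(unknown)) {
    offenders <- unique(ann$term[unknown])
    if (strict) {
      abort(sprintf("annotation(s) to unknown term(s): %s",
                    paste(offenders, collapse = ", ")))
    }
    warn(sprintf("dropped %d annotation(s) to unknown term(s): %s",
                 sum(unknown), paste(utils::head(offenders, 5), collapse = ", ")))
    ann <- ann[!unknown, ]
    i <- i[!unknown]
  }

  obs <- graph$terms$is_obsolete[i]
  if (any(obs)) {
    repl <- graph$terms$replaced_by[i]
    if (remap_obsolete) {
      can_fix <- obs & !is.na(repl) & repl %in% graph$terms$id
      ann$term[can_fix] <- repl[can_fix]
      dead <- obs & !can_fix
    } else {
      dead <- obs
    }
    if (any(dead)) {
      warn(sprintf("dropped %d annotation(s) to obsolete term(s) without replacement: %s",
                   sum(dead),
                   paste(utils::head(unique(ann$term[dead]), 5), collapse = ", ")))
    }
    ann <- ann[!dead, ]
  }

  # aspect letters that disagree with the term namespace: keep, but log
  ns <- graph$terms$namespace[match(ann$term, graph$terms$id)]
  expected <- c(biological_process = "P", molecular_function = "F",
                cellular_component = "C")[ns]
  mismatch <- !is.na(expected) & ann$aspect != expected
  if (any(mismatch)) {
    inform(sprintf("%d annotation(s) have an aspect letter disagreeing with the term namespace (kept)",
                   sum(mismatch)))
  }

  # collapse exact duplicates on the identity key
  key <- paste(
    ann$accession,
    map_chr(ann$qualifiers, function(q) paste(sort(q), collapse = "|")),
    ann$term, ann$evidence, ann$taxon,
    sep = "\r"
  )
  ann <- ann[!duplicated(key), ]
  ann <- select(ann, -"qualifier")
  finish_annotation_set(ann, src, drop_not, evidence_whitelist)
}

empty_annotation_set <- function() {
  tibble(
    db = character(), accession = character(), symbol = character(),
    term = character(), reference = character(), evidence = character(),
    with_from = character(), aspect = character(), name = character(),
    synonym = character(), type = character(), taxon = integer(),
    date = character(), assigned_by = character(), extension = character(),
    gene_product_form = character(), qualifiers = list()
  )
}

finish_annotation_set <- function(ann, src, drop_not, evidence_whitelist) {
  ann <- arrange(ann, .data$accession, .data$term, .data$evidence)
  attr(ann, "provenance") <- list(
    source = src,
    drop_not = drop_not,
    evidence_whitelist = evidence_whitelist
  )
  class(ann) <- c("annotation_set", class(ann))
  ann
}

#' Write annotations back out as GAF 2.1 text
#'
#' Inverse of [parse_gaf()] for fixture round-trips; emits the same
#' 17-column dialect with a `!gaf-version: 2.1` header.
#'
#' @param annotations An `annotation_set`.
#' @return A single string of GAF text.
#' @export
write_gaf <- function(annotations) {
  a <- annotations
  rows <- paste(
    a$db, a$accession, a$symbol,
    map_chr(a$qualifiers, paste, collapse = "|"),
    a$term, a$reference, a$evidence, a$with_from, a$aspect,
    a$name, a$synonym, a$type, paste0("taxon:", a$taxon),
    a$date, a$assigned_by, a$extension, a$gene_product_form,
    sep = "\t"
  )
  paste0(paste(c("!gaf-version: 2.1", rows), collapse = "\n"), "\n")
}

#' Summarise an annotation set
#'
#' Headline counts for an annotation set: distinct proteins, distinct terms,
#' total annotation records, and distinct proteins per NCBI taxon (the
#' per-species protein tally).
#'
#' @param annotations An `annotation_set`.
#' @return A list of class `annotation_summary` with `n_proteins`, `n_terms`,
#'   `n_annotations`, `n_proteins_with_annotation` and `per_taxon` (tibble:
#'   taxon, n_proteins, sorted by descending count).
#' @examples
#' fx <- go_motif_fixture()
#' g <- parse_obo(fx$obo)
#' summarize_annotations(parse_gaf(fx$gaf, g))
#' @export
summarize_annotations <- function(annotations) {
  per_taxon <- annotations |>
    as_tibble() |>
    distinct(.data$taxon, .data$accession) |>
    count(.data$taxon, name = "n_proteins") |>
    arrange(desc(.data$n_proteins), .data$taxon)
  structure(
    list(
      n_proteins = n_distinct(annotations$accession),
      n_terms = n_distinct(annotations$term),
      n_annotations = nrow(annotations),
      n_proteins_with_annotation = n_distinct(annotations$accession),
      per_taxon = per_taxon
    ),
    class = "annotation_summary"
  )
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf(
    "<annotation_summary> %d annotations | %d proteins | %d terms\n",
    x$n_annotations, x$n_proteins, x$n_terms
  ))
  if (nrow(x$per_taxon) > 0) {
    cat("  proteins per taxon:\n")
    for (i in seq_len(min(10, nrow(x$per_taxon)))) {
      cat(sprintf("    taxon %d: %d\n", x$per_taxon$taxon[i], x$per_taxon$n_proteins[i]))
    }
  }
  invisible(x)
}

#' @export
#' @rdname summarize_annotations
#' @param x An `annotation_summary`.
#' @param ... Unused.
#' @method glance annotation_summary
glance.annotation_summary <- function(x, ...) {
  tibble(
    n_proteins = x$n_proteins,
    n_terms = x$n_terms,
    n_annotations = x$n_annotations,
    n_taxa = nrow(x$per_taxon)
  )
}
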