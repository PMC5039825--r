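# Seeded generators for synthetic ontologies, GAF annotation files and drug
# tables, plus a small hand-written fixture holding the classic worked
# motifs (SH3 domain binding under protein binding; response to antibiotic
# under response to toxic substance). Everything downstream is testable
# from these without any external download.

MECHANISM_ACTIONS <- c(
  "protein kinase inhibitor", "growth factor receptor inhibitor",
  "receptor antagonist", "receptor agonist", "enzyme inhibitor",
  "ion channel blocker"
)

#' Specify a synthetic fixture
#'
#' Collects the knobs of the synthetic-data generators in one validated
#' object. The defaults describe the benchmark conditions used throughout
#' the package: 200 terms per namespace in a DAG of depth up to 8, 1000
#' proteins averaging 5 annotations each with a specificity bias towards
#' leaf terms, a species mix echoing the dominance of human/rat/mouse
#' targets in curated drug-target sets, and 50 drugs with on average 2
#' mechanism targets each. The same spec and seed always reproduce
#' byte-identical outputs.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_terms Terms per namespace (including the namespace root).
#' @param max_depth Maximum depth of generated terms.
#' @param branching Mean children per term (> 0 when `n_terms` > 1).
#' @param multiparent_fraction Fraction of non-root terms given a second
#'   parent (an extra `is_a` or `part_of` edge to another lower-depth term).
#' @param n_proteins Number of annotated proteins.
#' @param annotations_per_protein Mean annotations per protein (Poisson,
#'   minimum 1).
#' @param specificity_bias Probability an annotation goes to a leaf term
#'   rather than an arbitrary non-root term.
#' @param taxa Named numeric vector: NCBI taxid -> sampling weight.
#' @param n_drugs Number of drugs.
#' @param targets_per_drug Mean mechanism targets per drug (minimum 1).
#' @param atc_classes Named numeric vector: ATC class prefix -> weight.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_terms = 200L,
                         max_depth = 8L,
                         branching = 2.5,
                         multiparent_fraction = 0.15,
                         n_proteins = 1000L,
                         annotations_per_protein = 5,
                         specificity_bias = 0.7,
                         taxa = c("9606" = 0.55, "10116" = 0.16,
                                  "10090" = 0.15, "9913" = 0.08,
                                  "4932" = 0.06),
                         n_drugs = 50L,
                         targets_per_drug = 2,
                         atc_classes = c(L = 0.5, N = 0.2, C = 0.15,
                                         J = 0.1, P = 0.05)) {
  stopifnot(
    n_terms >= 1, max_depth >= 1, n_proteins >= 0,
    annotations_per_protein >= 1, n_drugs >= 0, targets_per_drug >= 1
  )
  if (multiparent_fraction < 0 || multiparent_fraction > 1 ||
      specificity_bias < 0 || specificity_bias > 1) {
    abort("fractions must lie in [0, 1]")
  }
  if (branching <= 0 && n_terms > 1 && max_depth > 1) {
    abort("branching must be > 0 to place more than one term below a root")
  }
  structure(
    list(
      seed = as.integer(seed), n_terms = as.integer(n_terms),
      max_depth = as.integer(max_depth), branching = branching,
      multiparent_fraction = multiparent_fraction,
      n_proteins = as.integer(n_proteins),
      annotations_per_protein = annotations_per_protein,
      specificity_bias = specificity_bias, taxa = taxa,
      n_drugs = as.integer(n_drugs), targets_per_drug = targets_per_drug,
      atc_classes = atc_classes
    ),
    class = "fixture_spec"
  )
}

# Synthetic term ids use a reserved "GO:9" + 6 digit block so they can never
# collide with the real ids used in the hand-written motif fixture.
synthetic_id <- function(k) sprintf("GO:9%06d", k)

#' Generate a synthetic OBO ontology
#'
#' One DAG per namespace: a root, then terms layered to `max_depth` with on
#' average `branching` children per term, each non-root term getting one
#' `is_a` parent in the layer above and, for a `multiparent_fraction` of
#' terms, a second `is_a` or `part_of` parent at any shallower layer (so the
#' graph stays acyclic by construction).
#'
#' @param spec A `fixture_spec`.
#' @return A single string of OBO 1.2 text.
#' @export
make_ontology <- function(spec) {
  withr::with_seed(spec$seed, make_ontology_impl(spec))
}

make_ontology_impl <- function(spec) {
  ns_short <- c(biological_process = "bp", molecular_function = "mf",
                cellular_component = "cc")
  stanzas <- character(0)
  counter <- 0L
  for (ns in NAMESPACES) {
    ids <- synthetic_id(counter + seq_len(spec$n_terms))
    counter <- counter + spec$n_terms
    depth <- integer(spec$n_terms)
    depth[1] <- 0L
    # layer sizes grow geometrically with `branching`, clipped at max_depth
    placed <- 1L
    level_members <- list(`0` = 1L)
    d <- 0L
    size_d <- 1L
    while (placed < spec$n_terms) {
      d <- d + 1L
      remaining <- spec$n_terms - placed
      size_next <- if (d >= spec$max_depth) remaining else
        min(remaining, max(1L, round(size_d * spec$branching)))
      idx <- placed + seq_len(size_next)
      depth[idx] <- d
      level_members[[as.character(d)]] <- idx
      placed <- placed + size_next
      size_d <- size_next
    }

    parents <- vector("list", spec$n_terms)
    for (i in seq_len(spec$n_terms)[-1]) {
      cand <- level_members[[as.character(depth[i] - 1L)]]
      p1 <- if (length(cand) == 1) cand else sample(cand, 1)
      parents[[i]] <- list(c("is_a", ids[p1]))
      if (depth[i] > 0 && stats::runif(1) < spec$multiparent_fraction) {
        shallower <- which(depth < depth[i])
        shallower <- setdiff(shallower, p1)
        if (length(shallower) > 0) {
          p2 <- if (length(shallower) == 1) shallower else sample(shallower, 1)
          rel <- if (stats::runif(1) < 0.5) "is_a" else "part_of"
          parents[[i]] <- c(parents[[i]], list(c(rel, ids[p2])))
        }
      }
    }

    for (i in seq_len(spec$n_terms)) {
      nm <- if (i == 1) ns else
        sprintf("synthetic %s term %06d", ns_short[[ns]], i)
      stanza <- c(
        "[Term]",
        sprintf("id: %s", ids[i]),
        sprintf("name: %s", nm),
        sprintf("namespace: %s", ns)
      )
      for (p in parents[[i]]) {
        stanza <- c(stanza, if (p[1] == "is_a") {
          sprintf("is_a: %s", p[2])
        } else {
          sprintf("relationship: %s %s", p[1], p[2])
        })
      }
      stanzas <- c(stanzas, stanza, "")
    }
  }
  paste0(paste(c("format-version: 1.2", "", stanzas), collapse = "\n"), "\n")
}

#' Generate a synthetic GAF annotation file
#'
#' Proteins `P000001`, `P000002`, ... each get a Poisson number of
#' annotations (minimum 1) to non-root terms, drawn from leaf terms with
#' probability `specificity_bias` and from any non-root term otherwise.
#' Each protein belongs to one taxon, sampled by weight.
#'
#' @param spec A `fixture_spec`.
#' @param graph The `ontology_graph` parsed from [make_ontology()] output
#'   (or any compatible graph).
#' @return A single string of GAF 2.1 text.
#' @export
make_gaf <- function(spec, graph) {
  withr::with_seed(spec$seed + 1L, make_gaf_impl(spec, graph))
}

make_gaf_impl <- function(spec, graph) {
  header <- "!gaf-version: 2.1"
  if (spec$n_proteins == 0) return(paste0(header, "\n"))

  active <- graph$terms[!graph$terms$is_obsolete, ]
  roots <- unlist(graph$roots, use.names = FALSE)
  non_root <- setdiff(active$id, roots)
  if (length(non_root) == 0) {
    abort("graph has no non-root terms to annotate")
  }
  leaves <- setdiff(non_root, unique(graph$edges$parent))
  if (length(leaves) == 0) leaves <- non_root
  aspect_of <- c(biological_process = "P", molecular_function = "F",
                 cellular_component = "C")
  ns_by_id <- stats::setNames(active$namespace, active$id)
  evidence_pool <- c("IEA", "IDA", "ISS", "TAS", "EXP")

  rows <- character(0)
  taxids <- names(spec$taxa)
  for (i in seq_len(spec$n_proteins)) {
    acc <- sprintf("P%06d", i)
    taxon <- if (length(taxids) == 1) taxids else
      sample(taxids, 1, prob = spec$taxa)
    k <- stats::rpois(1, spec$annotations_per_protein - 1) + 1L
    use_leaf <- stats::runif(k) < spec$specificity_bias
    terms <- character(k)
    terms[use_leaf] <- sample(leaves, sum(use_leaf), replace = TRUE)
    terms[!use_leaf] <- sample(non_root, sum(!use_leaf), replace = TRUE)
    terms <- unique(terms)
    ev <- sample(evidence_pool, length(terms), replace = TRUE)
    rows <- c(rows, paste(
      "UniProtKB", acc, acc, "", terms, "GO_REF:0000002", ev, "",
      aspect_of[ns_by_id[terms]], acc, "", "protein",
      paste0("taxon:", taxon), "20160927", "targetslim", "", "",
      sep = "\t"
    ))
  }
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Generate synthetic drug, mechanism and target tables
#'
#' Each drug gets at least one ATC code sampled by class weight (completed
#' to a full 7-character level-5 code) and a Poisson number (minimum 1) of
#' mechanism targets drawn from `accessions`, with action labels from a
#' small fixed vocabulary including "protein kinase inhibitor". The target
#' table assigns each accession a taxon by the fixture's taxon weights.
#'
#' @param spec A `fixture_spec`.
#' @param accessions Non-empty character vector of target accessions when
#'   `n_drugs` >= 1.
#' @return A list of three single-string TSV tables: `drugs`, `mechanisms`,
#'   `targets`.
#' @export
make_drug_tables <- function(spec, accessions) {
  if (spec$n_drugs >= 1 && length(accessions) == 0) {
    abort("accessions must be non-empty when n_drugs >= 1")
  }
  withr::with_seed(spec$seed + 2L, make_drug_tables_impl(spec, accessions))
}

make_drug_tables_impl <- function(spec, accessions) {
  drug_header <- "drug_id\tname\tatc_codes"
  mech_header <- "drug_id\taccession\taction"
  targ_header <- "accession\ttaxid\torganism"
  organisms <- c("9606" = "Homo sapiens", "10116" = "Rattus norvegicus",
                 "10090" = "Mus musculus", "9913" = "Bos taurus",
                 "4932" = "Saccharomyces cerevisiae")

  if (spec$n_drugs == 0) {
    return(list(
      drugs = paste0(drug_header, "\n"),
      mechanisms = paste0(mech_header, "\n"),
      targets = paste0(targ_header, "\n")
    ))
  }

  full_code <- function(prefix) {
    # complete a class prefix to a level-5 code: L -> L01XE01 style
    code <- prefix
    if (nchar(code) < 3) code <- paste0(code, sprintf("%02d", sample(1:16, 1)))
    if (nchar(code) < 4) code <- paste0(code, sample(LETTERS, 1))
    if (nchar(code) < 5) code <- paste0(code, sample(LETTERS, 1))
    if (nchar(code) < 7) code <- paste0(code, sprintf("%02d", sample(1:99, 1)))
    code
  }

  classes <- names(spec$atc_classes)
  drug_rows <- character(spec$n_drugs)
  mech_rows <- character(0)
  for (i in seq_len(spec$n_drugs)) {
    id <- sprintf("D%04d", i)
    n_codes <- 1L + stats::rpois(1, 0.3)
    cls <- if (length(classes) == 1) rep(classes, n_codes) else
      sample(classes, n_codes, replace = TRUE, prob = spec$atc_classes)
    codes <- toupper(vapply(cls, full_code, ""))
    drug_rows[i] <- paste(id, sprintf("synthetic drug %d", i),
                          paste(unique(codes), collapse = "|"), sep = "\t")
    k <- stats::rpois(1, spec$targets_per_drug - 1) + 1L
    targets <- sample(accessions, min(k, length(accessions)))
    actions <- sample(MECHANISM_ACTIONS, length(targets), replace = TRUE)
    mech_rows <- c(mech_rows, paste(id, targets, actions, sep = "\t"))
  }

  taxids <- names(spec$taxa)
  accs <- sort(unique(accessions))
  tax <- if (length(taxids) == 1) rep(taxids, length(accs)) else
    sample(taxids, length(accs), replace = TRUE, prob = spec$taxa)
  targ_rows <- paste(accs, tax,
                     ifelse(is.na(organisms[tax]),
                            paste("taxon", tax), organisms[tax]),
                     sep = "\t")

  list(
    drugs = paste0(paste(c(drug_header, drug_rows), collapse = "\n"), "\n"),
    mechanisms = paste0(paste(c(mech_header, mech_rows), collapse = "\n"), "\n"),
    targets = paste0(paste(c(targ_header, targ_rows), collapse = "\n"), "\n")
  )
}

#' Generate a complete fixture bundle
#'
#' Convenience wrapper running [make_ontology()], [make_gaf()] and
#' [make_drug_tables()] in sequence, wiring the generated accessions into
#' the drug tables.
#'
#' @param spec A `fixture_spec`.
#' @return A list of strings: `obo`, `gaf`, `drugs`, `mechanisms`,
#'   `targets`.
#' @export
make_fixture_bundle <- function(spec) {
  obo <- make_ontology(spec)
  graph <- parse_obo(obo)
  gaf <- make_gaf(spec, graph)
  accessions <- sprintf("P%06d", seq_len(max(spec$n_proteins, 1L)))
  tables <- make_drug_tables(spec, accessions)
  c(list(obo = obo, gaf = gaf), tables)
}

#' The hand-written worked-example fixture
#'
#' A small ontology (16 terms across all three namespaces, real GO ids and
#' names) holding the motifs every module's documentation leans on:
#' GO:0017124 "SH3 domain binding" under GO:0005515 "protein binding" (the
#' granular binding term that must not be generalised away), GO:0046677
#' "response to antibiotic" under GO:0009636 "response to toxic substance"
#' (the tree/search example), a diamond above GO:0009636, a mixed
#' `is_a`/`part_of` path to GO:0005634 "nucleus", and one obsolete term
#' with a `replaced_by` pointer. The GAF annotates five named proteins to
#' the motif terms.
#'
#' @return A list with `obo` and `gaf` strings.
#' @export
go_motif_fixture <- function() {
  obo <- paste(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0003674",
    "name: molecular_function",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0005488",
    "name: binding",
    "namespace: molecular_function",
    "is_a: GO:0003674",
    "",
    "[Term]",
    "id: GO:0005515",
    "name: protein binding",
    "namespace: molecular_function",
    "is_a: GO:0005488",
    "",
    "[Term]",
    "id: GO:0017124",
    "name: SH3 domain binding",
    "namespace: molecular_function",
    "synonym: \"SH3 binding\" EXACT []",
    "is_a: GO:0005515",
    "",
    "[Term]",
    "id: GO:0003824",
    "name: catalytic activity",
    "namespace: molecular_function",
    "is_a: GO:0003674",
    "",
    "[Term]",
    "id: GO:0016301",
    "name: kinase activity",
    "namespace: molecular_function",
    "is_a: GO:0003824",
    "",
    "[Term]",
    "id: GO:0016302",
    "name: obsolete phosphorylase kinase regulator activity",
    "namespace: molecular_function",
    "is_obsolete: true",
    "replaced_by: GO:0016301",
    "",
    "[Term]",
    "id: GO:0008150",
    "name: biological_process",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0050896",
    "name: response to stimulus",
    "namespace: biological_process",
    "is_a: GO:0008150",
    "",
    "[Term]",
    "id: GO:0042221",
    "name: response to chemical",
    "namespace: biological_process",
    "is_a: GO:0050896",
    "",
    "[Term]",
    "id: GO:0006950",
    "name: response to stress",
    "namespace: biological_process",
    "is_a: GO:0050896",
    "",
    "[Term]",
    "id: GO:0009636",
    "name: response to toxic substance",
    "namespace: biological_process",
    "synonym: \"toxin response\" EXACT []",
    "is_a: GO:0042221",
    "is_a: GO:0006950",
    "",
    "[Term]",
    "id: GO:0046677",
    "name: response to antibiotic",
    "namespace: biological_process",
    "is_a: GO:0009636",
    "",
    "[Term]",
    "id: GO:0005575",
    "name: cellular_component",
    "namespace: cellular_component",
    "",
    "[Term]",
    "id: GO:0005622",
    "name: intracellular anatomical structure",
    "namespace: cellular_component",
    "is_a: GO:0005575",
    "",
    "[Term]",
    "id: GO:0043226",
    "name: organelle",
    "namespace: cellular_component",
    "is_a: GO:0005575",
    "",
    "[Term]",
    "id: GO:0005634",
    "name: nucleus",
    "namespace: cellular_component",
    "is_a: GO:0043226",
    "relationship: part_of GO:0005622",
    ""
  ), collapse = "\n")

  gaf_row <- function(acc, term, aspect, taxon = 9606, evidence = "IDA") {
    paste("UniProtKB", acc, acc, "", term, "GO_REF:0000002", evidence, "",
          aspect, acc, "", "protein", paste0("taxon:", taxon), "20160927",
          "targetslim", "", "", sep = "\t")
  }
  gaf <- paste(c(
    "!gaf-version: 2.1",
    gaf_row("P11111", "GO:0017124", "F"),
    gaf_row("P11111", "GO:0009636", "P"),
    gaf_row("P22222", "GO:0005515", "F"),
    gaf_row("P22222", "GO:0046677", "P"),
    gaf_row("P33333", "GO:0016301", "F", taxon = 10090),
    gaf_row("P33333", "GO:0046677", "P", taxon = 10090),
    gaf_row("P44444", "GO:0005634", "C"),
    gaf_row("P55555", "GO:0042221", "P", taxon = 10116),
    ""
  ), collapse = "\n")

  list(obo = obo, gaf = gaf)
}
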