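Package: targetslim
Title: Build and Browse Gene Ontology Slims for Drug-Target Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for summarising the Gene Ontology annotations of protein
    drug targets with a GO slim. Parses OBO 1.2 ontologies and GAF 2.1/2.2
    annotation files, maps annotated terms to their nearest slim ancestors
    (map2slim semantics, including "count mode" protein tallies), measures
    slim coverage of a protein set and iteratively refines a slim towards a
    target coverage, renders the result as a searchable protein-target tree,
    and links GO-category groupings of targets to drug ATC classes and
    mechanisms of action. A seeded fixture generator produces synthetic
    ontologies, annotation files and drug tables so the whole workflow runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    withr,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
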