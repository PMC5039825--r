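# targetslim

Build, refine and browse Gene Ontology slims for protein drug-target space.

Curated drug-discovery resources annotate their single-protein targets with
Gene Ontology (GO) terms of wildly varying specificity, which makes it hard
to compare, group, or search targets by biology. The standard remedy is a
**GO slim**: a small set of high-level terms to which every fine-grained
annotation is mapped upward through the ontology's `is_a`/`part_of`
hierarchy. `targetslim` implements that whole workflow for people who curate
target sets or mine drug–target databases: parsing OBO ontologies and GAF
annotation files, map2slim-style term mapping with per-term protein tallies,
coverage-driven iterative slim refinement, a searchable protein-target tree,
and the link from GO categories of targets to drug ATC classes and
mechanisms of action. A seeded fixture generator produces synthetic
ontologies, GAF files and drug tables, so everything runs and is tested
without any external download.

## The method

**Direct mapping (map2slim).** For an ontology DAG `G`, a slim `S`, and a
relation set `R` (default `{is_a, part_of}`), an annotated term `t` maps to
every slim term `s` reachable from `t` by a directed path under `R` with no
slim term strictly between `t` and `s`. If `t ∈ S`, it maps to itself and is
never generalised further — an annotation to a granular slim member such as
*SH3 domain binding* (GO:0017124) stays there instead of collapsing into
*protein binding* (GO:0005515). A term below several qualifying slim terms
keeps all of them. The **inclusive** mapping is `S ∩ ({t} ∪ ancestors(t))`.

**Count mode.** For each slim term, the number of distinct proteins with at
least one annotation whose direct (resp. inclusive) mapping contains it.

**Coverage and refinement.** A protein is *covered* when at least one of its
annotations maps inclusively to a non-root slim term (namespace roots earn
no credit — they would make any slim look perfect). Starting from any slim,
`refine_slim()` alternates two moves until a target coverage (default 90 %)
is reached: prune slim terms that tally zero proteins, and greedily add the
non-slim, non-root term covering the most currently-uncovered proteins
(ties go to the deeper, more specific term, then the smaller term id).

**Information content.** `ic(s) = −log₂(n_s / N)` where `n_s` is the number
of proteins inclusively mapped to slim term `s` and `N` the number of
annotated proteins; terms with `ic` below a threshold are flagged as overly
generic — the quantitative cue behind keeping granular binding terms in a
slim rather than one catch-all parent.

**Drug links.** Mechanism-of-action targets of drugs in an ATC class
(prefix match on level boundaries 1/3/4/5/7) are grouped by chosen slim
categories; drugs are counted once per Venn region — the region of their
exact covered category set — and broken down by mechanism action labels.

## Worked example

The built-in motif fixture is a 16-term ontology with five annotated
proteins, holding the two classic motifs: GO:0017124 under GO:0005515, and
GO:0046677 *response to antibiotic* under GO:0009636 *response to toxic
substance*.

```r
library(targetslim)

fx   <- go_motif_fixture()
g    <- parse_obo(fx$obo)
ann  <- parse_gaf(fx$gaf, g)
slim <- slim_set(g, c("GO:0009636", "GO:0046677", "GO:0005515",
                      "GO:0017124", "GO:0016301", "GO:0005634"))

tidy(count_mode(g, slim, ann))
#> # A tibble: 6 × 5
#>   term       name                        namespace          n_direct n_inclusive
#>   <chr>      <chr>                       <chr>                 <int>       <int>
#> 1 GO:0005515 protein binding             molecular_function        1           2
#> 2 GO:0005634 nucleus                     cellular_component        1           1
#> 3 GO:0009636 response to toxic substance biological_process        1           3
#> 4 GO:0016301 kinase activity             molecular_function        1           1
#> 5 GO:0017124 SH3 domain binding          molecular_function        1           1
#> 6 GO:0046677 response to antibiotic      biological_process        2           2
```

Direct counts respect the slim-free-path rule (the two antibiotic-annotated
proteins stay on GO:0046677); inclusive counts roll proteins up to every
slim ancestor, so GO:0009636 collects all three toxic-response proteins.
SH3-domain binding keeps its own protein even though protein binding is in
the slim.

```r
slim_coverage(g, slim, ann, target = 0.9)
#> <coverage_report> overall 80.0% (4/5 proteins; target 90%)
#>   biological_process: 75.0% (3/4)
#>   molecular_function: 100.0% (3/3)
#>   cellular_component: 100.0% (1/1)
#>   1 uncovered accession(s), 0 zero-count slim term(s)

tree <- build_target_tree(g, slim, ann)
tree
#> <target_tree> 6 slim terms across 3 namespace(s)
#> biological_process (3)
#>   GO:0009636 response to toxic substance (3)
#>     GO:0046677 response to antibiotic (2)
#> molecular_function (3)
#>   GO:0005515 protein binding (2)
#>     GO:0017124 SH3 domain binding (1)
#>   GO:0016301 kinase activity (1)
#> cellular_component (1)
#>   GO:0005634 nucleus (1)

search_tree(tree, "toxic substance")
#> # A tibble: 1 × 3
#>   term       name                        cumulative_count
#>   <chr>      <chr>                                  <int>
#> 1 GO:0009636 response to toxic substance                3
```

The one uncovered protein is annotated only to *response to chemical*,
which sits above every slim term; `suggest_terms()` would propose adding
that term (or a descendant) to close the gap, and `refine_slim()` automates
the prune/add loop. Tree counts are cumulative (node plus slim
descendants), with each protein counted once.

## Command line

A thin Rscript front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "targetslim.R", package = "targetslim"))')
Rscript $CLI fixtures --seed 1 --out-dir fx/
Rscript $CLI slim-refine --obo fx/ontology.obo --gaf fx/annotations.gaf \
        --slim fx/ontology.obo --target 0.9 --out-slim refined.txt
Rscript $CLI tree-search --obo fx/ontology.obo --gaf fx/annotations.gaf \
        --slim refined.txt --query "synthetic"
Rscript $CLI drug-venn --obo fx/ontology.obo --gaf fx/annotations.gaf \
        --slim refined.txt --drugs fx/drugs.tsv --mechanisms fx/mechanisms.tsv \
        --atc L --categories GO:9000002,GO:9000003
```

Subcommands: `slim-map`, `slim-count`, `slim-coverage`, `slim-refine`,
`tree-build`, `tree-search`, `drug-venn`, `fixtures`. Tables go to stdout
(or `--out`), logs to stderr; exit codes are 0 (success), 1 (validation or
parse error), 2 (usage error). Every option can also live in a flat
key-value `--config` file, with flags taking precedence.

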