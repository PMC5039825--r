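---
title: "Slimming drug-target annotation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slimming drug-target annotation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetslim)
```

## The problem

Protein drug targets carry GO annotations of very uneven specificity: one
target may be annotated to *SH3 domain binding*, another to nothing more
specific than *binding*. Summarising a target set therefore needs a **GO
slim** — a few hundred high-level terms — plus a mapping rule that carries
every fine-grained annotation up to the slim. `targetslim` implements the
slim construction loop (map, count, prune, add, repeat until coverage), the
browsable target tree built from the result, and the downstream link from
GO categories to drug ATC classes and mechanisms of action.

## Mapping semantics

Two mappings are computed for every annotated term `t`, under a relation
set `R` that defaults to `{is_a, part_of}`:

* **direct**: every slim term `s` reachable from `t` via `R`-edges by a
  path with *no slim term strictly between* `t` and `s`. If `t` is itself
  in the slim, the direct mapping is `{t}` — a slim member is never
  generalised to a slim ancestor. This is the published map2slim behaviour
  and is what protects granular slim members: with both GO:0017124 (*SH3
  domain binding*) and GO:0005515 (*protein binding*) in a slim, an SH3
  annotation stays at GO:0017124.
* **inclusive**: `slim ∩ ({t} ∪ ancestors(t))`, used for rolled-up counts,
  coverage and the tree's cumulative numbers.

A term below several qualifying slim terms keeps all of them; collapsing
multi-parents to one would silently bias counts. "Count mode" tallies
distinct proteins (accession identity, column 2 of the GAF) per slim term
under each mapping; direct counts can never exceed inclusive ones.

The regulates-family relations are parsed but excluded from traversal by
default: slimming along regulatory edges would conflate "regulates X" with
"is X". The relation set is an explicit argument everywhere (and a
`--relations` flag on the CLI) because published runs of the mapper do not
always state their choice.

## Coverage and the refinement loop

A protein is **covered** when at least one of its annotations maps
inclusively to a *non-root* slim term. Roots are excluded because a slim
containing `biological_process` would cover everything and say nothing.
Coverage is reported per namespace (over the proteins annotated in that
namespace, credited by the namespace of the slim term reached) and overall
(over distinct annotated accessions); the 90 % default target is treated as
overall coverage.

`refine_slim()` automates what is otherwise a manual curation loop. Each
round:

1. **prune** slim terms whose inclusive tally is zero — provably
   coverage-neutral, since a term's inclusive protein set depends only on
   the term and the annotations, not on the rest of the slim;
2. **suggest and commit** greedy additions: among non-slim, non-root,
   non-obsolete terms, add the one covering the most currently-uncovered
   proteins, committing each pick before scoring the next, until the
   target, a gain of zero, or a per-round cap.

Gain ties break towards the **deeper** candidate — depth being the longest
`is_a`/`part_of` path to a root — preferring the more specific,
information-richer term; remaining ties break on the smaller term id so
runs are reproducible. The loop stops at the target, after a round that
changes nothing, or at `max_rounds`; its coverage trail is non-decreasing
by construction (additions are monotone, pruning is neutral). When every
protein has at least one annotation to a non-root term, the greedy step can
always add that term itself, so full coverage is reachable in principle.
Greedy set cover is not optimal — the resulting slim can be larger than the
minimum — but it is deterministic and transparent, which matters more here;
a report-only mode (`suggest_terms()`, or `--report-only` on the CLI)
supports a human-in-the-loop workflow instead.

**Information content** operationalises the "loss of information" argument
for keeping granular terms: `ic(s) = −log₂(fraction of annotated proteins
inclusively mapped to s)`, in bits (any log base is equivalent up to
scale). A term every protein maps to has ic 0; `information_report()` flags
terms under a caller-chosen threshold (default 1 bit, i.e. terms absorbing
more than half the proteins) as candidates for replacement by their
children. No quantitative cutoff can reproduce a curator's judgement;
the report is a screen, not a decision rule.

## The target tree

The browsable tree is the slim-induced hierarchy: slim term `p` parents
slim term `s` when `p` direct-maps `s` under the slim with `s` removed —
i.e. dropped GO intermediates are contracted away. Terms with no slim
ancestor hang off their namespace root. A multi-parent slim term is
rendered under each parent (a navigation tree cannot display a DAG node
once) with counts computed once and shared. Displayed counts are
**cumulative** — node plus slim descendants, each protein once — matching
the browsing semantics of "N protein targets annotated to this term";
direct counts are retained internally. Search is case-insensitive substring
match over names and synonyms: deterministic and testable, unlike stemming
or fuzzy matching. The JSON serialization is canonical (display order,
sorted protein lists), so export → import → export is byte-identical.

## Drug links

ATC prefixes must sit on a level boundary (1/3/4/5/7 characters), so "L"
selects the antineoplastic/immunomodulating class but "L0" is rejected
rather than silently matching "L01" and "L04". Drug-to-category attribution
goes through curated mechanism-of-action targets only, not every assayed
protein. Venn regions are disjoint: a drug counts once, in the region of
its exact covered-category set, and region counts therefore sum to the
number of drugs with at least one covered category. The five categories are
a required argument — category choice is an analysis decision, not a
constant of the method.

## Synthetic fixtures

The generator emulates the *shape* of a GOA/ChEMBL-style extract, not its
content: per-namespace rooted DAGs (default 200 terms per namespace, depth
≤ 8, branching 2.5, 15 % of terms with a second `is_a`/`part_of` parent,
acyclic by layered construction), 1000 proteins with Poisson(5)-distributed
annotations (minimum 1) biased 0.7 towards leaf terms, a species mix
dominated by human/rat/mouse as in curated target sets, and 50 drugs with
Poisson(2) mechanism targets and weighted ATC classes. Synthetic term ids
use a reserved `GO:9xxxxxx` block so they can never collide with the real
ids in the hand-written motif fixture. One seed drives all randomness; the
same spec and seed give byte-identical files.

What passing tests on these fixtures shows: the mapping rule, tallies,
coverage algebra, tree and Venn logic are correct on DAGs of realistic
shape. What it does not show: behaviour on real GO topology (much deeper,
heavier multi-parenting, cross-namespace `part_of`), real evidence-code
distributions, or the release-dependent counts of any live database — those
depend on snapshots and curation and are out of scope by design.

## Numerical and edge-case choices

* Term order in every output is sorted by term id; children in the tree
  sort by descending cumulative count then id — all outputs are
  byte-reproducible.
* Obsolete terms are kept in the term table (so `replaced_by` redirection
  works during GAF parsing) but are edge-less, never traversed, never
  allowed in a slim, and never suggested.
* Annotations to terms missing from the graph are dropped with a warning
  (error in strict mode); aspect letters conflicting with the term's
  namespace are kept but logged — silent data loss is worse than an
  upstream inconsistency.
* `NOT`-qualified annotations are dropped by default: negative assertions
  must not inflate slim counts. The evidence whitelist defaults to
  keep-all, matching the convention of slimming across all evidence codes;
  both are flags.
* Duplicate GAF records collapse on (accession, qualifiers, term,
  evidence, taxon); isoform suffixes (column 17) are ignored because
  targets are accession-keyed.
* Coverage with zero annotated proteins is 0, not NaN; an all-empty slim
  prunes to the empty slim; empty slims are rejected by the tree builder.
* Subset export rewrites parent links to the nearest kept ancestors (path
  contraction); a contracted link is labelled `is_a` when an all-`is_a`
  slim-free path exists, `part_of` otherwise.

## Problem sizes used in the checks

The test suite and the acceptance script exercise: 1000 seeded random DAGs
(≤ 50 terms, ≤ 3 parents) against an independent igraph-reachability
oracle for both relation sets; count-mode cross-checks at 500 proteins;
refinement from a seeded 10-term starter on the default 3 × 200-term /
1000-protein benchmark (reaching ≥ 90 % overall coverage); 100 random
term-addition monotonicity trials; and 50 drugs × 5 categories against
power-set enumeration. These sizes make the whole suite run in a few
minutes on one CPU while keeping each property's search space honest.

## Known limitations

* The greedy refinement is a heuristic; it will not reproduce a manually
  curated slim's exact term choices, only its coverage behaviour.
* `intersection_of` logical definitions, GPAD/GPI, annotation extensions
  and taxon constraints are not parsed.
* Search is substring-only; no stemming, no synonyms beyond those in the
  ontology file.
* The per-namespace coverage denominator counts proteins by the namespaces
  they are annotated in; a protein reached only across namespaces (via a
  cross-namespace `part_of`) credits the slim term's namespace, which can
  in principle differ from the annotation's.
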