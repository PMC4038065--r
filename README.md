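# gosets

Build GSEA-compatible (MSigDB-format) gene set collections for any species
from Gene Ontology annotations.

## The problem

Gene Set Enrichment Analysis (GSEA) and related tools (ErmineJ, fgsea, ...)
need predefined gene set collections in `.gmt`/`.gmx` format. Curated
GO-derived collections are readily available for human but rarely for other
species, and even the human collections lag the current GO release by years.
Given a GO ontology (OBO file) and any gene–GO association source, `gosets`
constructs an up-to-date collection for the organism of interest.

A naive "one set per annotated term" build misses most of the signal, because
curators annotate genes to the most specific applicable term. Under the GO
**true-path rule**, a gene annotated to a term is implicitly annotated to all
of that term's ancestors, so `gosets` propagates every association up the
ontology DAG before building sets:

```
members(t) = direct(t) ∪  ⋃ members(c)   over all children c of t
```

following `is_a` and `part_of` edges (configurable). In typical builds the
large majority of term–gene memberships exist only because of this
propagation step. The pipeline then applies evidence-code filtering, optional
gene identifier remapping, size filtering (default 10–700 genes, inclusive),
and collapses terms with identical gene content into a single set whose
description records *every* contributing term together with its depth — the
shortest edge distance from the namespace root, a rough specificity level:

```
GO:0000002 muscle system process [level 1]|GO:0000003 muscle contraction [level 2]
```

The set is named after, and its URL points to, the most general (minimum
depth) of those terms.

## Input sources

* **NCBI gene2go** — tab-separated, Entrez Gene IDs, evidence codes, taxon
  filter required.
* **GAF 2.x** — the GO association file format; choose symbol or object ID,
  optional taxon filter.
* **Array annotation files** — Affymetrix NetAffx CSV or Agilent TSV dialects
  (no evidence codes; use the `all` evidence profile).

Rows whose qualifier asserts `NOT` are excluded everywhere. Synonymous GO
accessions are remapped to the supplied ontology's preferred accession,
obsolete and unknown accessions are dropped, and all three cases are counted
and reported.

## Worked example

The package ships a seeded fixture generator, so the whole pipeline can be
exercised without downloading the real GO releases:

```r
library(gosets)
write_fixture_dir("demo", fixture_spec(n_terms = 60, n_genes = 50,
                                       n_assocs = 200, seed = 42))
cfg <- run_config("demo/ontology.obo", "gene2go", "demo/gene2go.tsv",
                  "demo/sets.gmt", taxon = 10090, evidence = "all",
                  min_size = 5)
col <- build_genesets(cfg)
#> ontology: parsed 60 terms
#> read: 224 associations from gene2go source
#> resolve: 10 synonym(s) remapped, 10 obsolete and 4 unknown term reference(s) dropped
#> gosets-summary synonyms=10 obsolete=10 unknown=4 propagated_fraction=0.7663 sets=38 output=demo/sets.gmt
col
#> gene set collection: 38 sets, sizes 5 - 50 (mean 18.2)
```

The summary line says what happened: 10 associations used a synonymous
accession and were remapped, 10 pointed at obsolete terms and 4 at unknown
accessions (both dropped), and 77% of the final term–gene memberships were
created by propagation rather than stated directly in the source. Each `.gmt`
line holds the set name, the representative term's URL plus the full term
list with levels, then the genes:

```
SYNTHETIC_PROCESS_05	http://amigo.geneontology.org/amigo/term/GO:0000005 GO:0000005 synthetic process 05 [level 1]	100001	100002	...
```

Why propagation matters, on the canned 16-direct/81-descendant fixture:

```r
sf <- sarcomere_fixture()
idx <- build_index(sf$associations)
length(idx$members[["GO:0000002"]])                      # 16 before
length(propagate(idx, sf$dag)$members[["GO:0000002"]])   # 97 after
```

For real data, point `run_config()` (or the CLI below) at a GO release OBO
file and e.g. the NCBI gene2go table with your organism's taxon ID.

## Command line

```sh
exec/gosets build --ontology go.obo --source gene2go.tsv --kind gene2go \
    --taxon 10090 --evidence high_quality --out mouse_go.gmt
exec/gosets fixtures --dir fixtures/ --seed 1
```

`--cache` caches the parsed ontology for repeat runs; `--config` loads a JSON
run configuration (flags win). Exit codes: 0 success, 2 configuration error,
3 parse error, 4 I/O error.

## Acceptance script

`scripts/acceptance.R` regenerates a seeded synthetic fixture, runs the full
pipeline on it end to end, and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
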